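# Shared fixtures, memoized so expensive populations are built once per
# test run. Everything is generated in code under fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

fixture_seeds <- function(n = 120L, rng_seed = 2024L) {
  key <- paste0("seeds.", n, ".", rng_seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_seed_set(n, rng_seed = rng_seed)
  }
  .fixture_env[[key]]
}

fixture_edit_table <- function() {
  if (is.null(.fixture_env$edit_table)) {
    .fixture_env$edit_table <- estimate_edit_probabilities(fixture_seeds())
  }
  .fixture_env$edit_table
}

# small curated molecules spanning the features the core must handle
FIXTURE_SMILES <- c(
  ethanol = "CCO", acetic_acid = "CC(=O)O", benzene = "c1ccccc1",
  pyridine = "c1ccncc1", pyrrole = "c1cc[nH]c1", naphthalene = "c1ccc2ccccc2c1",
  cyclohexane = "C1CCCCC1", acetonitrile = "CC#N", tfmb = "FC(F)(F)c1ccccc1",
  mdma = "CC(Cc1ccc2c(c1)OCO2)NC", acetamide = "CC(N)=O",
  isopropanol = "CC(C)O", butene = "CC=CC", glycine = "NCC(=O)O"
)

fixture_records <- function() {
  if (is.null(.fixture_env$records)) {
    .fixture_env$records <- lapply(names(FIXTURE_SMILES), function(nm)
      parse_and_sanitize(FIXTURE_SMILES[[nm]], id = nm))
  }
  .fixture_env$records
}

# independent all-pairs shortest-path oracle built on igraph (Wiener tests)
wiener_oracle_igraph <- function(record) {
  mol <- record$mol
  n <- length(mol$atoms$element)
  if (n <= 1L) return(0)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(mol$bonds$a)) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a, mol$bonds$b))
  }
  d <- igraph::distances(g)
  if (any(is.infinite(d))) stop("disconnected")
  sum(d) / 2
}

# independent per-atom ln-factorial oracle from the raw bond list
bertz_oracle <- function(record) {
  mol <- record$mol
  n <- length(mol$atoms$element)
  deg <- integer(n)
  for (k in seq_along(mol$bonds$a)) {
    deg[mol$bonds$a[k]] <- deg[mol$bonds$a[k]] + 1L
    deg[mol$bonds$b[k]] <- deg[mol$bonds$b[k]] + 1L
  }
  sum(vapply(deg, function(d) log(factorial(d)), 0))
}
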