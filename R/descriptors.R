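# Physicochemical descriptors. Graph-derived quantities (weights, counts,
# fractions) are computed on the package's own molecular graph; logP and
# TPSA are delegated to OpenBabel (via ChemmineOB), whose TPSA is the
# standard polar-surface-contribution sum and whose logP is an atom
# contribution model.

.DESCRIPTOR_NAMES <- c("MW", "NVE", "NRE", "TPSA", "MolLogP",
                       "NHD", "NHA", "NRB", "FractionCSP3")

mol_weight <- function(mol) {
  hs <- implicit_h(mol)
  sum(.ATOMIC_MASS[mol$atoms$element]) + sum(hs) * .ATOMIC_MASS[["H"]]
}

n_heteroatoms <- function(mol) {
  sum(!mol$atoms$element %in% c("C", "H"))
}

# Lipinski-style H-bond donors/acceptors: N or O with >=1 H / any N or O
hbond_counts <- function(mol) {
  hs <- implicit_h(mol)
  no <- mol$atoms$element %in% c("N", "O")
  c(NHD = sum(no & hs >= 1L), NHA = sum(no))
}

n_rotatable_bonds <- function(mol) {
  m <- n_bonds(mol)
  if (m == 0L) return(0L)
  deg <- heavy_degree(mol)
  rbf <- ring_bond_flags(mol)
  single <- abs(mol$bonds$order - 1) < 1e-9 & !mol$bonds$aromatic
  nonterminal <- deg[mol$bonds$a] >= 2L & deg[mol$bonds$b] >= 2L
  sum(single & !rbf & nonterminal)
}

fraction_csp3 <- function(mol) {
  is_c <- mol$atoms$element == "C"
  if (!any(is_c)) return(0)
  sp3 <- vapply(which(is_c), function(i) {
    if (mol$atoms$aromatic[i]) return(FALSE)
    inc <- mol$bonds$a == i | mol$bonds$b == i
    !any(inc & (mol$bonds$order > 1 + 1e-9 | mol$bonds$aromatic))
  }, TRUE)
  sum(sp3) / sum(is_c)
}

n_valence_electrons <- function(mol) {
  hs <- implicit_h(mol)
  sum(.VALENCE_ELECTRONS[mol$atoms$element]) + sum(hs) -
    sum(mol$atoms$charge)
}

# refined Morgan ranks without the tie-breaking pass: symmetric positions
# share a rank, which is what substituent-distinctness tests need
symmetry_ranks <- function(mol) {
  n <- n_atoms(mol)
  if (n <= 1L) return(rep(1L, n))
  adj <- adjacency(mol)
  hs <- implicit_h(mol)
  deg <- heavy_degree(mol)
  key <- sprintf("%s|%d|%d|%+d|%d",
                 mol$atoms$element, as.integer(mol$atoms$aromatic),
                 deg, mol$atoms$charge, hs)
  rank <- match(key, sort(unique(key)))
  repeat {
    key <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      nbr <- if (is.null(nb)) "" else {
        ords <- mol$bonds$order[nb[, 2L]]
        ords[mol$bonds$aromatic[nb[, 2L]]] <- 1.5
        paste(sort(sprintf("%d:%g", rank[nb[, 1L]], ords)), collapse = ",")
      }
      sprintf("%05d|%s", rank[i], nbr)
    }, "")
    new_rank <- match(key, sort(unique(key)))
    if (length(unique(new_rank)) == length(unique(rank))) return(new_rank)
    rank <- new_rank
  }
}

# potential stereocenters: sp3 carbon with four pairwise-distinct
# substituents (implicit H counted as one substituent, so at most one H);
# distinctness judged on symmetry ranks of the heavy neighbors
chiral_carbon_flags <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(logical(0))
  hs <- implicit_h(mol)
  deg <- heavy_degree(mol)
  rank <- symmetry_ranks(mol)
  adj <- adjacency(mol)
  vapply(seq_len(n), function(i) {
    if (mol$atoms$element[i] != "C" || mol$atoms$aromatic[i]) return(FALSE)
    inc <- mol$bonds$a == i | mol$bonds$b == i
    if (any(inc & (mol$bonds$order > 1 + 1e-9 | mol$bonds$aromatic))) return(FALSE)
    if (deg[i] + hs[i] != 4L || hs[i] > 1L) return(FALSE)
    nb <- adj[[i]]
    nbr_ranks <- rank[nb[, 1L]]
    length(unique(nbr_ranks)) == length(nbr_ranks)
  }, TRUE)
}

# batched OpenBabel properties for a character vector of SMILES;
# returns a data.frame with columns logP and TPSA aligned to the input.
# One obabel process handles the whole batch; the ChemmineOB in-process
# binding is the fallback when the binary is unavailable.
ob_properties <- function(smiles) {
  if (!length(smiles)) return(data.frame(logP = numeric(), TPSA = numeric()))
  ids <- sprintf("obq%06d", seq_along(smiles))
  logP <- rep(NA_real_, length(smiles))
  tpsa <- rep(NA_real_, length(smiles))
  if (nzchar(Sys.which("obabel"))) {
    inp <- tempfile(fileext = ".smi")
    on.exit(unlink(inp), add = TRUE)
    writeLines(paste(smiles, ids), inp)
    out <- suppressWarnings(
      system2("obabel", c(inp, "-otxt", "--append", shQuote("logP TPSA")),
              stdout = TRUE, stderr = FALSE))
    parts <- strsplit(out, "[ \t]+")
    for (p in parts) {
      if (length(p) < 3L) next
      k <- match(p[1], ids)
      if (!is.na(k)) {
        logP[k] <- suppressWarnings(as.numeric(p[2]))
        tpsa[k] <- suppressWarnings(as.numeric(p[3]))
      }
    }
  } else {
    inp <- paste(paste(smiles, ids, sep = "\t"), collapse = "\n")
    res <- ChemmineOB::forEachMol("SMILES", inp, function(m) {
      p <- ChemmineOB::prop_OB(m)
      c(logP = p$logP, TPSA = p$TPSA, title = p$title)
    })
    for (r in res) {
      k <- match(r[["title"]], ids)
      if (!is.na(k)) {
        logP[k] <- as.numeric(r[["logP"]])
        tpsa[k] <- as.numeric(r[["TPSA"]])
      }
    }
  }
  data.frame(logP = logP, TPSA = tpsa)
}

#' Molecular descriptor vector
#'
#' The nine descriptors used by the diversity analysis: molecular weight
#' (MW, g/mol), number of valence electrons (NVE), number of radical
#' electrons (NRE; zero in this closed-shell implicit-hydrogen model),
#' topological polar surface area (TPSA, A^2), logP (MolLogP), hydrogen
#' bond donors/acceptors (NHD/NHA, Lipinski N/O definitions), rotatable
#' bonds (NRB, non-ring single bonds between non-terminal heavy atoms) and
#' the fraction of sp3-hybridized carbons.
#'
#' @param record a valid `molecule_record`.
#' @param ob optional precomputed one-row data frame with `logP` and
#'   `TPSA` (used internally for batching).
#' @return named numeric vector of the nine descriptors.
#' @export
descriptor_vector <- function(record, ob = NULL) {
  stopifnot(inherits(record, "molecule_record"))
  if (!isTRUE(record$valid)) stop("cannot compute descriptors for an invalid record")
  mol <- record$mol
  if (is.null(ob)) ob <- ob_properties(record$smiles_canonical)
  hb <- hbond_counts(mol)
  c(MW = mol_weight(mol),
    NVE = n_valence_electrons(mol),
    NRE = 0,
    TPSA = ob$TPSA[1],
    MolLogP = ob$logP[1],
    NHD = unname(hb["NHD"]),
    NHA = unname(hb["NHA"]),
    NRB = n_rotatable_bonds(mol),
    FractionCSP3 = fraction_csp3(mol))
}

#' Descriptor matrix for a population
#'
#' Computes [descriptor_vector()] for every valid record with a single
#' batched logP/TPSA call.
#'
#' @param records list of `molecule_record`s (invalid ones are skipped).
#' @return data frame with one row per valid record, `id` column first.
#' @export
descriptor_matrix <- function(records) {
  valid <- Filter(function(r) isTRUE(r$valid), records)
  if (!length(valid)) {
    out <- as.data.frame(matrix(numeric(), 0, length(.DESCRIPTOR_NAMES),
                                dimnames = list(NULL, .DESCRIPTOR_NAMES)))
    return(cbind(data.frame(id = character()), out))
  }
  smis <- vapply(valid, function(r) r$smiles_canonical, "")
  ob <- ob_properties(smis)
  rows <- t(vapply(seq_along(valid), function(k) {
    descriptor_vector(valid[[k]], ob = ob[k, , drop = FALSE])
  }, numeric(length(.DESCRIPTOR_NAMES))))
  out <- as.data.frame(rows)
  names(out) <- .DESCRIPTOR_NAMES
  cbind(data.frame(id = vapply(valid, function(r) r$id, ""),
                   stringsAsFactors = FALSE), out)
}
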