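# Graph mutation operators. Both operate on the kekulized heavy-atom
# graph and validate every candidate through the same full sanitization
# used for the token operators; invalid candidates are rejected and
# resampled up to the configured cap.

.GBGA_EDITS <- c("add-atom", "remove-atom", "add-bond", "remove-bond",
                 "change-element", "change-bond-order", "form-ring",
                 "cleave-ring")

# propose one primitive edit; returns list(mol, trace) or NULL when the
# edit kind is not applicable to this molecule
propose_gbga_edit <- function(mol, kind, cfg) {
  n <- n_atoms(mol)
  fv <- free_valence(mol)
  switch(kind,
    "add-atom" = {
      cand <- which(fv >= 1)
      if (!length(cand)) return(NULL)
      a <- cand[sample.int(length(cand), 1L)]
      el <- sample(cfg$element_palette, 1L)
      maxo <- min(3, fv[a], max(.DEFAULT_VALENCE[[el]]))
      o <- sample.int(max(1L, floor(maxo)), 1L)
      mol2 <- add_atom_(mol, el)
      mol2 <- add_bond_(mol2, a, n_atoms(mol2), o)
      list(mol = mol2, trace = sprintf("add-atom %s(order %d) at %d", el, o, a))
    },
    "remove-atom" = {
      if (n < 2L) return(NULL)
      a <- sample.int(n, 1L)
      mol2 <- remove_atoms_(mol, a)
      if (length(unique(components(mol2))) > 1L) {
        if (cfg$remove_policy == "reject") return(NULL)
        mol2 <- keep_largest_fragment(mol2)
      }
      list(mol = mol2, trace = sprintf("remove-atom %d", a))
    },
    "add-bond" = {
      cand <- which(fv >= 1)
      if (length(cand) < 2L) return(NULL)
      for (try in 1:10) {
        ab <- sample(cand, 2L)
        if (is.na(find_bond(mol, ab[1], ab[2]))) {
          mol2 <- add_bond_(mol, ab[1], ab[2], 1)
          return(list(mol = mol2,
                      trace = sprintf("add-bond %d-%d", ab[1], ab[2])))
        }
      }
      NULL
    },
    "remove-bond" = {
      m <- n_bonds(mol)
      if (m == 0L) return(NULL)
      rbf <- ring_bond_flags(mol)
      cand <- which(!rbf)
      if (!length(cand)) return(NULL)
      k <- cand[sample.int(length(cand), 1L)]
      mol2 <- remove_bonds_(mol, k)
      if (length(unique(components(mol2))) > 1L) {
        if (cfg$remove_policy == "reject") return(NULL)
        mol2 <- keep_largest_fragment(mol2)
      }
      list(mol = mol2, trace = sprintf("remove-bond %d-%d",
                                       mol$bonds$a[k], mol$bonds$b[k]))
    },
    "change-element" = {
      a <- sample.int(n, 1L)
      pool <- setdiff(cfg$element_palette, mol$atoms$element[a])
      if (!length(pool)) return(NULL)
      el <- sample(pool, 1L)
      mol2 <- mol
      mol2$atoms$element[a] <- el
      list(mol = mol2, trace = sprintf("change-element %d %s->%s",
                                       a, mol$atoms$element[a], el))
    },
    "change-bond-order" = {
      m <- n_bonds(mol)
      if (m == 0L) return(NULL)
      k <- sample.int(m, 1L)
      old <- round(mol$bonds$order[k])
      pool <- setdiff(1:3, old)
      o <- sample(pool, 1L)
      mol2 <- mol
      mol2$bonds$order[k] <- o
      mol2$bonds$aromatic[k] <- FALSE
      list(mol = mol2, trace = sprintf("change-bond-order %d-%d %d->%d",
                                       mol$bonds$a[k], mol$bonds$b[k], old, o))
    },
    "form-ring" = {
      cand <- which(fv >= 1)
      if (length(cand) < 2L) return(NULL)
      a <- cand[sample.int(length(cand), 1L)]
      adj <- adjacency(mol)
      d <- bfs_dist(adj, a, n)
      sizes <- cfg$ring_sizes
      partners <- which(fv >= 1 & (d + 1) %in% sizes)
      partners <- partners[vapply(partners, function(b) is.na(find_bond(mol, a, b)), TRUE)]
      if (!length(partners)) return(NULL)
      b <- partners[sample.int(length(partners), 1L)]
      mol2 <- add_bond_(mol, a, b, 1)
      list(mol = mol2, trace = sprintf("form-ring %d-%d (size %d)", a, b, d[b] + 1))
    },
    "cleave-ring" = {
      m <- n_bonds(mol)
      if (m == 0L) return(NULL)
      rbf <- ring_bond_flags(mol)
      cand <- which(rbf)
      if (!length(cand)) return(NULL)
      k <- cand[sample.int(length(cand), 1L)]
      mol2 <- remove_bonds_(mol, k)
      mol2$bonds$aromatic[] <- FALSE # broken aromatic ring loses the flag
      list(mol = mol2, trace = sprintf("cleave-ring %d-%d",
                                       mol$bonds$a[k], mol$bonds$b[k]))
    },
    NULL)
}

# finalize a sanitized candidate graph into a mutation record
.finish_graph_mutation <- function(parent, operator, mol2, attempts, trace,
                                   t0, cfg) {
  smi <- write_canonical_smiles(mol2)
  elapsed <- proc.time()[["elapsed"]] - t0
  make_mutation_record(parent, operator, smi, attempts = attempts,
                       trace = trace, elapsed = elapsed, cfg = cfg)
}

#' Graph-based genetic-algorithm mutation (GB-GA)
#'
#' Applies one primitive graph edit drawn from add/remove atom, add/remove
#' bond, change element, change bond order, form ring (sizes 3-7) or
#' cleave ring, with uniform default weights. Each candidate is checked by
#' full sanitization; invalid candidates are rejected and resampled up to
#' `resample_cap` retries. Atom or bond removals that disconnect the
#' molecule keep the largest fragment under the default policy.
#'
#' @param record valid parent `molecule_record`.
#' @param cfg a `mutation_config` (operator `"GB-GA"`).
#' @return a `mutation_record` (error `resample-exhausted` when every
#'   retry failed).
#' @export
graph_mutation_gbga <- function(record, cfg = mutation_config("GB-GA")) {
  stopifnot(inherits(record, "molecule_record"), isTRUE(record$valid))
  .maybe_seed(cfg)
  t0 <- proc.time()[["elapsed"]]
  weights <- cfg$edit_weights
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(.GBGA_EDITS)), .GBGA_EDITS)
  kinds <- names(weights)

  max_attempts <- cfg$resample_cap + 1L
  for (attempt in seq_len(max_attempts)) {
    mol <- record$mol
    traces <- character(cfg$edits_per_mutant)
    ok <- TRUE
    for (e in seq_len(cfg$edits_per_mutant)) {
      kind <- sample(kinds, 1L, prob = weights)
      prop <- propose_gbga_edit(mol, kind, cfg)
      if (is.null(prop)) { ok <- FALSE; break }
      s <- sanitize_mol(prop$mol)
      if (!is.null(s$error)) { ok <- FALSE; break }
      mol <- s$mol
      traces[e] <- prop$trace
    }
    if (ok && n_atoms(mol) > 0L) {
      return(.finish_graph_mutation(record, "GB-GA", mol, attempt,
                                    traces[nzchar(traces)], t0, cfg))
    }
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  make_mutation_record(record, "GB-GA", NULL, attempts = max_attempts,
                       trace = character(), elapsed = elapsed, cfg = cfg,
                       error = "resample-exhausted")
}

#' Estimate graph-edit probabilities from a corpus
#'
#' Counts attachment events over all bonds of the corpus - context is the
#' element of the attachment atom, the event is the (added element, bond
#' order) pair, counted in both directions - plus the ring-size
#' distribution and the marginal attach/ring edit-kind probabilities.
#' Frequencies are normalized per context; the result is invariant to
#' corpus ordering.
#'
#' @param corpus list of `molecule_record`s (at least one valid).
#' @return an `edit_probability_table` with components `attach` (per
#'   context element, a data frame of element/order/p), `ring_sizes`
#'   (data frame size/p) and `p_ring` (marginal ring-edit probability).
#' @export
estimate_edit_probabilities <- function(corpus) {
  valid <- Filter(function(r) isTRUE(r$valid), corpus)
  if (!length(valid)) stop("empty corpus: no valid molecules")
  counts <- list()  # context -> named count vector "element|order"
  n_bond_events <- 0L
  ring_sizes <- integer()
  for (rec in valid) {
    mol <- rec$mol
    m <- n_bonds(mol)
    if (m > 0L) {
      for (k in seq_len(m)) {
        a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
        o <- round(mol$bonds$order[k])
        ea <- mol$atoms$element[a]; eb <- mol$atoms$element[b]
        for (ctx_ev in list(c(ea, eb), c(eb, ea))) {
          key <- ctx_ev[1]
          ev <- paste(ctx_ev[2], o, sep = "|")
          if (is.null(counts[[key]])) counts[[key]] <- numeric()
          counts[[key]][ev] <- (if (is.na(counts[[key]][ev])) 0 else counts[[key]][ev]) + 1
        }
      }
      n_bond_events <- n_bond_events + 2L * m
    }
    rings <- find_rings(mol)
    ring_sizes <- c(ring_sizes, lengths(rings))
  }
  attach <- lapply(counts, function(v) {
    parts <- strsplit(names(v), "|", fixed = TRUE)
    df <- data.frame(element = vapply(parts, `[`, "", 1L),
                     order = as.integer(vapply(parts, `[`, "", 2L)),
                     p = as.numeric(v) / sum(v))
    df <- df[order(df$element, df$order), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  attach <- attach[sort(names(attach))]
  rs <- if (length(ring_sizes)) {
    tab <- table(ring_sizes)
    data.frame(size = as.integer(names(tab)), p = as.numeric(tab) / sum(tab))
  } else data.frame(size = integer(), p = numeric())
  p_ring <- if (n_bond_events + length(ring_sizes) == 0L) 0 else
    length(ring_sizes) / (n_bond_events + length(ring_sizes))
  structure(list(attach = attach, ring_sizes = rs, p_ring = p_ring,
                 n_molecules = length(valid)),
            class = "edit_probability_table")
}

#' @export
print.edit_probability_table <- function(x, ...) {
  cat(sprintf("<edit_probability_table> %d molecules, %d contexts, p_ring=%.3f\n",
              x$n_molecules, length(x$attach), x$p_ring))
  invisible(x)
}

#' Corpus-trained graph mutation (GB-GM)
#'
#' Grows or modifies the parent by sampling one attachment (or
#' ring-formation) event from an [estimate_edit_probabilities()] table,
#' conditioned on a uniformly chosen attachment atom with free valence.
#' Candidates are sanitization-checked with resampling, as in GB-GA.
#' Parents with no applicable context for any atom yield `operator-skip`.
#'
#' @param record valid parent `molecule_record`.
#' @param table an `edit_probability_table`.
#' @param cfg a `mutation_config` (operator `"GB-GM"`).
#' @return a `mutation_record`.
#' @export
graph_generative_mutation <- function(record, table,
                                      cfg = mutation_config("GB-GM")) {
  stopifnot(inherits(record, "molecule_record"), isTRUE(record$valid),
            inherits(table, "edit_probability_table"))
  .maybe_seed(cfg)
  t0 <- proc.time()[["elapsed"]]

  mol0 <- record$mol
  fv0 <- free_valence(mol0)
  has_ctx <- which(fv0 >= 1 & mol0$atoms$element %in% names(table$attach))
  if (!length(has_ctx)) {
    elapsed <- proc.time()[["elapsed"]] - t0
    return(make_mutation_record(record, "GB-GM", NULL, attempts = 1L,
                                trace = character(), elapsed = elapsed,
                                cfg = cfg, error = "operator-skip"))
  }

  max_attempts <- cfg$resample_cap + 1L
  for (attempt in seq_len(max_attempts)) {
    mol <- mol0
    traces <- character(cfg$edits_per_mutant)
    ok <- TRUE
    for (e in seq_len(cfg$edits_per_mutant)) {
      fv <- free_valence(mol)
      do_ring <- nrow(table$ring_sizes) > 0L && stats::runif(1) < table$p_ring
      if (do_ring) {
        s <- table$ring_sizes$size[sample.int(nrow(table$ring_sizes), 1L,
                                              prob = table$ring_sizes$p)]
        cand <- which(fv >= 1)
        if (!length(cand)) { ok <- FALSE; break }
        a <- cand[sample.int(length(cand), 1L)]
        d <- bfs_dist(adjacency(mol), a, n_atoms(mol))
        partners <- which(fv >= 1 & abs(d - (s - 1)) < 1e-9)
        partners <- partners[vapply(partners, function(b)
          is.na(find_bond(mol, a, b)), TRUE)]
        if (!length(partners)) { ok <- FALSE; break }
        b <- partners[sample.int(length(partners), 1L)]
        mol <- add_bond_(mol, a, b, 1)
        traces[e] <- sprintf("ring size %d at %d-%d", s, a, b)
      } else {
        cand <- which(fv >= 1 & mol$atoms$element %in% names(table$attach))
        if (!length(cand)) { ok <- FALSE; break }
        a <- cand[sample.int(length(cand), 1L)]
        ctx <- table$attach[[mol$atoms$element[a]]]
        j <- sample.int(nrow(ctx), 1L, prob = ctx$p)
        el <- ctx$element[j]; o <- ctx$order[j]
        if (o > fv[a]) { ok <- FALSE; break }
        mol <- add_atom_(mol, el)
        mol <- add_bond_(mol, a, n_atoms(mol), o)
        traces[e] <- sprintf("attach %s(order %d) at %d", el, o, a)
      }
      s2 <- sanitize_mol(mol)
      if (!is.null(s2$error)) { ok <- FALSE; break }
      mol <- s2$mol
    }
    if (ok) {
      return(.finish_graph_mutation(record, "GB-GM", mol, attempt,
                                    traces[nzchar(traces)], t0, cfg))
    }
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  make_mutation_record(record, "GB-GM", NULL, attempts = max_attempts,
                       trace = character(), elapsed = elapsed, cfg = cfg,
                       error = "resample-exhausted")
}
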