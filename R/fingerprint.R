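# Circular (Morgan/ECFP4-style) fingerprint: radius-2 atom environments
# hashed onto a fixed-length bit vector. Initial atom invariants combine
# element, heavy degree, implicit H count, charge, aromaticity and ring
# membership; each iteration rehashes the atom with the sorted
# (bond-order, neighbor-id) list. All arithmetic stays below 2^53 so the
# hash is exactly reproducible in double precision.

.fp_hash_mix <- function(h, v) {
  ((h * 1000003) %% 2147483647 + v) %% 2147483647
}

.element_code <- function(el) match(el, .ELEMENTS)

#' Circular fingerprint of a molecule
#'
#' @param record a valid `molecule_record`.
#' @param nbits fingerprint length (default 2048).
#' @param radius neighborhood radius (default 2, ECFP4-equivalent
#'   diameter 4).
#' @return integer vector of 0/1 of length `nbits`.
#' @export
fingerprint <- function(record, nbits = 2048L, radius = 2L) {
  stopifnot(inherits(record, "molecule_record"))
  if (!isTRUE(record$valid)) stop("cannot fingerprint an invalid record")
  mol <- record$mol
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  hs <- implicit_h(mol)
  deg <- heavy_degree(mol)
  rbf <- ring_bond_flags(mol)
  in_ring <- rep(FALSE, n)
  if (n_bonds(mol)) in_ring[unique(c(mol$bonds$a[rbf], mol$bonds$b[rbf]))] <- TRUE

  ids <- vapply(seq_len(n), function(i) {
    h <- 0
    h <- .fp_hash_mix(h, .element_code(mol$atoms$element[i]))
    h <- .fp_hash_mix(h, deg[i])
    h <- .fp_hash_mix(h, hs[i])
    h <- .fp_hash_mix(h, mol$atoms$charge[i] + 8)
    h <- .fp_hash_mix(h, as.integer(mol$atoms$aromatic[i]))
    .fp_hash_mix(h, as.integer(in_ring[i]))
  }, 0)

  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(i) {
      h <- .fp_hash_mix(0, r)
      h <- .fp_hash_mix(h, ids[i])
      nb <- adj[[i]]
      if (!is.null(nb)) {
        ords <- mol$bonds$order[nb[, 2L]]
        ords[mol$bonds$aromatic[nb[, 2L]]] <- 1.5
        pair <- ords * 2147483647 + ids[nb[, 1L]]
        for (p in sort(pair)) {
          h <- .fp_hash_mix(h, p %% 2147483647)
          h <- .fp_hash_mix(h, p %/% 2147483647)
        }
      }
      h
    }, 0)
    ids <- new_ids
    all_ids <- c(all_ids, new_ids)
  }

  bits <- integer(nbits)
  bits[(all_ids %% nbits) + 1L] <- 1L
  bits
}

#' Tanimoto similarity between two bit vectors
#'
#' `|A and B| / (|A| + |B| - |A and B|)` on set bits. The degenerate case of
#' two all-zero fingerprints is defined as 1.0 with a warning.
#'
#' @param a,b equal-length 0/1 vectors (or valid `molecule_record`s, which
#'   are fingerprinted first).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (inherits(a, "molecule_record")) a <- fingerprint(a)
  if (inherits(b, "molecule_record")) b <- fingerprint(b)
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  union <- sum(a) + sum(b) - inter
  if (union == 0) {
    warning("both fingerprints empty; Tanimoto defined as 1")
    return(1)
  }
  inter / union
}
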