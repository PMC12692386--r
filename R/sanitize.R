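# Sanitization: the chemistry-aware validation pass that defines "validity"
# for the whole benchmark. It mirrors the usual full-sanitization pipeline:
# syntax (done by the parser), ring-closure bookkeeping, kekulization of
# aromatic input, valence checking against the standard valence table, and
# aromaticity perception on the kekulized graph so that aromatic and Kekule
# writings of the same ring normalize identically.

# number of double bonds an aromatic atom must receive during kekulization
.kekule_needs <- function(mol, i, arom_atoms) {
  el <- mol$atoms$element[i]
  deg <- heavy_degree(mol)[i]
  hc <- mol$atoms$hcount[i]
  chg <- mol$atoms$charge[i]
  # an existing fixed double/triple bond (non-aromatic) saturates the atom
  inc <- (mol$bonds$a == i | mol$bonds$b == i) & !mol$bonds$aromatic
  if (any(inc) && any(mol$bonds$order[inc] >= 2)) return(0L)
  if (el == "C") {
    if (chg != 0) return(0L)
    return(1L)
  }
  if (el == "N") {
    if (!is.na(hc) && hc >= 1L) return(0L)      # pyrrole-type [nH]
    if (chg == -1L) return(0L)
    if (chg == 1L) return(1L)                   # pyridinium-type [n+]
    if (deg >= 3L) return(0L)                   # substituted pyrrole-type n
    return(1L)                                  # pyridine-type n
  }
  if (el %in% c("O", "S")) return(0L)           # furan/thiophene-type
  if (el == "B") return(0L)
  0L
}

# assign single/double orders to aromatic (order 1.5) bonds via backtracking
# perfect matching on the atoms that require one double bond each
kekulize_mol <- function(mol, forbid_double = integer()) {
  ab <- which(mol$bonds$aromatic & abs(mol$bonds$order - 1.5) < 1e-9)
  if (!length(ab)) return(list(mol = mol))
  arom_atoms <- sort(unique(c(mol$bonds$a[ab], mol$bonds$b[ab])))

  # aromatic bonds must sit in rings
  rbf <- ring_bond_flags(mol)
  if (!all(rbf[ab])) {
    return(list(error = "kekulize",
                message = "aromatic bond outside of any ring"))
  }

  needs <- integer(n_atoms(mol))
  for (i in arom_atoms) needs[i] <- .kekule_needs(mol, i, arom_atoms)

  needy <- arom_atoms[needs[arom_atoms] == 1L]
  # candidate double bonds: aromatic bonds joining two needy atoms
  cand <- ab[mol$bonds$a[ab] %in% needy & mol$bonds$b[ab] %in% needy]
  cand <- setdiff(cand, forbid_double)

  assigned <- logical(length(cand))
  satisfied <- logical(n_atoms(mol))

  ok <- kekule_search(mol, needy, cand, satisfied, 1L)
  if (is.null(ok)) {
    if (length(forbid_double)) {
      return(list(error = "kekulize",
                  message = "no Kekule assignment avoiding constrained bonds"))
    }
    return(list(error = "kekulize",
                message = "no valid Kekule structure for aromatic system"))
  }
  mol$bonds$order[ab] <- 1
  mol$bonds$order[ok] <- 2
  list(mol = mol)
}

# depth-first matching: pick the first unsatisfied needy atom, try each
# incident candidate bond whose partner is also unsatisfied
kekule_search <- function(mol, needy, cand, satisfied, depth) {
  open <- needy[!satisfied[needy]]
  if (!length(open)) return(integer())
  v <- open[1]
  inc <- cand[(mol$bonds$a[cand] == v | mol$bonds$b[cand] == v)]
  for (k in inc) {
    w <- if (mol$bonds$a[k] == v) mol$bonds$b[k] else mol$bonds$a[k]
    if (satisfied[w]) next
    sat2 <- satisfied
    sat2[c(v, w)] <- TRUE
    rest <- kekule_search(mol, needy, cand, sat2, depth + 1L)
    if (!is.null(rest)) return(c(k, rest))
  }
  NULL
}

# valence check on a kekulized graph; returns NULL when fine, else a message
check_valence <- function(mol) {
  bos <- bond_order_sum(mol)
  if (any(abs(bos - round(bos)) > 1e-9)) {
    return("unresolved aromatic bond order")
  }
  for (i in seq_len(n_atoms(mol))) {
    el <- mol$atoms$element[i]
    allowed <- .charged_valences(el, mol$atoms$charge[i])
    if (is.null(allowed)) {
      return(sprintf("unsupported charge state %+d on %s", mol$atoms$charge[i], el))
    }
    hc <- mol$atoms$hcount[i]
    if (!is.na(hc)) {
      tot <- bos[i] + hc
      if (!any(abs(allowed - tot) < 1e-9)) {
        return(sprintf("atom %d (%s) total valence %g not in {%s}",
                       i, el, tot, paste(allowed, collapse = ",")))
      }
    } else if (bos[i] > max(allowed) + 1e-9) {
      return(sprintf("atom %d (%s) bond order sum %g exceeds maximum valence %g",
                     i, el, bos[i], max(allowed)))
    }
  }
  NULL
}

# aromaticity perception on a kekulized, valence-checked graph.
# A candidate ring (size 5-7) is aromatic when every member is sp2-eligible
# and the Hueckel pi count is 4n+2. Contributions: 1 for an atom with a
# double bond to another in-ring atom (or, in fused systems, to an atom of
# an adjacent ring), 2 for a lone-pair heteroatom (N/O/S with only single
# bonds), otherwise the ring is rejected.
perceive_aromaticity <- function(mol) {
  mol$atoms$aromatic <- rep(FALSE, n_atoms(mol))
  mol$bonds$aromatic <- rep(FALSE, n_bonds(mol))
  if (n_bonds(mol) == 0L) return(mol)
  rings <- find_rings(mol, max_size = 7L)
  if (!length(rings)) return(mol)
  ring_atoms_all <- unique(unlist(rings))
  is_dbl <- abs(mol$bonds$order - 2) < 1e-9
  is_tri <- abs(mol$bonds$order - 3) < 1e-9

  for (ring in rings) {
    if (length(ring) < 5L || length(ring) > 7L) next
    pi <- 0L
    ok <- TRUE
    for (i in ring) {
      el <- mol$atoms$element[i]
      inc <- mol$bonds$a == i | mol$bonds$b == i
      di <- which(inc & is_dbl)
      if (length(di)) {
        partners <- ifelse(mol$bonds$a[di] == i, mol$bonds$b[di], mol$bonds$a[di])
        if (any(partners %in% ring)) pi <- pi + 1L
        else if (any(partners %in% ring_atoms_all)) pi <- pi + 1L # fused
        else { ok <- FALSE; break }                               # exocyclic C=O etc.
      } else if (el %in% c("N", "O", "S") && mol$atoms$charge[i] <= 0L) {
        pi <- pi + 2L
      } else if (el == "C" && mol$atoms$charge[i] == -1L) {
        pi <- pi + 2L
      } else {
        ok <- FALSE; break
      }
      if (any(inc & is_tri)) { ok <- FALSE; break }
    }
    if (ok && pi %in% c(2L, 6L, 10L)) {
      mol$atoms$aromatic[ring] <- TRUE
      nr <- length(ring)
      for (j in seq_len(nr)) {
        a <- ring[j]; b <- ring[if (j == nr) 1L else j + 1L]
        bd <- find_bond(mol, a, b)
        if (!is.na(bd)) mol$bonds$aromatic[bd] <- TRUE
      }
    }
  }
  mol
}

# full sanitization of a parsed graph; returns list(mol=) or list(error=,message=)
sanitize_mol <- function(mol) {
  if (n_atoms(mol) == 0L) {
    return(list(error = "empty-input", message = "no atoms"))
  }
  kk <- kekulize_mol(mol)
  if (!is.null(kk$error)) return(kk)
  mol <- kk$mol
  vmsg <- check_valence(mol)
  if (!is.null(vmsg)) return(list(error = "valence", message = vmsg))
  mol <- perceive_aromaticity(mol)
  mol$atoms$hcount <- rep(NA_integer_, n_atoms(mol)) # implicit H from here on
  list(mol = mol)
}

#' Parse and sanitize a SMILES string into a molecule record
#'
#' Attempts to parse a SMILES string and run full sanitization (syntax,
#' ring-closure bookkeeping, kekulization, valence check against the
#' standard valence table, aromaticity perception). Molecules that cannot
#' be sanitized are labeled invalid; this uniform external check is the
#' validity verdict used for every mutation operator in the benchmark.
#' The function never raises on malformed input.
#'
#' @param smiles SMILES string (possibly malformed).
#' @param id identifier carried through the benchmark; defaults to `"m1"`.
#' @return an object of class `molecule_record` with fields `id`,
#'   `smiles_input`, `smiles_canonical` (NA when invalid), `valid`,
#'   `error` (category string, NA when valid) and the internal graph.
#'   Error categories include `syntax`, `unclosed-ring`, `valence`,
#'   `kekulize` and `empty-input`.
#' @examples
#' parse_and_sanitize("CCO")$valid             # TRUE
#' parse_and_sanitize("C1CC")$error            # "unclosed-ring"
#' parse_and_sanitize("C(C)(C)(C)(C)C")$error  # "valence"
#' @export
parse_and_sanitize <- function(smiles, id = "m1") {
  fail <- function(cat, msg) {
    structure(list(id = id, smiles_input = as.character(smiles)[1],
                   smiles_canonical = NA_character_, valid = FALSE,
                   error = cat, error_message = msg, mol = NULL),
              class = "molecule_record")
  }
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    return(fail("syntax", "input is not a single string"))
  }
  p <- parse_smiles_graph(smiles)
  if (!is.null(p$error)) return(fail(p$error, p$message))
  s <- tryCatch(sanitize_mol(p$mol), error = function(e) {
    list(error = "sanitize", message = conditionMessage(e))
  })
  if (!is.null(s$error)) return(fail(s$error, s$message))
  can <- tryCatch(write_canonical_smiles(s$mol), error = function(e) NULL)
  if (is.null(can)) return(fail("canonicalize", "canonical writer failed"))
  structure(list(id = id, smiles_input = smiles, smiles_canonical = can,
                 valid = TRUE, error = NA_character_,
                 error_message = NA_character_, mol = s$mol),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<molecule_record %s> valid: %s\n", x$id, x$smiles_canonical))
  } else {
    cat(sprintf("<molecule_record %s> INVALID (%s): %s\n", x$id, x$error,
                x$smiles_input))
  }
  invisible(x)
}

#' Canonicalize a valid molecule record
#'
#' Returns the canonical SMILES of a valid record. Canonicalization is
#' idempotent and invariant to atom reordering of the input writing.
#'
#' @param record a valid `molecule_record`.
#' @return canonical SMILES string.
#' @export
canonicalize <- function(record) {
  stopifnot(inherits(record, "molecule_record"))
  if (!isTRUE(record$valid)) {
    stop("cannot canonicalize an invalid molecule record (", record$error, ")")
  }
  record$smiles_canonical
}
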