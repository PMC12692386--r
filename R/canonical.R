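# Canonical SMILES writer. Atom ranks come from iterative Morgan-style
# refinement of local invariants (element, aromaticity, heavy degree,
# charge, implicit H, ring membership) with neighbor-rank multisets; the
# writer then walks the graph depth-first in rank order. Remaining ties
# after refinement correspond to (near-)automorphic atoms, so the emitted
# string is invariant to how the input writing ordered its atoms.
# Stereochemistry is not represented: stereo marks are parsed and dropped.

canonical_ranks <- function(mol) {
  n <- n_atoms(mol)
  if (n == 1L) return(1L)
  adj <- adjacency(mol)
  hs <- implicit_h(mol)
  deg <- heavy_degree(mol)
  rbf <- ring_bond_flags(mol)
  in_ring <- rep(FALSE, n)
  if (n_bonds(mol)) {
    in_ring[unique(c(mol$bonds$a[rbf], mol$bonds$b[rbf]))] <- TRUE
  }
  key <- sprintf("%s|%d|%d|%+d|%d|%d",
                 mol$atoms$element, as.integer(mol$atoms$aromatic),
                 deg, mol$atoms$charge, hs, as.integer(in_ring))
  rank <- match(key, sort(unique(key)))

  refine <- function(rank) {
    repeat {
      key <- vapply(seq_len(n), function(i) {
        nb <- adj[[i]]
        nbr_part <- if (length(nb)) {
          ords <- mol$bonds$order[nb[, "bond"]]
          arom <- mol$bonds$aromatic[nb[, "bond"]]
          ords[arom] <- 1.5
          parts <- sprintf("%s:%g", rank[nb[, "nbr"]], ords)
          paste(sort(parts), collapse = ",")
        } else ""
        sprintf("%05d|%s", rank[i], nbr_part)
      }, "")
      new_rank <- match(key, sort(unique(key)))
      if (length(unique(new_rank)) == length(unique(rank))) return(new_rank)
      rank <- new_rank
    }
  }

  rank <- refine(rank)
  while (length(unique(rank)) < n) {
    # break the lowest tied class deterministically and re-refine
    tab <- table(rank)
    tied <- as.integer(names(tab)[tab > 1])
    cls <- min(tied)
    members <- which(rank == cls)
    rank <- rank * 2L
    rank[members[1]] <- rank[members[1]] - 1L
    rank <- match(rank, sort(unique(rank)))
    rank <- refine(rank)
  }
  rank
}

atom_symbol_out <- function(mol, i, hs) {
  el <- mol$atoms$element[i]
  arom <- mol$atoms$aromatic[i]
  chg <- mol$atoms$charge[i]
  sym <- if (arom) tolower(el) else el
  organic <- el %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
  needs_bracket <- chg != 0L || !organic ||
    (arom && el %in% c("N", "P") && hs[i] > 0L)
  if (!needs_bracket) return(sym)
  h <- if (hs[i] == 0L) "" else if (hs[i] == 1L) "H" else paste0("H", hs[i])
  c_str <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
  else sprintf("%+d", chg)
  paste0("[", sym, h, c_str, "]")
}

bond_symbol_out <- function(mol, k, from, to) {
  if (mol$bonds$aromatic[k]) return("")
  o <- mol$bonds$order[k]
  if (abs(o - 2) < 1e-9) return("=")
  if (abs(o - 3) < 1e-9) return("#")
  # explicit single needed between two aromatic atoms (e.g. biaryl link)
  if (mol$atoms$aromatic[from] && mol$atoms$aromatic[to]) return("-")
  ""
}

# write canonical SMILES for a sanitized molgraph (multi-fragment joined
# with "."); deterministic given the graph
write_canonical_smiles <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return("")
  rank <- canonical_ranks(mol)
  adj <- adjacency(mol)
  hs <- implicit_h(mol)
  comp <- components(mol)

  frag_strings <- character(0)

  for (cid in sort(unique(comp))) {
    atoms_c <- which(comp == cid)
    start <- atoms_c[order(rank[atoms_c])][1]
    # Two-pass: first determine the DFS tree and ring-closure edges, then
    # assign digits so both endpoints print them.
    parent_bond_of <- rep(NA_integer_, n)
    order_visited <- integer(0)
    tree_children <- vector("list", n)
    ring_edges <- list()
    seen <- rep(FALSE, n)
    dfs <- function(v, pb) {
      seen[v] <<- TRUE
      parent_bond_of[v] <<- pb
      order_visited <<- c(order_visited, v)
      nb <- adj[[v]]
      if (length(nb)) {
        for (j in order(rank[nb[, "nbr"]])) {
          w <- nb[j, "nbr"]; bk <- nb[j, "bond"]
          if (!is.na(pb) && bk == pb) next
          if (seen[w]) {
            key <- paste0(min(v, w), ".", max(v, w), ".", bk)
            if (!key %in% names(ring_edges)) {
              ring_edges[[key]] <<- c(a = unname(w), b = unname(v),
                                      bond = unname(bk))
            }
          } else {
            tree_children[[v]] <<- c(tree_children[[v]], list(c(w, bk)))
            dfs(w, bk)
          }
        }
      }
    }
    dfs(start, NA_integer_)

    # digit assignment: in visitation order of the closing endpoint
    digits_at <- vector("list", n)
    digit_free <- rep(TRUE, 99)
    open_digit <- list()
    pos <- match(seq_len(n), order_visited)
    if (length(ring_edges)) {
      # order ring edges by position of their later endpoint, then earlier
      res <- do.call(rbind, ring_edges)
      later <- pmax(pos[res[, "a"]], pos[res[, "b"]])
      earlier <- pmin(pos[res[, "a"]], pos[res[, "b"]])
      eord <- order(earlier, later)
      # simple scheme: assign digits in order of opening; free on closing
      events <- data.frame(
        a = res[eord, "a"], b = res[eord, "b"], bond = res[eord, "bond"],
        open = earlier[eord], close = later[eord]
      )
      # process openings in DFS position order
      for (r in seq_len(nrow(events))) {
        d <- which(digit_free)[1]
        digit_free[d] <- FALSE
        ev <- events[r, ]
        av <- order_visited[ev$open]; bv <- order_visited[ev$close]
        bs <- bond_symbol_out(mol, ev$bond, av, bv)
        dtxt <- if (d <= 9) as.character(d) else sprintf("%%%02d", d)
        digits_at[[av]] <- c(digits_at[[av]], paste0(bs, dtxt))
        digits_at[[bv]] <- c(digits_at[[bv]], paste0(bs, dtxt))
      }
    }

    build <- function(v) {
      s <- paste0(atom_symbol_out(mol, v, hs),
                  paste(digits_at[[v]], collapse = ""))
      kids <- tree_children[[v]]
      if (length(kids)) {
        for (j in seq_along(kids)) {
          w <- kids[[j]][1]; bk <- kids[[j]][2]
          bs <- bond_symbol_out(mol, bk, v, w)
          sub <- paste0(bs, build(w))
          if (j < length(kids)) s <- paste0(s, "(", sub, ")")
          else s <- paste0(s, sub)
        }
      }
      s
    }
    frag_strings <- c(frag_strings, build(start))
  }
  paste(frag_strings, collapse = ".")
}
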