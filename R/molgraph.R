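#' @name molgraph
#' @title Internal molecular graph container
#'
#' @description
#' Molecules are held as a light-weight adjacency structure: parallel
#' vectors of heavy atoms (element, aromatic flag, formal charge, explicit
#' H count when a bracket atom pinned it) and of bonds (endpoint indices,
#' kekulized numeric order, aromatic flag). Hydrogens are implicit
#' throughout; `implicit_h()` recovers them from the valence table.
#'
#' All mutation operators, descriptors and indices in the package operate on
#' this container; SMILES strings are only the interchange format.
#' @keywords internal
NULL

new_mol <- function(element = character(), aromatic = logical(),
                    charge = integer(), hcount = integer(),
                    bond_a = integer(), bond_b = integer(),
                    bond_order = numeric(), bond_aromatic = logical()) {
  structure(list(
    atoms = list(
      element = as.character(element),
      aromatic = as.logical(aromatic),
      charge = as.integer(charge),
      hcount = as.integer(hcount)   # NA = implicit
    ),
    bonds = list(
      a = as.integer(bond_a), b = as.integer(bond_b),
      order = as.numeric(bond_order),
      aromatic = as.logical(bond_aromatic)
    )
  ), class = "molgraph")
}

n_atoms <- function(mol) length(mol$atoms$element)
n_bonds <- function(mol) length(mol$bonds$a)

# adjacency list: per atom a 2-column matrix of (neighbor, bond row)
adjacency <- function(mol) {
  n <- n_atoms(mol)
  m <- n_bonds(mol)
  adj <- vector("list", n)
  if (m == 0L) return(adj)
  ends <- c(mol$bonds$a, mol$bonds$b)
  other <- c(mol$bonds$b, mol$bonds$a)
  brow <- rep.int(seq_len(m), 2L)
  o <- order(ends)
  ends <- ends[o]; other <- other[o]; brow <- brow[o]
  cuts <- c(0L, cumsum(tabulate(ends, n)))
  for (i in seq_len(n)) {
    if (cuts[i + 1L] > cuts[i]) {
      k <- (cuts[i] + 1L):cuts[i + 1L]
      adj[[i]] <- cbind(nbr = other[k], bond = brow[k])
    }
  }
  adj
}

bond_order_sum <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  m <- n_bonds(mol)
  if (m > 0L) {
    for (k in seq_len(m)) {
      o <- mol$bonds$order[k]
      s[mol$bonds$a[k]] <- s[mol$bonds$a[k]] + o
      s[mol$bonds$b[k]] <- s[mol$bonds$b[k]] + o
    }
  }
  s
}

heavy_degree <- function(mol) {
  n <- n_atoms(mol)
  if (n_bonds(mol) == 0L) return(integer(n))
  tabulate(mol$bonds$a, n) + tabulate(mol$bonds$b, n)
}

# implicit hydrogen count per atom (assumes valence checking passed);
# atoms with an explicit bracket H count keep it
implicit_h <- function(mol) {
  bos <- bond_order_sum(mol)
  n <- n_atoms(mol)
  h <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(mol$atoms$hcount[i])) {
      h[i] <- mol$atoms$hcount[i]
      next
    }
    allowed <- .charged_valences(mol$atoms$element[i], mol$atoms$charge[i])
    if (is.null(allowed)) { h[i] <- 0L; next }
    v <- allowed[allowed >= bos[i] - 1e-9]
    h[i] <- if (length(v)) as.integer(round(v[1] - bos[i])) else 0L
  }
  h
}

# remaining bonding capacity before the maximum allowed valence is exceeded
free_valence <- function(mol) {
  bos <- bond_order_sum(mol)
  hc <- ifelse(is.na(mol$atoms$hcount), 0L, mol$atoms$hcount)
  n <- n_atoms(mol)
  fv <- numeric(n)
  for (i in seq_len(n)) {
    allowed <- .charged_valences(mol$atoms$element[i], mol$atoms$charge[i])
    if (is.null(allowed)) { fv[i] <- 0; next }
    fv[i] <- max(allowed) - bos[i] - hc[i]
  }
  pmax(fv, 0)
}

components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  if (n == 0L) return(comp)
  adj <- adjacency(mol)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    stack <- s
    comp[s] <- cid
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[v]]
      if (!is.null(nb)) {
        nxt <- nb[, 1L][comp[nb[, 1L]] == 0L]
        comp[nxt] <- cid
        stack <- c(stack, nxt)
      }
    }
  }
  comp
}

bfs_dist <- function(adj, from, n) {
  d <- rep(Inf, n)
  d[from] <- 0
  head <- 1L
  queue <- integer(n)
  queue[1L] <- from
  tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    nb <- adj[[v]]
    if (!is.null(nb)) {
      for (w in nb[, 1L]) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          tail <- tail + 1L
          queue[tail] <- w
        }
      }
    }
  }
  d
}

# ring-bond flags via bridge detection (a bond is a ring bond iff it is not
# a bridge); iterative DFS low-link
ring_bond_flags <- function(mol) {
  n <- n_atoms(mol)
  m <- n_bonds(mol)
  if (m == 0L) return(logical(0))
  adj <- adjacency(mol)
  disc <- integer(n); low <- integer(n)
  is_bridge <- logical(m)
  timer <- 0L
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    # stack frames: (vertex, parent bond, next neighbor index)
    sv <- root; sb <- NA_integer_; si <- 1L
    timer <- timer + 1L
    disc[root] <- low[root] <- timer
    stack_v <- c(root); stack_b <- c(NA_integer_); stack_i <- c(1L)
    while (length(stack_v)) {
      top <- length(stack_v)
      v <- stack_v[top]
      nb <- adj[[v]]
      i <- stack_i[top]
      if (is.null(nb) || i > nrow(nb)) {
        # retreat
        pb <- stack_b[top]
        stack_v <- stack_v[-top]; stack_b <- stack_b[-top]; stack_i <- stack_i[-top]
        if (length(stack_v)) {
          p <- stack_v[length(stack_v)]
          if (low[v] < low[p]) low[p] <- low[v]
          if (low[v] > disc[p]) is_bridge[pb] <- TRUE
        }
        next
      }
      stack_i[top] <- i + 1L
      w <- nb[i, 1L]; bk <- nb[i, 2L]
      if (!is.na(stack_b[top]) && bk == stack_b[top]) next
      if (disc[w] == 0L) {
        timer <- timer + 1L
        disc[w] <- low[w] <- timer
        stack_v <- c(stack_v, w); stack_b <- c(stack_b, bk); stack_i <- c(stack_i, 1L)
      } else {
        if (disc[w] < low[v]) low[v] <- disc[w]
      }
    }
  }
  !is_bridge
}

# one shortest cycle through each ring bond, deduplicated; adequate as an
# SSSR stand-in for the ring systems handled here
find_rings <- function(mol, max_size = 12L) {
  m <- n_bonds(mol)
  if (m == 0L) return(list())
  rb <- ring_bond_flags(mol)
  if (!any(rb)) return(list())
  adj <- adjacency(mol)
  n <- n_atoms(mol)
  rings <- list()
  keys <- character(0)
  for (k in which(rb)) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    path <- shortest_path_avoiding(adj, a, b, k, n)
    if (is.null(path) || length(path) > max_size) next
    key <- paste(sort(path), collapse = "-")
    if (!key %in% keys) {
      keys <- c(keys, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

shortest_path_avoiding <- function(adj, from, to, avoid_bond, n) {
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  seen[from] <- TRUE
  queue <- integer(n); queue[1L] <- from
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (j in seq_len(nrow(nb))) {
      if (nb[j, 2L] == avoid_bond) next
      w <- nb[j, 1L]
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        if (w == to) {
          path <- w
          while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
          return(path)
        }
        tail <- tail + 1L
        queue[tail] <- w
      }
    }
  }
  NULL
}

ring_count <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(0L)
  as.integer(n_bonds(mol) - n + length(unique(components(mol))))
}

add_atom_ <- function(mol, element, aromatic = FALSE, charge = 0L,
                      hcount = NA_integer_) {
  mol$atoms$element <- c(mol$atoms$element, element)
  mol$atoms$aromatic <- c(mol$atoms$aromatic, aromatic)
  mol$atoms$charge <- c(mol$atoms$charge, as.integer(charge))
  mol$atoms$hcount <- c(mol$atoms$hcount, as.integer(hcount))
  mol
}

add_bond_ <- function(mol, a, b, order = 1, aromatic = FALSE) {
  mol$bonds$a <- c(mol$bonds$a, as.integer(a))
  mol$bonds$b <- c(mol$bonds$b, as.integer(b))
  mol$bonds$order <- c(mol$bonds$order, as.numeric(order))
  mol$bonds$aromatic <- c(mol$bonds$aromatic, aromatic)
  mol
}

remove_atoms_ <- function(mol, idx) {
  keep <- setdiff(seq_len(n_atoms(mol)), idx)
  map <- integer(n_atoms(mol))
  map[keep] <- seq_along(keep)
  bkeep <- mol$bonds$a %in% keep & mol$bonds$b %in% keep
  mol$atoms <- lapply(mol$atoms, `[`, keep)
  mol$bonds <- lapply(mol$bonds, `[`, bkeep)
  mol$bonds$a <- map[mol$bonds$a]
  mol$bonds$b <- map[mol$bonds$b]
  class(mol) <- "molgraph"
  mol
}

remove_bonds_ <- function(mol, bidx) {
  keep <- setdiff(seq_len(n_bonds(mol)), bidx)
  mol$bonds <- lapply(mol$bonds, `[`, keep)
  mol
}

keep_largest_fragment <- function(mol) {
  comp <- components(mol)
  if (length(unique(comp)) <= 1L) return(mol)
  sizes <- table(comp)
  best <- as.integer(names(sizes)[which.max(sizes)])
  remove_atoms_(mol, which(comp != best))
}

find_bond <- function(mol, a, b) {
  hit <- which((mol$bonds$a == a & mol$bonds$b == b) |
                 (mol$bonds$a == b & mol$bonds$b == a))
  if (length(hit)) hit[1] else NA_integer_
}
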