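# Restricted SELFIES codec over the benchmark's 15-token alphabet:
#   [epsilon] [Ring1] [Ring2] [Branch1_1] [Branch1_2] [Branch1_3]
#   [F] [O] [=O] [N] [=N] [#N] [C] [=C] [#C]
# The decoder is a derivation automaton that tracks the remaining bonding
# capacity of every atom: requested bond orders are clamped to what the
# valence table allows, branch/ring payloads are read through single-token
# indices, and over-long or dangling arguments are consumed harmlessly.
# By construction every token sequence decodes to a molecule that passes
# full sanitization (the empty sequence decodes to the empty string).

.selfies_token_info <- function(tok) {
  if (tok == "[epsilon]") return(list(kind = "epsilon"))
  if (tok == "[Ring1]") return(list(kind = "ring", size = 1L))
  if (tok == "[Ring2]") return(list(kind = "ring", size = 2L))
  m <- regmatches(tok, regexec("^\\[Branch1_([123])\\]$", tok))[[1]]
  if (length(m)) return(list(kind = "branch", order = as.integer(m[2])))
  m <- regmatches(tok, regexec("^\\[([=#]?)([A-Z][a-z]?)\\]$", tok))[[1]]
  if (length(m) && .is_known_element(m[3])) {
    q <- switch(m[2], "=" = 2L, "#" = 3L, 1L)
    return(list(kind = "atom", element = m[3], order = q))
  }
  list(kind = "unknown")
}

# numeric index of a token (0-based position in the default SELFIES
# alphabet; unknown tokens index as 0); used for branch lengths and ring
# reach
.selfies_index <- function(tok, symbols) {
  i <- match(tok, symbols)
  if (is.na(i)) 0L else i - 1L
}

#' Decode a SELFIES token sequence into a SMILES string
#'
#' Derives a molecular graph from the token sequence under valence
#' constraints, so any sequence over the SELFIES alphabet yields a
#' sanitizable molecule. The empty sequence (or a sequence deriving no
#' atoms) yields the empty string, which downstream validity checking
#' classifies as `empty-input`.
#'
#' @param seq a `token_sequence` of kind `"SELFIES"` (or a character vector
#'   of bracketed tokens).
#' @return a SMILES string (possibly `""`).
#' @examples
#' decode_selfies(token_sequence("SELFIES", c("[C]", "[C]", "[O]")))
#' @export
decode_selfies <- function(seq) {
  tokens <- if (inherits(seq, "token_sequence")) seq$tokens else as.character(seq)
  if (!length(tokens)) return("")
  symbols <- default_alphabet("SELFIES")$symbols
  base <- length(symbols)

  env <- new.env(parent = emptyenv())
  env$element <- character()
  env$capacity <- integer()
  env$ba <- integer(); env$bb <- integer(); env$bo <- integer()

  maxval <- function(el) max(.DEFAULT_VALENCE[[el]])

  derive <- function(tokens, parent, max_first_bond) {
    cur <- parent
    first <- TRUE
    i <- 1L
    nT <- length(tokens)
    while (i <= nT) {
      info <- .selfies_token_info(tokens[i])
      if (info$kind == "atom") {
        if (cur == 0L) {
          env$element <- c(env$element, info$element)
          env$capacity <- c(env$capacity, maxval(info$element))
          cur <- length(env$element)
          first <- FALSE
        } else {
          if (env$capacity[cur] <= 0L) break
          v <- maxval(info$element)
          b <- min(info$order, env$capacity[cur], v)
          if (first) b <- min(b, max_first_bond)
          env$element <- c(env$element, info$element)
          env$capacity <- c(env$capacity, v - b)
          new <- length(env$element)
          env$ba <- c(env$ba, cur); env$bb <- c(env$bb, new)
          env$bo <- c(env$bo, b)
          env$capacity[cur] <- env$capacity[cur] - b
          cur <- new
          first <- FALSE
        }
        i <- i + 1L
      } else if (info$kind == "epsilon") {
        break
      } else if (info$kind == "branch") {
        if (i + 1L > nT) break
        Q <- .selfies_index(tokens[i + 1L], symbols)
        L <- Q + 1L
        to <- min(nT, i + 1L + L)
        payload <- if (i + 2L <= to) tokens[(i + 2L):to] else character()
        if (cur != 0L && env$capacity[cur] > 0L && length(payload)) {
          derive(payload, cur, info$order)
        }
        i <- to + 1L
      } else if (info$kind == "ring") {
        need <- info$size
        if (i + need > nT) break
        if (need == 1L) {
          N <- .selfies_index(tokens[i + 1L], symbols) + 1L
        } else {
          N <- .selfies_index(tokens[i + 1L], symbols) * base +
            .selfies_index(tokens[i + 2L], symbols) + 1L
        }
        if (cur != 0L) {
          target <- max(1L, cur - N)
          dup <- any((env$ba == cur & env$bb == target) |
                       (env$ba == target & env$bb == cur))
          if (target != cur && !dup &&
              env$capacity[cur] >= 1L && env$capacity[target] >= 1L) {
            env$ba <- c(env$ba, target); env$bb <- c(env$bb, cur)
            env$bo <- c(env$bo, 1L)
            env$capacity[cur] <- env$capacity[cur] - 1L
            env$capacity[target] <- env$capacity[target] - 1L
          }
        }
        i <- i + need + 1L
      } else {
        i <- i + 1L # unknown token: ignored
      }
    }
    invisible(NULL)
  }

  derive(tokens, 0L, 3L)
  if (!length(env$element)) return("")
  mol <- new_mol(env$element, rep(FALSE, length(env$element)),
                 rep(0L, length(env$element)),
                 rep(NA_integer_, length(env$element)),
                 env$ba, env$bb, env$bo, rep(FALSE, length(env$ba)))
  s <- sanitize_mol(mol)
  if (!is.null(s$error)) {
    # cannot happen for capacity-tracked derivations; fail loudly if it does
    stop("internal error: derived molecule failed sanitization: ", s$message)
  }
  write_canonical_smiles(s$mol)
}

#' Encode a molecule as a SELFIES token sequence
#'
#' Writes a SELFIES derivation for a sanitizable molecule over the
#' benchmark alphabet chemistry (neutral C/N/O/F atoms, single fragment).
#' Aromatic rings are kekulized with ring-closure bonds constrained to
#' single order, since the alphabet has no higher-order ring token. A
#' molecule that cannot be expressed (other elements, charges, several
#' fragments, a branch needing more than 15 tokens or an unreachable ring
#' closure) raises an error; the SELFIES mutation operator records such
#' parents as operator skips.
#'
#' @param smiles a SMILES string or a valid `molecule_record`.
#' @return a `token_sequence` of kind `"SELFIES"`.
#' @examples
#' s <- encode_selfies("CC(=O)O")
#' decode_selfies(s)
#' @export
encode_selfies <- function(smiles) {
  rec <- if (inherits(smiles, "molecule_record")) smiles
  else parse_and_sanitize(smiles)
  if (!isTRUE(rec$valid)) {
    stop("cannot encode an unsanitizable molecule (", rec$error, ")")
  }
  mol <- rec$mol
  if (!all(mol$atoms$element %in% c("C", "N", "O", "F"))) {
    stop("SELFIES alphabet covers C/N/O/F chemistry only")
  }
  if (any(mol$atoms$charge != 0L)) stop("charged atoms are not encodable")
  if (length(unique(components(mol))) > 1L) {
    stop("multi-fragment molecules are not encodable")
  }

  symbols <- default_alphabet("SELFIES")$symbols
  base <- length(symbols)
  n <- n_atoms(mol)
  adj <- adjacency(mol)

  # a fixed double/triple ring-closure bond depends on where the DFS tree
  # is rooted, so on failure the derivation is retried from other roots
  last_err <- NULL
  for (root in seq_len(n)) {
    out <- tryCatch(.encode_selfies_from(mol, adj, symbols, base, n, root),
                    error = function(e) e)
    if (!inherits(out, "error")) return(out)
    last_err <- out
  }
  stop(conditionMessage(last_err))
}

.encode_selfies_from <- function(mol, adj, symbols, base, n, root) {
  # spanning tree by DFS, preferring high fixed bond orders so that
  # double/triple bonds become tree edges and closures stay single
  parent <- rep(NA_integer_, n)
  parent_bond <- rep(NA_integer_, n)
  children <- vector("list", n)
  closure <- list() # list of c(a=, b=, bond=) per non-tree edge
  seen <- rep(FALSE, n)
  dfs_order <- integer(0)
  dfs <- function(v) {
    seen[v] <<- TRUE
    dfs_order <<- c(dfs_order, v)
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible(NULL))
    ords <- mol$bonds$order[nb[, 2L]]
    ords[mol$bonds$aromatic[nb[, 2L]]] <- 1 # aromatic orders re-assigned later
    for (j in order(-ords, nb[, 1L])) {
      w <- nb[j, 1L]; bk <- nb[j, 2L]
      if (!is.na(parent_bond[v]) && bk == parent_bond[v]) next
      if (seen[w]) {
        key <- paste0(min(v, w), ".", max(v, w))
        if (!key %in% names(closure)) {
          closure[[key]] <<- c(a = unname(w), b = unname(v), bond = unname(bk))
        }
      } else {
        parent[w] <<- v
        parent_bond[w] <<- bk
        children[[v]] <<- c(children[[v]], w)
        dfs(w)
      }
    }
    invisible(NULL)
  }
  dfs(root)

  closure_bonds <- if (length(closure)) {
    vapply(closure, function(x) x[["bond"]], 0L)
  } else integer()

  # re-kekulize aromatic systems keeping closure bonds single; pin the
  # implicit H counts first so pyrrole-type NH keeps its lone pair role
  if (any(mol$bonds$aromatic)) {
    mol$atoms$hcount <- implicit_h(mol)
    mol$bonds$order[mol$bonds$aromatic] <- 1.5
    kk <- kekulize_mol(mol, forbid_double = closure_bonds)
    if (!is.null(kk$error)) {
      stop("no Kekule assignment with single-order ring closures")
    }
    mol <- kk$mol
  }
  if (any(abs(mol$bonds$order[closure_bonds] - 1) > 1e-9)) {
    stop("ring-closure bond of order > 1 is not encodable")
  }

  pos <- match(seq_len(n), dfs_order)
  ord_prefix <- function(o) if (abs(o - 2) < 1e-9) "=" else if (abs(o - 3) < 1e-9) "#" else ""
  index_token <- function(q) {
    if (q < 0L || q >= base) stop("index out of token range")
    symbols[q + 1L]
  }

  emit <- function(v) {
    o <- if (is.na(parent_bond[v])) 1 else mol$bonds$order[parent_bond[v]]
    toks <- sprintf("[%s%s]", ord_prefix(o), mol$atoms$element[v])
    # ring closures ending at v (v is the later endpoint)
    for (cl in closure) {
      late <- if (pos[cl[["a"]]] > pos[cl[["b"]]]) cl[["a"]] else cl[["b"]]
      early <- if (late == cl[["a"]]) cl[["b"]] else cl[["a"]]
      if (late != v) next
      N <- pos[late] - pos[early]
      if (N - 1L < base) {
        toks <- c(toks, "[Ring1]", index_token(N - 1L))
      } else if (N - 1L < base * base) {
        toks <- c(toks, "[Ring2]", index_token((N - 1L) %/% base),
                  index_token((N - 1L) %% base))
      } else stop("ring closure reach exceeds token range")
    }
    kids <- children[[v]] # already ordered smallest subtree first
    if (length(kids)) {
      sub <- lapply(kids, emit)
      nk <- length(kids)
      for (j in seq_len(nk)) {
        if (j < nk) {
          L <- length(sub[[j]])
          if (L > base) stop("branch too long for single-index branch token")
          bo <- mol$bonds$order[parent_bond[kids[j]]]
          k <- as.integer(round(bo))
          toks <- c(toks, sprintf("[Branch1_%d]", k), index_token(L - 1L),
                    sub[[j]])
        } else {
          toks <- c(toks, sub[[j]])
        }
      }
    }
    toks
  }

  # emission must follow creation order used by pos: children reordered by
  # subtree size changes creation order, so recompute positions iteratively
  # until stable (size-based ordering is independent of positions, one pass
  # after reordering suffices)
  reorder_positions <- function() {
    # recompute dfs_order following the smallest-first child ordering
    sizes <- integer(n)
    post <- function(v) {
      s <- 1L
      for (w in children[[v]]) s <- s + post(w)
      sizes[v] <<- s
      s
    }
    post(dfs_order[1])
    for (v in seq_len(n)) {
      kids <- children[[v]]
      if (length(kids) > 1L) children[[v]] <<- kids[order(sizes[kids])]
    }
    new_order <- integer(0)
    pre <- function(v) {
      new_order <<- c(new_order, v)
      for (w in children[[v]]) pre(w)
    }
    pre(dfs_order[1])
    pos <<- match(seq_len(n), new_order)
  }
  reorder_positions()

  token_sequence("SELFIES", emit(dfs_order[1]))
}
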