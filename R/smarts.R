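# Reaction-SMARTS subset engine for the reaction-based mutation operator.
# Supported pattern language: organic-subset atoms (C N O S F Cl Br I,
# aromatic c n o s), bracket atoms with primitives element, exact H count
# (H / H<n>), `!H0` (at least one H), charge (+ - +0 ... with explicit
# zero), `R` / `!R` ring membership and `*` (any atom), plus atom maps
# `:n`; bonds default single-or-aromatic with explicit `- = # : ~`;
# branches, ring-closure digits and `.` component separation; `>>`
# separates reactant and product sides. This covers the packaged
# click-like template set; it is not a general SMARTS implementation.

smarts_tokenize <- function(s) tokenize_smiles(s)$tokens

# parse one pattern atom token -> list of test fields
parse_smarts_atom <- function(tok) {
  at <- list(element = NA_character_, aromatic = NA, hcount = NA_integer_,
             hmin = NA_integer_, charge = NA_integer_, charge_set = FALSE,
             ring = NA, any = FALSE, map = NA_integer_)
  bare <- c("C", "N", "O", "S", "P", "B", "F", "Cl", "Br", "I")
  bare_arom <- c("c", "n", "o", "s", "p", "b")
  if (tok %in% bare) {
    at$element <- tok; at$aromatic <- FALSE
    return(at)
  }
  if (tok %in% bare_arom) {
    at$element <- toupper(tok); at$aromatic <- TRUE
    return(at)
  }
  if (tok == "*") { at$any <- TRUE; return(at) }
  if (!grepl("^\\[.*\\]$", tok)) stop("unsupported SMARTS token: ", tok)
  body <- substr(tok, 2L, nchar(tok) - 1L)
  i <- 1L
  n <- nchar(body)
  neg <- FALSE
  while (i <= n) {
    ch <- substr(body, i, i)
    if (ch == "!") { neg <- TRUE; i <- i + 1L; next }
    if (ch == ";" || ch == "&") { i <- i + 1L; next } # high-precedence AND
    if (ch == "*") { at$any <- TRUE; i <- i + 1L }
    else if (ch == "H") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", substr(body, j, j))) j <- j + 1L
      cnt <- if (j == i + 1L) 1L else as.integer(substr(body, i + 1L, j - 1L))
      if (neg) {
        if (cnt != 0L) stop("only !H0 negation is supported")
        at$hmin <- 1L
        neg <- FALSE
      } else at$hcount <- cnt
      i <- j
    } else if (ch %in% c("+", "-")) {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", substr(body, j, j))) j <- j + 1L
      mag <- if (j == i + 1L) 1L else as.integer(substr(body, i + 1L, j - 1L))
      at$charge <- if (ch == "+") mag else -mag
      at$charge_set <- TRUE
      i <- j
    } else if (ch == "R") {
      at$ring <- !neg
      neg <- FALSE
      i <- i + 1L
    } else if (ch == ":") {
      at$map <- as.integer(substr(body, i + 1L, n))
      break
    } else if (grepl("[A-Z]", ch)) {
      el <- ch
      if (i < n && grepl("[a-z]", substr(body, i + 1L, i + 1L)) &&
          paste0(ch, substr(body, i + 1L, i + 1L)) %in% bare) {
        el <- paste0(ch, substr(body, i + 1L, i + 1L))
        i <- i + 1L
      }
      at$element <- el; at$aromatic <- FALSE
      i <- i + 1L
    } else if (grepl("[a-z]", ch)) {
      at$element <- toupper(ch); at$aromatic <- TRUE
      i <- i + 1L
    } else stop("unsupported SMARTS primitive '", ch, "' in ", tok)
  }
  at
}

# parse one side component list: returns list of components, each
# list(atoms = list of atom tests, bonds = data.frame(a, b, type))
# bond type: "any1" (single-or-aromatic default), "-", "=", "#", ":", "~"
parse_smarts_side <- function(s) {
  comps <- list()
  for (comp in strsplit(s, ".", fixed = TRUE)[[1]]) {
    toks <- smarts_tokenize(comp)
    atoms <- list()
    bonds <- list()
    prev <- 0L
    pending <- NA_character_
    stack <- integer()
    ringmap <- list()
    for (tok in toks) {
      if (tok %in% c("-", "=", "#", ":", "~")) pending <- tok
      else if (tok == "(") stack <- c(stack, prev)
      else if (tok == ")") { prev <- stack[length(stack)]; stack <- stack[-length(stack)] }
      else if (grepl("^[0-9]$", tok)) {
        open <- ringmap[[tok]]
        if (is.null(open)) ringmap[[tok]] <- list(atom = prev, bond = pending)
        else {
          ty <- if (!is.na(open$bond)) open$bond else if (!is.na(pending)) pending else "any1"
          bonds[[length(bonds) + 1L]] <- list(a = open$atom, b = prev, type = ty)
          ringmap[[tok]] <- NULL
        }
        pending <- NA_character_
      } else {
        atoms[[length(atoms) + 1L]] <- parse_smarts_atom(tok)
        idx <- length(atoms)
        if (prev > 0L) {
          ty <- if (is.na(pending)) "any1" else pending
          bonds[[length(bonds) + 1L]] <- list(a = prev, b = idx, type = ty)
        }
        prev <- idx
        pending <- NA_character_
      }
    }
    if (length(ringmap)) stop("unclosed ring index in SMARTS component: ", comp)
    bdf <- if (length(bonds)) {
      data.frame(a = vapply(bonds, function(x) x$a, 0L),
                 b = vapply(bonds, function(x) x$b, 0L),
                 type = vapply(bonds, function(x) x$type, ""))
    } else data.frame(a = integer(), b = integer(), type = character())
    comps[[length(comps) + 1L]] <- list(atoms = atoms, bonds = bdf)
  }
  comps
}

#' Reaction template
#'
#' A named reaction-SMARTS transform whose first reactant component is
#' matched against the parent molecule and whose optional second component
#' is matched against a reagent drawn from the given class of a
#' building-block library. The SMARTS is compiled on construction.
#'
#' @param name template name.
#' @param smarts reaction SMARTS (`reactants>>products`, subset language).
#' @param reagent_class building-block class for the second reactant
#'   component (`NA` for single-reactant templates).
#' @return a `reaction_template`.
#' @export
reaction_template <- function(name, smarts, reagent_class = NA_character_) {
  sides <- strsplit(smarts, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("reaction SMARTS must contain one '>>': ", smarts)
  reactants <- parse_smarts_side(sides[1])
  products <- parse_smarts_side(sides[2])
  if (!length(reactants)) stop("no reactant component in ", smarts)
  if (length(reactants) == 2L && is.na(reagent_class)) {
    stop("two-component template needs a reagent class: ", name)
  }
  structure(list(name = name, smarts = smarts, reagent_class = reagent_class,
                 reactants = reactants, products = products),
            class = "reaction_template")
}

#' @export
print.reaction_template <- function(x, ...) {
  cat(sprintf("<reaction_template %s> %s%s\n", x$name, x$smarts,
              if (is.na(x$reagent_class)) "" else paste0(" [", x$reagent_class, "]")))
  invisible(x)
}

# does target atom i of mol satisfy the pattern atom test?
.smarts_atom_ok <- function(test, mol, i, hs, in_ring) {
  if (test$any) return(TRUE)
  if (!is.na(test$element) && mol$atoms$element[i] != test$element) return(FALSE)
  if (!is.na(test$aromatic) && mol$atoms$aromatic[i] != test$aromatic) return(FALSE)
  if (!is.na(test$hcount) && hs[i] != test$hcount) return(FALSE)
  if (!is.na(test$hmin) && hs[i] < test$hmin) return(FALSE)
  if (test$charge_set && mol$atoms$charge[i] != test$charge) return(FALSE)
  if (!is.na(test$ring) && in_ring[i] != test$ring) return(FALSE)
  TRUE
}

.smarts_bond_ok <- function(type, mol, bk) {
  o <- mol$bonds$order[bk]
  arom <- mol$bonds$aromatic[bk]
  switch(type,
         "any1" = arom || abs(o - 1) < 1e-9,
         "-" = !arom && abs(o - 1) < 1e-9,
         "=" = !arom && abs(o - 2) < 1e-9,
         "#" = abs(o - 3) < 1e-9,
         ":" = arom,
         "~" = TRUE,
         FALSE)
}

# all matches of one pattern component against a molecule; returns a list
# of integer vectors (pattern atom -> molecule atom), up to max_matches
smarts_match <- function(pattern, mol, max_matches = 64L) {
  np <- length(pattern$atoms)
  if (np == 0L || n_atoms(mol) == 0L) return(list())
  hs <- implicit_h(mol)
  rbf <- ring_bond_flags(mol)
  in_ring <- rep(FALSE, n_atoms(mol))
  if (n_bonds(mol)) in_ring[unique(c(mol$bonds$a[rbf], mol$bonds$b[rbf]))] <- TRUE
  # pattern adjacency
  padj <- vector("list", np)
  if (nrow(pattern$bonds)) {
    for (k in seq_len(nrow(pattern$bonds))) {
      a <- pattern$bonds$a[k]; b <- pattern$bonds$b[k]
      padj[[a]] <- rbind(padj[[a]], c(b, k))
      padj[[b]] <- rbind(padj[[b]], c(a, k))
    }
  }
  matches <- list()
  assignment <- integer(np)
  used <- rep(FALSE, n_atoms(mol))
  recurse <- function(pi) {
    if (length(matches) >= max_matches) return(invisible(NULL))
    if (pi > np) {
      matches[[length(matches) + 1L]] <<- assignment
      return(invisible(NULL))
    }
    # candidate molecule atoms: must satisfy atom test and all bonds to
    # already-assigned pattern neighbors
    for (mi in seq_len(n_atoms(mol))) {
      if (used[mi]) next
      if (!.smarts_atom_ok(pattern$atoms[[pi]], mol, mi, hs, in_ring)) next
      ok <- TRUE
      nbs <- padj[[pi]]
      if (!is.null(nbs)) {
        for (r in seq_len(nrow(nbs))) {
          pj <- nbs[r, 1L]
          if (pj < pi) {
            bk <- find_bond(mol, mi, assignment[pj])
            if (is.na(bk) ||
                !.smarts_bond_ok(pattern$bonds$type[nbs[r, 2L]], mol, bk)) {
              ok <- FALSE; break
            }
          }
        }
      }
      if (!ok) next
      assignment[pi] <<- mi
      used[mi] <<- TRUE
      recurse(pi + 1L)
      used[mi] <<- FALSE
    }
    invisible(NULL)
  }
  recurse(1L)
  matches
}

# apply a compiled reaction to parent (+ optional reagent) given matches;
# returns list(mol=) or list(error=, message=)
apply_reaction <- function(template, parent_mol, parent_match,
                           reagent_mol = NULL, reagent_match = NULL) {
  # combined molecule: parent atoms then reagent atoms
  np <- n_atoms(parent_mol)
  mol <- parent_mol
  offset <- np
  if (!is.null(reagent_mol)) {
    mol$atoms <- Map(c, mol$atoms, reagent_mol$atoms)
    mol$bonds <- list(a = c(mol$bonds$a, reagent_mol$bonds$a + offset),
                      b = c(mol$bonds$b, reagent_mol$bonds$b + offset),
                      order = c(mol$bonds$order, reagent_mol$bonds$order),
                      aromatic = c(mol$bonds$aromatic, reagent_mol$bonds$aromatic))
    class(mol) <- "molgraph"
  }

  # gather reactant-side atom assignments: pattern component index ->
  # molecule atom index (combined numbering)
  rx <- template$reactants
  assigns <- list(parent_match)
  if (length(rx) >= 2L) {
    if (is.null(reagent_match)) return(list(error = "no-reagent-match"))
    assigns[[2]] <- reagent_match + offset
  }

  # map id -> combined atom index; also track unmapped reactant atoms
  map_to_atom <- list()
  unmapped_atoms <- integer()
  react_bonds <- list() # mapid pair -> present in reactant side
  for (ci in seq_along(rx)) {
    comp <- rx[[ci]]
    asg <- assigns[[ci]]
    for (ai in seq_along(comp$atoms)) {
      mp <- comp$atoms[[ai]]$map
      if (is.na(mp)) unmapped_atoms <- c(unmapped_atoms, asg[ai])
      else map_to_atom[[as.character(mp)]] <- asg[ai]
    }
    if (nrow(comp$bonds)) {
      for (k in seq_len(nrow(comp$bonds))) {
        m1 <- comp$atoms[[comp$bonds$a[k]]]$map
        m2 <- comp$atoms[[comp$bonds$b[k]]]$map
        if (!is.na(m1) && !is.na(m2)) {
          key <- paste(sort(c(m1, m2)), collapse = "-")
          react_bonds[[key]] <- TRUE
        }
      }
    }
  }

  # product side: collect atoms (mapped survive, unmapped are new) and
  # bonds between product atoms
  prod_atoms <- list() # per product component/atom: combined atom idx
  new_atom_specs <- list()
  pd <- template$products
  # first pass: create new atoms
  for (ci in seq_along(pd)) {
    comp <- pd[[ci]]
    idxs <- integer(length(comp$atoms))
    for (ai in seq_along(comp$atoms)) {
      sp <- comp$atoms[[ai]]
      if (!is.na(sp$map)) {
        tgt <- map_to_atom[[as.character(sp$map)]]
        if (is.null(tgt)) return(list(error = "bad-template",
                                      message = "product map absent from reactants"))
        idxs[ai] <- tgt
        if (sp$charge_set) mol$atoms$charge[tgt] <- sp$charge
      } else {
        if (is.na(sp$element)) return(list(error = "bad-template",
                                           message = "unmapped product atom needs an element"))
        mol <- add_atom_(mol, sp$element,
                         charge = if (sp$charge_set) sp$charge else 0L)
        idxs[ai] <- n_atoms(mol)
      }
    }
    prod_atoms[[ci]] <- idxs
  }

  # second pass: product bonds override bonds between mapped atoms
  prod_bond_keys <- character()
  for (ci in seq_along(pd)) {
    comp <- pd[[ci]]
    idxs <- prod_atoms[[ci]]
    if (nrow(comp$bonds)) {
      for (k in seq_len(nrow(comp$bonds))) {
        a <- idxs[comp$bonds$a[k]]; b <- idxs[comp$bonds$b[k]]
        ty <- comp$bonds$type[k]
        ord <- switch(ty, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "any1" = 1, "~" = 1)
        arom <- identical(ty, ":")
        old <- find_bond(mol, a, b)
        if (!is.na(old)) mol <- remove_bonds_(mol, old)
        mol <- add_bond_(mol, a, b, ord, arom)
        m1 <- comp$atoms[[comp$bonds$a[k]]]$map
        m2 <- comp$atoms[[comp$bonds$b[k]]]$map
        if (!is.na(m1) && !is.na(m2)) {
          prod_bond_keys <- c(prod_bond_keys,
                              paste(sort(c(m1, m2)), collapse = "-"))
        }
      }
    }
  }

  # reactant-side bonds between mapped atoms that do not appear on the
  # product side are broken
  for (key in names(react_bonds)) {
    if (!key %in% prod_bond_keys) {
      ids <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
      a <- map_to_atom[[as.character(ids[1])]]
      b <- map_to_atom[[as.character(ids[2])]]
      bk <- find_bond(mol, a, b)
      if (!is.na(bk)) mol <- remove_bonds_(mol, bk)
    }
  }

  # delete atoms matched by unmapped reactant-template atoms
  anchor <- map_to_atom[[as.character(min(as.integer(names(map_to_atom))))]]
  if (length(unmapped_atoms)) {
    keep_map <- setdiff(seq_len(n_atoms(mol)), unmapped_atoms)
    anchor_new <- match(anchor, keep_map)
    mol <- remove_atoms_(mol, unmapped_atoms)
    anchor <- anchor_new
  }

  # keep the fragment holding the anchor (lowest-map parent atom); spectator
  # fragments (cleaved leaving groups) are discarded
  comp_id <- components(mol)
  if (length(unique(comp_id)) > 1L) {
    mol <- remove_atoms_(mol, which(comp_id != comp_id[anchor]))
  }
  list(mol = mol)
}
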