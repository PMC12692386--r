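#' Tokenize a SMILES string
#'
#' Purely lexical split of a SMILES string into atom symbols, bond symbols,
#' branch parentheses, ring-closure digits and dot separators. Two-letter
#' organic-subset elements (`Cl`, `Br`) and full bracket atoms `[...]` are
#' single tokens, as are `%nn` two-digit ring closures. Stereo bond marks
#' (`/`, `\\`) are ordinary tokens. No chemistry is checked here; joining
#' the tokens always reproduces the input byte-for-byte.
#'
#' @param smiles a SMILES string (possibly malformed).
#' @return an object of class `token_sequence` with fields `kind = "SMILES"`
#'   and `tokens` (character vector).
#' @examples
#' tokenize_smiles("C(=O)N")$tokens
#' tokenize_smiles("CCl")$tokens # two tokens, not three
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  tokens <- character()
  i <- 1L
  n <- nchar(smiles)
  while (i <= n) {
    ch <- substr(smiles, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(smiles, i, n), fixed = TRUE)
      if (j == -1L) { # unterminated bracket: emit rest as one token
        tokens <- c(tokens, substr(smiles, i, n))
        break
      }
      tokens <- c(tokens, substr(smiles, i, i + j - 1L))
      i <- i + j
    } else if (ch == "%" && i + 2L <= n &&
               grepl("^[0-9]{2}$", substr(smiles, i + 1L, i + 2L))) {
      tokens <- c(tokens, substr(smiles, i, i + 2L))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n && substr(smiles, i + 1L, i + 1L) %in% c("l", "r")) {
      two <- substr(smiles, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        tokens <- c(tokens, two)
        i <- i + 2L
      } else {
        tokens <- c(tokens, ch)
        i <- i + 1L
      }
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  token_sequence("SMILES", tokens)
}

#' Construct a token sequence
#'
#' @param kind `"SMILES"` or `"SELFIES"`.
#' @param tokens character vector of symbols.
#' @return a `token_sequence` object.
#' @export
token_sequence <- function(kind = "SMILES", tokens = character()) {
  if (!kind %in% c("SMILES", "SELFIES")) stop("kind must be SMILES or SELFIES")
  if (kind == "SELFIES" && length(tokens) &&
      !all(grepl("^\\[[^][]*\\]$", tokens))) {
    stop("SELFIES tokens must be bracketed symbols of the form [...]")
  }
  structure(list(kind = kind, tokens = as.character(tokens)),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence %s, %d tokens> %s\n", x$kind,
              length(x$tokens), paste(x$tokens, collapse = " ")))
  invisible(x)
}

#' Join a token sequence back into its source string
#'
#' @param seq a `token_sequence`.
#' @return single string.
#' @export
join_tokens <- function(seq) paste(seq$tokens, collapse = "")

# --- internal SMILES -> molgraph parser ------------------------------------

# returns list(mol = molgraph) on success or
# list(error = category, message = chr) on failure; never raises
parse_smiles_graph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    return(list(error = "syntax", message = "input is not a single string"))
  }
  if (!nzchar(smiles)) {
    return(list(error = "empty-input", message = "empty SMILES string"))
  }
  toks <- tokenize_smiles(smiles)$tokens

  mol <- new_mol()
  prev <- 0L                 # index of atom awaiting the next bond
  pending_bond <- NA_character_
  stack <- integer()         # branch return points
  ringmap <- list()          # digit -> list(atom, bond)
  expect_atom_after_bond <- FALSE

  syntax <- function(msg) list(error = "syntax", message = msg)

  for (tok in toks) {
    if (tok %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.na(pending_bond)) return(syntax("two bond symbols in a row"))
      pending_bond <- tok
      expect_atom_after_bond <- TRUE
    } else if (tok == "(") {
      if (prev == 0L) return(syntax("branch start before any atom"))
      if (!is.na(pending_bond)) return(syntax("bond symbol before branch open"))
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (!length(stack)) return(syntax("unmatched closing parenthesis"))
      if (!is.na(pending_bond)) return(syntax("dangling bond before branch close"))
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      if (!is.na(pending_bond)) return(syntax("bond symbol before dot"))
      prev <- 0L
    } else if (grepl("^[0-9]$", tok) || grepl("^%[0-9]{2}$", tok)) {
      if (prev == 0L) return(syntax("ring closure before any atom"))
      digit <- sub("^%", "", tok)
      open <- ringmap[[digit]]
      if (is.null(open)) {
        ringmap[[digit]] <- list(atom = prev, bond = pending_bond)
      } else {
        b1 <- open$bond; b2 <- pending_bond
        bond <- if (!is.na(b1)) b1 else b2
        if (!is.na(b1) && !is.na(b2) && b1 != b2) {
          return(syntax(sprintf("conflicting bond symbols on ring closure %s", digit)))
        }
        if (open$atom == prev) return(syntax("ring closure to the same atom"))
        if (!is.na(find_bond(mol, open$atom, prev))) {
          return(syntax("duplicate ring-closure bond"))
        }
        ord <- switch(if (is.na(bond)) "default" else bond,
                      "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
                      "/" = 1, "\\" = 1, "default" = NA)
        arom <- FALSE
        if (is.na(ord)) { # unspecified: aromatic if both ends aromatic
          if (mol$atoms$aromatic[open$atom] && mol$atoms$aromatic[prev]) {
            ord <- 1.5; arom <- TRUE
          } else ord <- 1
        } else if (ord == 1.5) arom <- TRUE
        mol <- add_bond_(mol, open$atom, prev, ord, arom)
        ringmap[[digit]] <- NULL
      }
      pending_bond <- NA_character_
      expect_atom_after_bond <- FALSE
    } else {
      at <- parse_atom_token(tok)
      if (!is.null(at$error)) return(syntax(at$error))
      mol <- add_atom_(mol, at$element, at$aromatic, at$charge, at$hcount)
      idx <- n_atoms(mol)
      if (prev > 0L) {
        ord <- switch(if (is.na(pending_bond)) "default" else pending_bond,
                      "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
                      "/" = 1, "\\" = 1, "default" = NA)
        arom <- FALSE
        if (is.na(ord)) {
          if (mol$atoms$aromatic[prev] && at$aromatic) { ord <- 1.5; arom <- TRUE }
          else ord <- 1
        } else if (ord == 1.5) arom <- TRUE
        mol <- add_bond_(mol, prev, idx, ord, arom)
      }
      prev <- idx
      pending_bond <- NA_character_
      expect_atom_after_bond <- FALSE
    }
  }

  if (length(stack)) return(syntax("unclosed branch parenthesis"))
  if (expect_atom_after_bond || !is.na(pending_bond)) {
    return(syntax("dangling bond symbol at end of string"))
  }
  if (length(ringmap)) {
    return(list(error = "unclosed-ring",
                message = sprintf("ring bond index %s never closed",
                                  paste(names(ringmap), collapse = ","))))
  }
  if (n_atoms(mol) == 0L) {
    return(list(error = "empty-input", message = "no atoms in SMILES"))
  }
  list(mol = mol)
}

# parse one atom token (bare organic-subset symbol or [bracket] atom)
parse_atom_token <- function(tok) {
  bare <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
  bare_arom <- c("b", "c", "n", "o", "p", "s")
  if (tok %in% bare) {
    return(list(element = tok, aromatic = FALSE, charge = 0L, hcount = NA_integer_))
  }
  if (tok %in% bare_arom) {
    return(list(element = toupper(tok), aromatic = TRUE, charge = 0L,
                hcount = NA_integer_))
  }
  if (grepl("^\\[.*\\]$", tok)) {
    body <- substr(tok, 2L, nchar(tok) - 1L)
    # [isotope?][symbol][@|@@]?[H<n>?]?[charge]?[:map]?
    m <- regmatches(body, regexec(
      "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H([0-9]*))?([+-][0-9]*|\\+\\+|--)?(:[0-9]+)?$",
      body))[[1]]
    if (!length(m)) return(list(error = sprintf("malformed bracket atom %s", tok)))
    sym <- m[3]
    aromatic <- FALSE
    if (sym %in% bare_arom) { aromatic <- TRUE; sym <- toupper(sym) }
    else if (sym == tolower(sym) && nchar(sym) == 1L) {
      return(list(error = sprintf("unknown aromatic symbol in %s", tok)))
    }
    if (sym == "H") return(list(error = "explicit hydrogen atoms are not supported"))
    if (!.is_known_element(sym)) {
      return(list(error = sprintf("unknown element %s", sym)))
    }
    hc <- if (m[5] == "") 0L else if (m[6] == "") 1L else as.integer(m[6])
    chg_str <- m[7]
    charge <- if (chg_str == "") 0L
    else if (chg_str == "++") 2L
    else if (chg_str == "--") -2L
    else if (chg_str %in% c("+", "-")) ifelse(chg_str == "+", 1L, -1L)
    else as.integer(paste0(substr(chg_str, 1, 1),
                           ifelse(nchar(chg_str) > 1, substr(chg_str, 2, nchar(chg_str)), "1")))
    return(list(element = sym, aromatic = aromatic, charge = charge, hcount = hc))
  }
  list(error = sprintf("unexpected token '%s'", tok))
}
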