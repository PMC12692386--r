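#' Mutation alphabets
#'
#' The benchmark uses two fixed mutation alphabets. The SMILES alphabet is
#' the 13 characters `F O N C ( ) = # 1 2 3 4 5`; SMILES token mutation
#' only inserts or substitutes symbols from this set (seed molecules may of
#' course contain symbols outside it). The SELFIES alphabet is a 15-token
#' set over the same C/N/O/F chemistry: atom tokens with single, double and
#' triple bond prefixes, three single-index branch tokens, two ring tokens
#' and a padding/terminator token.
#'
#' @param kind `"SMILES"` or `"SELFIES"`.
#' @param symbols optional custom symbol set (unique, non-empty).
#' @return an `alphabet` object with fields `kind` and `symbols`.
#' @examples
#' default_alphabet("SMILES")$symbols
#' length(default_alphabet("SELFIES")$symbols) # 15
#' @export
default_alphabet <- function(kind = c("SMILES", "SELFIES")) {
  kind <- match.arg(kind)
  if (kind == "SMILES") {
    alphabet("SMILES", c("F", "O", "N", "C", "(", ")", "=", "#",
                         "1", "2", "3", "4", "5"))
  } else {
    alphabet("SELFIES", c("[epsilon]", "[Ring1]", "[Ring2]",
                          "[Branch1_1]", "[Branch1_2]", "[Branch1_3]",
                          "[F]", "[O]", "[=O]", "[N]", "[=N]", "[#N]",
                          "[C]", "[=C]", "[#C]"))
  }
}

#' @rdname default_alphabet
#' @export
alphabet <- function(kind = c("SMILES", "SELFIES"), symbols) {
  kind <- match.arg(kind)
  symbols <- as.character(symbols)
  if (!length(symbols)) stop("alphabet must be non-empty")
  if (anyDuplicated(symbols)) stop("alphabet symbols must be unique")
  structure(list(kind = kind, symbols = symbols), class = "alphabet")
}

#' @export
print.alphabet <- function(x, ...) {
  cat(sprintf("<alphabet %s, %d symbols> %s\n", x$kind, length(x$symbols),
              paste(x$symbols, collapse = " ")))
  invisible(x)
}
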