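#' Mutation configuration
#'
#' Shared configuration for the five mutation operators. `edits_per_mutant`
#' is the number of token/graph edits applied per requested mutant
#' (default 1). `resample_cap` bounds rejection-sampling retries for the
#' graph operators (0 disables resampling); SMILES token mutation never
#' resamples - its raw validity is the measured outcome - and SELFIES
#' token mutation needs no resampling by construction. `max_heavy_atoms`
#' guards against runaway growth: larger mutants are recorded invalid with
#' error `size-guard`.
#'
#' @param operator one of `"GB-GA"`, `"GB-GM"`, `"SCC"`, `"SF-T"`, `"SM-T"`.
#' @param edits_per_mutant positive integer, edits per mutant.
#' @param resample_cap non-negative integer retry bound for rejection
#'   sampling.
#' @param rng_seed integer seed; `NULL` uses the current RNG state.
#' @param alphabet mutation `alphabet` for the token operators (defaults to
#'   the built-in 13-character SMILES / 15-token SELFIES alphabets).
#' @param max_heavy_atoms heavy-atom growth guard.
#' @param element_palette elements available to graph edits.
#' @param ring_sizes ring sizes the graph operator may form.
#' @param remove_policy `"largest-fragment"` keeps the biggest piece when an
#'   atom/bond removal disconnects the molecule; `"reject"` discards the
#'   edit instead.
#' @param edit_weights optional named weights over the graph edit kinds.
#' @return a `mutation_config` object.
#' @export
mutation_config <- function(operator = c("GB-GA", "GB-GM", "SCC", "SF-T", "SM-T"),
                            edits_per_mutant = 1L,
                            resample_cap = 20L,
                            rng_seed = NULL,
                            alphabet = NULL,
                            max_heavy_atoms = 120L,
                            element_palette = c("C", "N", "O", "F"),
                            ring_sizes = 3:7,
                            remove_policy = c("largest-fragment", "reject"),
                            edit_weights = NULL) {
  operator <- match.arg(operator)
  remove_policy <- match.arg(remove_policy)
  stopifnot(edits_per_mutant >= 1L, resample_cap >= 0L, max_heavy_atoms >= 1L)
  if (is.null(alphabet)) {
    alphabet <- if (operator == "SF-T") default_alphabet("SELFIES")
    else default_alphabet("SMILES")
  }
  structure(list(operator = operator,
                 edits_per_mutant = as.integer(edits_per_mutant),
                 resample_cap = as.integer(resample_cap),
                 rng_seed = rng_seed,
                 alphabet = alphabet,
                 max_heavy_atoms = as.integer(max_heavy_atoms),
                 element_palette = element_palette,
                 ring_sizes = as.integer(ring_sizes),
                 remove_policy = remove_policy,
                 edit_weights = edit_weights),
            class = "mutation_config")
}

.maybe_seed <- function(cfg) {
  if (!is.null(cfg$rng_seed)) set.seed(as.integer(cfg$rng_seed))
}

# uniform MutationRecord builder: sanitizes the proposed SMILES, applies
# the heavy-atom guard, and carries provenance
make_mutation_record <- function(parent, operator, smiles, attempts, trace,
                                 elapsed, cfg, error = NULL) {
  if (!is.null(error)) {
    rec <- structure(list(id = paste0(parent$id, ".mut"),
                          smiles_input = if (is.null(smiles)) "" else smiles,
                          smiles_canonical = NA_character_, valid = FALSE,
                          error = error, error_message = error, mol = NULL),
                     class = "molecule_record")
  } else {
    rec <- parse_and_sanitize(smiles, id = paste0(parent$id, ".mut"))
    if (rec$valid && n_atoms(rec$mol) > cfg$max_heavy_atoms) {
      rec$valid <- FALSE
      rec$error <- "size-guard"
      rec$smiles_canonical <- NA_character_
      rec$mol <- NULL
    }
  }
  structure(list(parent_id = parent$id,
                 operator = operator,
                 mutant_smiles = if (is.null(smiles)) "" else smiles,
                 valid = rec$valid,
                 error = rec$error,
                 elapsed_s = elapsed,
                 attempts = as.integer(attempts),
                 edit_trace = trace,
                 record = rec),
            class = "mutation_record")
}

#' @export
print.mutation_record <- function(x, ...) {
  cat(sprintf("<mutation_record %s %s> %s (%s, %d attempt%s, %.4fs)\n",
              x$operator, x$parent_id,
              if (x$valid) x$record$smiles_canonical else x$mutant_smiles,
              if (x$valid) "valid" else paste0("invalid: ", x$error),
              x$attempts, if (x$attempts == 1L) "" else "s", x$elapsed_s))
  invisible(x)
}

#' Apply one random token edit
#'
#' Draws the edit kind uniformly from insert/replace/delete, the position
#' uniformly over the valid positions, and any new symbol uniformly from
#' the alphabet; a replacement never reproduces the original symbol when
#' the alphabet has at least two symbols. Deleting the last token yields
#' the empty sequence (classified invalid downstream); replace/delete on
#' an empty sequence is an error.
#'
#' @param seq a `token_sequence`.
#' @param alphabet an `alphabet` of matching kind.
#' @return list with elements `seq` (edited `token_sequence`) and `trace`
#'   (human-readable description of the edit).
#' @export
mutate_token_sequence <- function(seq, alphabet = default_alphabet(seq$kind)) {
  stopifnot(inherits(seq, "token_sequence"), inherits(alphabet, "alphabet"))
  L <- length(seq$tokens)
  kinds <- c("insert", "replace", "delete")
  kind <- sample(kinds, 1L)
  if (L == 0L && kind != "insert") {
    stop("cannot ", kind, " on an empty token sequence")
  }
  toks <- seq$tokens
  if (kind == "insert") {
    pos <- sample.int(L + 1L, 1L) - 1L  # insert after position pos (0 = front)
    sym <- sample(alphabet$symbols, 1L)
    toks <- append(toks, sym, after = pos)
    trace <- sprintf("insert %s at %d", sym, pos + 1L)
  } else if (kind == "replace") {
    pos <- sample.int(L, 1L)
    old <- toks[pos]
    pool <- alphabet$symbols
    if (length(pool) >= 2L) pool <- setdiff(pool, old)
    if (!length(pool)) pool <- alphabet$symbols
    sym <- sample(pool, 1L)
    toks[pos] <- sym
    trace <- sprintf("replace %s->%s at %d", old, sym, pos)
  } else {
    pos <- sample.int(L, 1L)
    trace <- sprintf("delete %s at %d", toks[pos], pos)
    toks <- toks[-pos]
  }
  list(seq = token_sequence(seq$kind, toks), trace = trace)
}

#' SMILES token mutation (SM-T)
#'
#' Tokenizes the parent's canonical SMILES, applies `edits_per_mutant`
#' random token edits drawing symbols only from the 13-character mutation
#' alphabet, joins and sanitizes. No resampling is performed: the raw
#' validity of the edited string is the quantity the benchmark measures.
#'
#' @param record valid parent `molecule_record`.
#' @param cfg a `mutation_config` (operator `"SM-T"`).
#' @return a `mutation_record`.
#' @export
smiles_token_mutation <- function(record, cfg = mutation_config("SM-T")) {
  stopifnot(inherits(record, "molecule_record"), isTRUE(record$valid))
  .maybe_seed(cfg)
  t0 <- proc.time()[["elapsed"]]
  seq <- tokenize_smiles(record$smiles_canonical)
  trace <- character(cfg$edits_per_mutant)
  for (e in seq_len(cfg$edits_per_mutant)) {
    if (length(seq$tokens) == 0L) break # nothing left to edit
    ed <- mutate_token_sequence(seq, cfg$alphabet)
    seq <- ed$seq
    trace[e] <- ed$trace
  }
  smi <- join_tokens(seq)
  elapsed <- proc.time()[["elapsed"]] - t0
  make_mutation_record(record, "SM-T", smi, attempts = 1L,
                       trace = trace[nzchar(trace)], elapsed = elapsed,
                       cfg = cfg)
}

#' SELFIES token mutation (SF-T)
#'
#' Encodes the parent to SELFIES, applies `edits_per_mutant` random token
#' edits over the 15-token alphabet, decodes and sanitizes. The grammar
#' guarantees every non-empty decode is valid, so no resampling is needed;
#' a decode to the empty string is recorded invalid (`empty-input`) and
#' counted in the validity denominator. Parents outside the encodable
#' chemistry yield an `operator-skip` record.
#'
#' @param record valid parent `molecule_record`.
#' @param cfg a `mutation_config` (operator `"SF-T"`).
#' @return a `mutation_record`.
#' @export
selfies_token_mutation <- function(record, cfg = mutation_config("SF-T")) {
  stopifnot(inherits(record, "molecule_record"), isTRUE(record$valid))
  .maybe_seed(cfg)
  t0 <- proc.time()[["elapsed"]]
  seq <- tryCatch(encode_selfies(record), error = function(e) NULL)
  if (is.null(seq)) {
    elapsed <- proc.time()[["elapsed"]] - t0
    return(make_mutation_record(record, "SF-T", NULL, attempts = 1L,
                                trace = character(), elapsed = elapsed,
                                cfg = cfg, error = "operator-skip"))
  }
  trace <- character(cfg$edits_per_mutant)
  for (e in seq_len(cfg$edits_per_mutant)) {
    if (length(seq$tokens) == 0L) break
    ed <- mutate_token_sequence(seq, cfg$alphabet)
    seq <- ed$seq
    trace[e] <- ed$trace
  }
  smi <- decode_selfies(seq)
  elapsed <- proc.time()[["elapsed"]] - t0
  make_mutation_record(record, "SF-T", smi, attempts = 1L,
                       trace = trace[nzchar(trace)], elapsed = elapsed,
                       cfg = cfg)
}
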