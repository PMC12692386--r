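#' Fit a fingerprint-based random-forest QSAR model
#'
#' Fits an ensemble-of-trees regressor of pIC50 on radius-2/2048-bit
#' circular fingerprints, the conservation-of-function scorer of the
#' benchmark. Duplicate SMILES are averaged first and unparseable rows
#' dropped (with a recorded count); a fixed 80/20 split under the given
#' seed provides the held-out R-squared and RMSE stored in
#' `train_summary`. Refitting with the same table and seed reproduces
#' identical predictions.
#'
#' @param table data frame with columns `smiles` and `pIC50` (an activity
#'   table), at least 50 usable rows.
#' @param seed integer RNG seed for the split and forest.
#' @param num_trees number of trees (default 500).
#' @param target_id label for the modeled target.
#' @param nbits,radius fingerprint specification.
#' @return object of class `qsar_model` with `predict`, `print` and
#'   `summary` methods.
#' @importFrom ranger ranger
#' @export
train_qsar <- function(table, seed = 1L, num_trees = 500L,
                       target_id = "target", nbits = 2048L, radius = 2L) {
  stopifnot(is.data.frame(table), all(c("smiles", "pIC50") %in% names(table)))
  if (!all(is.finite(table$pIC50))) stop("pIC50 values must be finite")
  # average duplicates on canonical form
  recs <- lapply(seq_len(nrow(table)), function(i)
    parse_and_sanitize(table$smiles[i], id = paste0("t", i)))
  ok <- vapply(recs, function(r) isTRUE(r$valid), TRUE)
  n_dropped <- sum(!ok)
  recs <- recs[ok]
  y <- table$pIC50[ok]
  can <- vapply(recs, function(r) r$smiles_canonical, "")
  agg <- tapply(y, can, mean)
  can_u <- names(agg)
  y_u <- as.numeric(agg)
  rec_u <- recs[match(can_u, can)]
  if (length(y_u) < 50L) {
    stop("too-few-rows: need at least 50 usable molecules, got ", length(y_u))
  }

  X <- t(vapply(rec_u, fingerprint, integer(nbits), nbits = nbits,
                radius = radius))
  colnames(X) <- paste0("b", seq_len(nbits))

  set.seed(as.integer(seed))
  n <- length(y_u)
  test_idx <- sample.int(n, max(1L, round(0.2 * n)))
  train_idx <- setdiff(seq_len(n), test_idx)

  fit_df <- data.frame(pIC50 = y_u[train_idx], X[train_idx, , drop = FALSE])
  rf <- ranger::ranger(pIC50 ~ ., data = fit_df, num.trees = num_trees,
                       seed = as.integer(seed), num.threads = 1L,
                       respect.unordered.factors = FALSE)
  pred_test <- stats::predict(rf, data.frame(X[test_idx, , drop = FALSE]))$predictions
  yt <- y_u[test_idx]
  ss_res <- sum((yt - pred_test)^2)
  ss_tot <- sum((yt - mean(yt))^2)
  r2 <- if (ss_tot < 1e-12) NA_real_ else 1 - ss_res / ss_tot
  rmse <- sqrt(mean((yt - pred_test)^2))

  structure(list(target_id = target_id,
                 fingerprint_spec = list(radius = radius, nbits = nbits),
                 model = rf,
                 seed = as.integer(seed),
                 train_summary = list(n = n, n_train = length(train_idx),
                                      n_test = length(test_idx),
                                      n_dropped = n_dropped,
                                      heldout_r2 = r2,
                                      heldout_rmse = rmse,
                                      y_range = range(y_u))),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  s <- x$train_summary
  cat(sprintf(paste0("<qsar_model %s> random forest on %d-bit radius-%d ",
                     "fingerprints\n  n=%d (%d dropped), held-out R2=%.3f, ",
                     "RMSE=%.3f pIC50 units\n"),
              x$target_id, x$fingerprint_spec$nbits, x$fingerprint_spec$radius,
              s$n, s$n_dropped, s$heldout_r2, s$heldout_rmse))
  invisible(x)
}

#' @export
summary.qsar_model <- function(object, ...) {
  out <- c(list(target_id = object$target_id), object$train_summary)
  class(out) <- "summary.qsar_model"
  out
}

#' @export
print.summary.qsar_model <- function(x, ...) {
  cat(sprintf("QSAR model for %s\n", x$target_id))
  cat(sprintf("  molecules: %d (train %d / test %d, %d dropped)\n",
              x$n, x$n_train, x$n_test, x$n_dropped))
  cat(sprintf("  held-out R2: %.3f, RMSE: %.3f\n", x$heldout_r2, x$heldout_rmse))
  cat(sprintf("  training pIC50 range: [%.2f, %.2f]\n",
              x$y_range[1], x$y_range[2]))
  invisible(x)
}

#' Predict pIC50 for a molecule
#'
#' @param model a `qsar_model`.
#' @param record a valid `molecule_record` (or list of records).
#' @return numeric prediction(s); tree ensembles keep them inside the
#'   training target range.
#' @export
predict_pic50 <- function(model, record) {
  stopifnot(inherits(model, "qsar_model"))
  recs <- if (inherits(record, "molecule_record")) list(record) else record
  if (!length(recs)) return(numeric())
  bad <- !vapply(recs, function(r) isTRUE(r$valid), TRUE)
  if (any(bad)) stop("cannot predict for invalid molecule records")
  X <- t(vapply(recs, fingerprint, integer(model$fingerprint_spec$nbits),
                nbits = model$fingerprint_spec$nbits,
                radius = model$fingerprint_spec$radius))
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  p <- stats::predict(model$model, data.frame(X))$predictions
  if (inherits(record, "molecule_record")) p[1] else p
}

#' @export
predict.qsar_model <- function(object, newdata, ...) {
  predict_pic50(object, newdata)
}

# predict from a list of precomputed fingerprints (harness batching)
.predict_fp_list <- function(model, fps) {
  if (!length(fps)) return(numeric())
  X <- do.call(rbind, fps)
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  stats::predict(model$model, data.frame(X))$predictions
}

#' Absolute parent-to-mutant potency shift
#'
#' `|pIC50(parent) - pIC50(mutant)|`: the magnitude of the predicted
#' bioactivity change, without directionality.
#'
#' @param model a `qsar_model`.
#' @param parent valid parent `molecule_record`.
#' @param mutant a `mutation_record` (must be valid) or valid
#'   `molecule_record`.
#' @return object of class `potency_shift` with the two predictions and
#'   `abs_delta`.
#' @export
potency_shift <- function(model, parent, mutant) {
  mrec <- if (inherits(mutant, "mutation_record")) mutant$record else mutant
  operator <- if (inherits(mutant, "mutation_record")) mutant$operator else NA_character_
  stopifnot(isTRUE(parent$valid))
  if (!isTRUE(mrec$valid)) stop("potency shift requires a valid mutant")
  pp <- predict_pic50(model, parent)
  pm <- predict_pic50(model, mrec)
  structure(list(parent_id = parent$id, operator = operator,
                 pIC50_parent = pp, pIC50_mutant = pm,
                 abs_delta = abs(pp - pm)),
            class = "potency_shift")
}

#' @export
print.potency_shift <- function(x, ...) {
  cat(sprintf("<potency_shift %s%s> %.3f -> %.3f, |delta| = %.3f\n",
              x$parent_id,
              if (is.na(x$operator)) "" else paste0(" ", x$operator),
              x$pIC50_parent, x$pIC50_mutant, x$abs_delta))
  invisible(x)
}
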