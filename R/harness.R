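# Benchmark harness: synthetic seed-set generation, the synthetic
# structure-activity oracle standing in for assay-derived training data,
# and the protocol runner producing the per-(operator, budget) report.

#' Generate a synthetic seed set
#'
#' Draws uniform-random SELFIES token sequences over the 15-token alphabet
#' and decodes them; the grammar guarantees validity, duplicates (by
#' canonical SMILES) are resampled, and the result is deterministic under
#' the seed. The set stands in for a drug-like seed population restricted
#' to C/N/O/F chemistry.
#'
#' @param n number of distinct molecules.
#' @param min_tokens,max_tokens token-length range of the sampled
#'   sequences (defaults 5-25).
#' @param rng_seed integer seed.
#' @return list of `n` valid `molecule_record`s with ids `s1..sn`.
#' @export
generate_seed_set <- function(n, min_tokens = 5L, max_tokens = 25L,
                              rng_seed = 1L) {
  stopifnot(n >= 1L, min_tokens >= 1L, min_tokens <= max_tokens)
  set.seed(as.integer(rng_seed))
  ab <- default_alphabet("SELFIES")$symbols
  seen <- character()
  out <- list()
  draws <- 0L
  while (length(out) < n) {
    draws <- draws + 1L
    if (draws > 100L * n) {
      stop("could not reach ", n, " distinct molecules in ", 100L * n, " draws")
    }
    L <- sample(seq.int(min_tokens, max_tokens), 1L)
    toks <- sample(ab, L, replace = TRUE)
    smi <- decode_selfies(toks)
    if (!nzchar(smi) || smi %in% seen) next
    rec <- parse_and_sanitize(smi, id = paste0("s", length(out) + 1L))
    if (!rec$valid) next # cannot happen by construction; guard anyway
    seen <- c(seen, smi)
    out[[length(out) + 1L]] <- rec
  }
  out
}

#' Synthetic structure-activity oracle parameters
#'
#' The oracle labels molecules with
#' `pIC50 = clip(intercept + w . z(descriptors) + N(0, sigma), 2, 12)`,
#' where `z` standardizes the nine-descriptor vector with the stored
#' center/scale. Default weights emphasize lipophilicity, size and
#' H-bonding balance - the properties fingerprint QSAR models typically
#' latch onto.
#'
#' @param weights named numeric vector over the descriptor names.
#' @param intercept baseline pIC50.
#' @param sigma assay-noise standard deviation (pIC50 units).
#' @param center,scale standardization vectors (filled in by
#'   [generate_activity_dataset()] when `NULL`).
#' @return an `oracle_params` object.
#' @export
oracle_params <- function(weights = c(MW = 0.8, NVE = 0, NRE = 0, TPSA = 0.6,
                                      MolLogP = 1.0, NHD = -0.4, NHA = 0.4,
                                      NRB = -0.3, FractionCSP3 = 0.3),
                          intercept = 6, sigma = 0.3,
                          center = NULL, scale = NULL) {
  stopifnot(sigma >= 0, all(names(weights) %in% .DESCRIPTOR_NAMES))
  w <- stats::setNames(numeric(length(.DESCRIPTOR_NAMES)), .DESCRIPTOR_NAMES)
  w[names(weights)] <- weights
  structure(list(weights = w, intercept = intercept, sigma = sigma,
                 center = center, scale = scale),
            class = "oracle_params")
}

#' Score one molecule with the synthetic oracle
#'
#' @param record valid `molecule_record`.
#' @param params an `oracle_params` with center/scale set.
#' @param descriptors optional precomputed descriptor vector (batching).
#' @return pIC50 in `[2, 12]`; noise is drawn from the current RNG state
#'   (none when `sigma = 0`).
#' @export
synthetic_activity_oracle <- function(record, params, descriptors = NULL) {
  stopifnot(inherits(params, "oracle_params"))
  if (is.null(params$center) || is.null(params$scale)) {
    stop("oracle params lack standardization (run generate_activity_dataset)")
  }
  d <- if (is.null(descriptors)) descriptor_vector(record) else descriptors
  z <- (d[.DESCRIPTOR_NAMES] - params$center) / params$scale
  val <- params$intercept + sum(params$weights * z)
  if (params$sigma > 0) val <- val + stats::rnorm(1L, 0, params$sigma)
  min(12, max(2, val))
}

#' Generate a synthetic activity dataset
#'
#' Generates a seed set, standardizes its descriptors, and labels every
#' molecule with the synthetic oracle - the stand-in for an
#' assay-derived (smiles, pIC50) table used in the QSAR
#' parameter-recovery experiments.
#'
#' @param n number of molecules (>= 50).
#' @param params an `oracle_params` (center/scale filled from this set
#'   when absent).
#' @param rng_seed integer seed (molecules and noise).
#' @param min_tokens,max_tokens passed to [generate_seed_set()].
#' @return data frame with columns `smiles`, `pIC50`; the completed
#'   `oracle_params` are attached as attribute `"params"`.
#' @export
generate_activity_dataset <- function(n, params = oracle_params(),
                                      rng_seed = 1L,
                                      min_tokens = 5L, max_tokens = 25L) {
  stopifnot(n >= 50L)
  recs <- generate_seed_set(n, min_tokens, max_tokens, rng_seed = rng_seed)
  dm <- descriptor_matrix(recs)
  X <- as.matrix(dm[.DESCRIPTOR_NAMES])
  if (is.null(params$center)) params$center <- colMeans(X)
  if (is.null(params$scale)) {
    sc <- apply(X, 2L, stats::sd)
    sc[sc < 1e-9] <- 1
    params$scale <- sc
  }
  set.seed(derive_seed(rng_seed, 104729L))
  y <- vapply(seq_along(recs), function(i) {
    synthetic_activity_oracle(recs[[i]], params, descriptors = X[i, ])
  }, 0)
  out <- data.frame(smiles = vapply(recs, function(r) r$smiles_canonical, ""),
                    pIC50 = y, stringsAsFactors = FALSE)
  attr(out, "params") <- params
  out
}

#' Benchmark protocol
#'
#' Bundles everything one benchmark run needs: the seed set, the operator
#' subset, the mutant budgets (default 1/3/5), the master seed, optional
#' per-operator configuration overrides and optional QSAR models for
#' potency-shift scoring. The GB-GM edit table defaults to one trained on
#' the seed set itself.
#'
#' @param seeds list of valid `molecule_record`s.
#' @param operators subset of the five operator names.
#' @param budgets mutant budgets.
#' @param rng_seed master seed; every operator call derives its own
#'   stream from it.
#' @param configs optional named list of `mutation_config` overrides.
#' @param qsar_models optional named list of `qsar_model`s.
#' @param edit_table optional `edit_probability_table` for GB-GM.
#' @param templates,library reaction templates / building blocks for SCC.
#' @return a `benchmark_protocol`.
#' @export
benchmark_protocol <- function(seeds,
                               operators = c("GB-GA", "GB-GM", "SCC",
                                             "SF-T", "SM-T"),
                               budgets = c(1L, 3L, 5L),
                               rng_seed = 1L,
                               configs = list(),
                               qsar_models = list(),
                               edit_table = NULL,
                               templates = NULL, library = NULL) {
  stopifnot(length(seeds) >= 1L, all(budgets >= 1L))
  operators <- match.arg(operators, c("GB-GA", "GB-GM", "SCC", "SF-T", "SM-T"),
                         several.ok = TRUE)
  if (!all(vapply(seeds, function(r) isTRUE(r$valid), TRUE))) {
    stop("all protocol seeds must be valid")
  }
  structure(list(seeds = seeds, operators = operators,
                 budgets = as.integer(budgets), rng_seed = as.integer(rng_seed),
                 configs = configs, qsar_models = qsar_models,
                 edit_table = edit_table, templates = templates,
                 library = library),
            class = "benchmark_protocol")
}

# population bookkeeping: validity percentage, counts and throughput
#' Summarize a mutant population
#'
#' The bookkeeping identities behind the benchmark's summary table:
#' `validity_percent = 100 * molecules / requested` and
#' `mol_per_s = molecules / time_s` (NA when no time was spent).
#'
#' @param n_valid number of valid mutants.
#' @param n_requested number of requested mutants (seeds x budget).
#' @param time_s summed operator wall-clock seconds.
#' @return one-row data frame with `validity_percent`, `molecules`,
#'   `time_s`, `mol_per_s`.
#' @export
summarize_population <- function(n_valid, n_requested, time_s) {
  stopifnot(n_requested >= 1L, n_valid >= 0L, n_valid <= n_requested)
  data.frame(validity_percent = 100 * n_valid / n_requested,
             molecules = n_valid,
             time_s = time_s,
             mol_per_s = if (time_s > 0) n_valid / time_s else NA_real_)
}

.op_index <- function(op) match(op, c("GB-GA", "GB-GM", "SCC", "SF-T", "SM-T"))

#' Run the benchmark protocol
#'
#' For every operator and budget: generates the mutants, aggregates
#' validity/time/throughput, computes parent-mutant complexity deltas,
#' potency shifts for each supplied QSAR model, parent-mutant similarity,
#' and per-operator KL divergences (original population vs pooled valid
#' mutants) for the nine diversity descriptors, the complexity fields and
#' each QSAR target. Operator failures on single molecules are recorded
#' as invalid mutants, never fatal.
#'
#' @param protocol a `benchmark_protocol`.
#' @param progress emit per-population progress messages to stderr.
#' @return a `benchmark_report`.
#' @export
run_benchmark <- function(protocol, progress = interactive()) {
  stopifnot(inherits(protocol, "benchmark_protocol"))
  seeds <- protocol$seeds
  n_seeds <- length(seeds)
  table <- protocol$edit_table
  if (is.null(table) && "GB-GM" %in% protocol$operators) {
    table <- estimate_edit_probabilities(seeds)
  }
  templates <- if (is.null(protocol$templates)) packaged_templates() else protocol$templates
  library <- if (is.null(protocol$library)) packaged_building_blocks() else protocol$library

  # per-run caches: descriptors, complexity profiles and fingerprints of
  # the seed population are computed once
  seed_dm <- descriptor_matrix(seeds)
  seed_profiles <- .profiles_matrix(seeds)
  seed_fps <- lapply(seeds, fingerprint)
  models <- protocol$qsar_models
  seed_pred <- lapply(models, function(m) predict_pic50(m, seeds))

  summary_rows <- list()
  delta_rows <- list()
  potency_rows <- list()
  sim_rows <- list()
  kl_rows <- list()
  klp_rows <- list()
  mutant_smiles <- list()
  signed_dmw <- list()

  for (op in protocol$operators) {
    cfg0 <- protocol$configs[[op]]
    if (is.null(cfg0)) cfg0 <- mutation_config(op)
    pooled_prof <- NULL
    pooled_dm <- NULL
    pooled_pred <- lapply(models, function(m) numeric())
    pooled_parent <- integer()
    for (k in protocol$budgets) {
      muts <- vector("list", n_seeds * k)
      t_total <- 0
      for (i in seq_len(n_seeds)) {
        cfg_i <- cfg0
        cfg_i$rng_seed <- derive_seed(
          protocol$rng_seed * 5 + .op_index(op), k * 1000L + i)
        mk <- generate_mutants(seeds[[i]], cfg_i, k = k, table = table,
                               templates = templates, library = library)
        for (j in seq_len(k)) muts[[(i - 1L) * k + j]] <- mk[[j]]
        t_total <- t_total + sum(vapply(mk, function(m) m$elapsed_s, 0))
      }
      valid_idx <- which(vapply(muts, function(m) isTRUE(m$valid), TRUE))
      parent_idx <- rep(seq_len(n_seeds), each = k)[valid_idx]
      mut_recs <- lapply(muts[valid_idx], function(m) m$record)
      n_req <- n_seeds * k
      srow <- summarize_population(length(valid_idx), n_req, t_total)
      srow <- cbind(data.frame(operator = op, k = k), srow)
      summary_rows[[length(summary_rows) + 1L]] <- srow
      if (progress) {
        message(sprintf("[%s k=%d] validity %.1f%% (%d/%d), %.1fs",
                        op, k, srow$validity_percent, srow$molecules,
                        n_req, t_total))
      }

      mut_prof <- if (length(mut_recs)) .profiles_matrix(mut_recs) else NULL
      if (!is.null(mut_prof)) {
        deltas <- abs(seed_profiles[parent_idx, , drop = FALSE] - mut_prof)
        delta_rows[[length(delta_rows) + 1L]] <- data.frame(
          operator = op, k = k, field = .COMPLEXITY_FIELDS,
          mean_abs_delta = colMeans(deltas, na.rm = TRUE),
          n_pairs = length(valid_idx))
      }

      mut_fps <- lapply(mut_recs, fingerprint)
      sims <- if (length(mut_fps)) {
        vapply(seq_along(mut_fps), function(j)
          tanimoto(seed_fps[[parent_idx[j]]], mut_fps[[j]]), 0)
      } else numeric()
      sim_rows[[length(sim_rows) + 1L]] <- data.frame(
        operator = op, k = k,
        mean_similarity = if (length(sims)) mean(sims) else NA_real_,
        n_pairs = length(sims))

      mut_pred <- lapply(models, function(m) .predict_fp_list(m, mut_fps))
      for (tg in names(models)) {
        mean_shift <- if (length(valid_idx)) {
          mean(abs(seed_pred[[tg]][parent_idx] - mut_pred[[tg]]))
        } else NA_real_
        potency_rows[[length(potency_rows) + 1L]] <- data.frame(
          operator = op, k = k, target = tg, mean_abs_delta = mean_shift,
          n_pairs = length(valid_idx))
      }

      mutant_smiles[[paste(op, k, sep = ".")]] <- vapply(
        muts, function(m) if (isTRUE(m$valid)) m$record$smiles_canonical
        else NA_character_, "")

      if (!is.null(mut_prof)) {
        pooled_prof <- rbind(pooled_prof, mut_prof)
        pooled_dm <- rbind(pooled_dm, descriptor_matrix(mut_recs))
        for (tg in names(models)) {
          pooled_pred[[tg]] <- c(pooled_pred[[tg]], mut_pred[[tg]])
        }
        pooled_parent <- c(pooled_parent, parent_idx)
      }
    }

    # per-operator distribution shifts: original vs pooled valid mutants
    if (!is.null(pooled_prof) && nrow(pooled_prof) >= 2L) {
      for (f in .DESCRIPTOR_NAMES) {
        kl <- if (stats::sd(c(seed_dm[[f]], pooled_dm[[f]])) < 1e-12) 0 else
          kl_divergence(seed_dm[[f]], pooled_dm[[f]])$value
        kl_rows[[length(kl_rows) + 1L]] <- data.frame(
          operator = op, metric = f, kl = kl)
      }
      for (f in .COMPLEXITY_FIELDS) {
        a <- seed_profiles[, f]; b <- pooled_prof[, f]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        kl <- if (!length(a) || !length(b) ||
                  stats::sd(c(a, b)) < 1e-12) 0 else
                    kl_divergence(a, b)$value
        kl_rows[[length(kl_rows) + 1L]] <- data.frame(
          operator = op, metric = paste0("cx.", f), kl = kl)
      }
      for (tg in names(models)) {
        klp_rows[[length(klp_rows) + 1L]] <- data.frame(
          operator = op, target = tg,
          kl = kl_divergence(seed_pred[[tg]], pooled_pred[[tg]])$value)
      }
      # signed MW change (direction diagnostic)
      seed_mw <- seed_profiles[, "MW"]
      signed_dmw[[op]] <- mean(pooled_prof[, "MW"] - seed_mw[pooled_parent])
    } else {
      signed_dmw[[op]] <- NA_real_
    }
  }

  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  report <- structure(list(
    summary = bind(summary_rows, data.frame()),
    complexity_deltas = bind(delta_rows, data.frame()),
    potency_shifts = bind(potency_rows, data.frame()),
    similarity = bind(sim_rows, data.frame()),
    kl_descriptors = bind(kl_rows, data.frame()),
    kl_potency = bind(klp_rows, data.frame()),
    mean_signed_dMW = unlist(signed_dmw),
    mutant_smiles = mutant_smiles,
    protocol_info = list(n_seeds = n_seeds, operators = protocol$operators,
                         budgets = protocol$budgets,
                         rng_seed = protocol$rng_seed)
  ), class = "benchmark_report")
  report
}

# complexity profiles for a population with one batched logP/TPSA call
.profiles_matrix <- function(records) {
  smis <- vapply(records, function(r) r$smiles_canonical, "")
  ob <- ob_properties(smis)
  t(vapply(seq_along(records), function(i)
    complexity_profile(records[[i]], ob = ob[i, , drop = FALSE]),
    numeric(length(.COMPLEXITY_FIELDS))))
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d seeds, operators: %s, budgets: %s\n",
              x$protocol_info$n_seeds,
              paste(x$protocol_info$operators, collapse = ", "),
              paste(x$protocol_info$budgets, collapse = "/")))
  s <- x$summary
  s$validity_percent <- round(s$validity_percent, 1)
  s$time_s <- round(s$time_s, 2)
  s$mol_per_s <- round(s$mol_per_s, 1)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
summary.benchmark_report <- function(object, ...) {
  agg <- stats::aggregate(cbind(validity_percent, molecules, time_s) ~ operator,
                          data = object$summary, FUN = mean)
  agg[order(-agg$validity_percent), ]
}

#' Per-aspect operator ranking
#'
#' Orders the operators by speed (total operator time, fastest first),
#' validity (highest first), mean absolute potency shift, mean complexity
#' change (average rank over descriptor fields and over index fields) and
#' structural diversity (lowest parent-mutant similarity first).
#'
#' @param report a `benchmark_report`.
#' @return data frame of ranks, one row per operator.
#' @export
rank_operators <- function(report) {
  s <- report$summary
  ops <- unique(s$operator)
  agg <- function(v, f) vapply(ops, function(o) f(v[s$operator == o]), 0)
  time_total <- agg(s$time_s, sum)
  validity <- agg(s$validity_percent, mean)
  rk <- data.frame(operator = ops,
                   speed = rank(time_total, ties.method = "min"),
                   validity = rank(-validity, ties.method = "min"))
  if (nrow(report$potency_shifts)) {
    p <- stats::aggregate(mean_abs_delta ~ operator, report$potency_shifts, mean)
    rk$pIC50 <- rank(-p$mean_abs_delta[match(ops, p$operator)], ties.method = "min")
  }
  if (nrow(report$complexity_deltas)) {
    cd <- report$complexity_deltas
    desc_f <- c("MW", "NR", "NH", "QCF", "HCF")
    idx_f <- c("BI", "HI", "WI", "QED", "PCI")
    rank_fields <- function(fields) {
      per_field <- lapply(fields, function(f) {
        v <- stats::aggregate(mean_abs_delta ~ operator, cd[cd$field == f, ], mean)
        rank(-v$mean_abs_delta[match(ops, v$operator)], ties.method = "average")
      })
      rank(Reduce(`+`, per_field), ties.method = "min")
    }
    rk$complexity_descriptors <- rank_fields(desc_f)
    rk$complexity_indices <- rank_fields(idx_f)
  }
  if (nrow(report$similarity)) {
    sm <- stats::aggregate(mean_similarity ~ operator, report$similarity, mean)
    rk$diversity <- rank(sm$mean_similarity[match(ops, sm$operator)],
                         ties.method = "min")
  }
  rk
}

#' Write a benchmark report to CSV files
#'
#' Writes `summary.csv`, `complexity_deltas.csv`, `potency_shifts.csv`,
#' `similarity.csv`, `kl_descriptors.csv`, `kl_potency.csv`, `ranks.csv`
#' and `run_config.json` (protocol echo) into `outdir`.
#'
#' @param report a `benchmark_report`.
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    write_table(df, p)
    files <<- c(files, p)
  }
  wr(report$summary, "summary.csv")
  wr(report$complexity_deltas, "complexity_deltas.csv")
  wr(report$potency_shifts, "potency_shifts.csv")
  wr(report$similarity, "similarity.csv")
  wr(report$kl_descriptors, "kl_descriptors.csv")
  wr(report$kl_potency, "kl_potency.csv")
  wr(rank_operators(report), "ranks.csv")
  cfg_path <- file.path(outdir, "run_config.json")
  jsonlite::write_json(report$protocol_info, cfg_path, auto_unbox = TRUE,
                       pretty = TRUE)
  files <- c(files, cfg_path)
  invisible(files)
}
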