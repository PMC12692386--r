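test_that("seed sets are distinct, valid, alphabet-closed and reproducible", {
  s <- generate_seed_set(60, rng_seed = 9L)
  expect_length(s, 60L)
  can <- vapply(s, function(r) r$smiles_canonical, "")
  expect_identical(anyDuplicated(can), 0L)
  expect_true(all(vapply(s, function(r) r$valid, TRUE)))
  for (r in s) {
    expect_true(all(r$mol$atoms$element %in% c("C", "N", "O", "F")), info = r$id)
  }
  s2 <- generate_seed_set(60, rng_seed = 9L)
  expect_identical(can, vapply(s2, function(r) r$smiles_canonical, ""))
  s3 <- generate_seed_set(60, rng_seed = 10L)
  expect_false(identical(can, vapply(s3, function(r) r$smiles_canonical, "")))
})

test_that("population bookkeeping reproduces the benchmark arithmetic", {
  # published-style populations: 486/500, 1446/1500, 448/1500
  expect_equal(summarize_population(486L, 500L, 145.2)$validity_percent, 97.2)
  expect_equal(summarize_population(1446L, 1500L, 1)$validity_percent, 96.4)
  expect_equal(round(summarize_population(448L, 1500L, 1)$validity_percent, 1),
               29.9)
  r <- summarize_population(486L, 500L, 145.2)
  expect_equal(r$mol_per_s, 486 / 145.2)
  expect_equal(round(r$mol_per_s, 1), 3.3)
  expect_equal(summarize_population(500L, 500L, 1)$validity_percent, 100)
  expect_true(is.na(summarize_population(10L, 20L, 0)$mol_per_s))
  expect_error(summarize_population(501L, 500L, 1))
})

test_that("run_benchmark aggregates populations with consistent identities", {
  seeds <- fixture_seeds(30, rng_seed = 301L)
  tab <- generate_activity_dataset(60, rng_seed = 302L)
  model <- train_qsar(tab, seed = 5L, num_trees = 50L)
  proto <- benchmark_protocol(seeds, operators = c("GB-GA", "SM-T"),
                              budgets = c(1L, 3L), rng_seed = 99L,
                              qsar_models = list(tgt = model))
  rep <- run_benchmark(proto, progress = FALSE)
  s <- rep$summary
  expect_identical(nrow(s), 4L)
  # bookkeeping identities on every row
  expect_equal(s$validity_percent, 100 * s$molecules / (30 * s$k))
  expect_equal(s$mol_per_s * s$time_s, s$molecules, tolerance = 1e-9)
  # all report sections present
  expect_true(all(c("summary", "complexity_deltas", "potency_shifts",
                    "similarity", "kl_descriptors", "kl_potency",
                    "mean_signed_dMW") %in% names(rep)))
  expect_true(all(rep$complexity_deltas$mean_abs_delta >= 0, na.rm = TRUE))
  expect_true(all(rep$kl_descriptors$kl >= 0))
  expect_true(all(rep$potency_shifts$mean_abs_delta >= 0, na.rm = TRUE))
  rk <- rank_operators(rep)
  expect_setequal(rk$operator, c("GB-GA", "SM-T"))
  expect_setequal(rk$validity, 1:2)
})

test_that("reports round-trip through CSV and rank by mean shift", {
  seeds <- fixture_seeds(30, rng_seed = 301L)
  proto <- benchmark_protocol(seeds, operators = c("SF-T", "SM-T"),
                              budgets = 1L, rng_seed = 7L)
  rep <- run_benchmark(proto, progress = FALSE)
  out <- tempfile()
  files <- write_report(rep, out)
  expect_true(file.exists(file.path(out, "summary.csv")))
  back <- read_table(file.path(out, "summary.csv"))
  expect_equal(back$validity_percent, rep$summary$validity_percent)
  expect_equal(back$molecules, rep$summary$molecules)
  ranks <- read_table(file.path(out, "ranks.csv"))
  expect_true(all(c("operator", "speed", "validity") %in% names(ranks)))
  cfg <- jsonlite::read_json(file.path(out, "run_config.json"))
  expect_equal(cfg$n_seeds, 30L)
  unlink(out, recursive = TRUE)
})

test_that("identical protocols reproduce identical mutants and aggregates", {
  seeds <- fixture_seeds(25, rng_seed = 501L)
  proto <- benchmark_protocol(seeds, budgets = c(1L, 3L), rng_seed = 4242L)
  r1 <- run_benchmark(proto, progress = FALSE)
  r2 <- run_benchmark(proto, progress = FALSE)
  # timing excluded from the comparison
  drop_time <- function(x) {
    x$summary$time_s <- NULL
    x$summary$mol_per_s <- NULL
    x[c("summary", "complexity_deltas", "potency_shifts", "similarity",
        "kl_descriptors", "mean_signed_dMW", "mutant_smiles")]
  }
  expect_identical(drop_time(r1), drop_time(r2))
})
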