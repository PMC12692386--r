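# QSAR tests run on a reduced table (n = 200) to keep the unit suite
# fast; the full n = 2000 parameter-recovery experiment lives with the
# acceptance checks.

fixture_activity <- function(n = 200L) {
  if (is.null(.fixture_env$activity)) {
    .fixture_env$activity <- generate_activity_dataset(n, rng_seed = 77L)
  }
  .fixture_env$activity
}

test_that("training handles duplicates, bad rows and degenerate targets", {
  tab <- fixture_activity()
  # duplicate SMILES averaged: append a duplicate with a different label
  tab2 <- rbind(tab, data.frame(smiles = tab$smiles[1],
                                pIC50 = tab$pIC50[1] + 2))
  m <- train_qsar(tab2, seed = 3L, num_trees = 100L)
  expect_s3_class(m, "qsar_model")
  expect_identical(m$train_summary$n, length(unique(tab$smiles)))
  # unparseable rows dropped with a count
  tab3 <- rbind(tab, data.frame(smiles = c("C1CC", "xyz"), pIC50 = c(5, 6)))
  m3 <- train_qsar(tab3, seed = 3L, num_trees = 100L)
  expect_identical(m3$train_summary$n_dropped, 2L)
  # too few rows
  expect_error(train_qsar(tab[1:20, ], seed = 1L), "too-few-rows")
  # constant target: predictions collapse to that constant
  tabc <- tab
  tabc$pIC50 <- 7.5
  mc <- train_qsar(tabc, seed = 3L, num_trees = 100L)
  pr <- predict_pic50(mc, lapply(tab$smiles[1:10], parse_and_sanitize))
  expect_true(all(abs(pr - 7.5) < 1e-6))
})

test_that("prediction is deterministic, range-bounded and fingerprint-driven", {
  tab <- fixture_activity()
  m1 <- train_qsar(tab, seed = 11L, num_trees = 100L)
  m2 <- train_qsar(tab, seed = 11L, num_trees = 100L)
  probe <- lapply(tab$smiles[1:25], parse_and_sanitize)
  expect_identical(predict_pic50(m1, probe), predict_pic50(m2, probe))
  # tree-ensemble predictions stay inside the training target range
  pr <- predict_pic50(m1, probe)
  expect_true(all(pr >= min(tab$pIC50) - 1e-9))
  expect_true(all(pr <= max(tab$pIC50) + 1e-9))
  # identical fingerprints (same canonical molecule) -> identical prediction
  a <- parse_and_sanitize("OCC")
  b <- parse_and_sanitize("CCO")
  expect_identical(predict_pic50(m1, a), predict_pic50(m1, b))
  expect_error(predict_pic50(m1, parse_and_sanitize("C1CC")), "invalid")
})

test_that("potency shifts are absolute, symmetric and zero for identity", {
  tab <- fixture_activity()
  m <- train_qsar(tab, seed = 11L, num_trees = 100L)
  p <- parse_and_sanitize(tab$smiles[1], "p")
  ident <- potency_shift(m, p, parse_and_sanitize(tab$smiles[1], "m"))
  expect_equal(ident$abs_delta, 0)
  q <- parse_and_sanitize(tab$smiles[2], "q")
  s1 <- potency_shift(m, p, q)
  s2 <- potency_shift(m, q, p)
  expect_equal(s1$abs_delta, s2$abs_delta)
  expect_gte(s1$abs_delta, 0)
  expect_equal(s1$abs_delta, abs(s1$pIC50_parent - s1$pIC50_mutant))
  # arithmetic: predictions 6.1 and 5.7 differ by 0.4
  expect_equal(abs(6.1 - 5.7), 0.4)
  bad <- parse_and_sanitize("C1CC")
  expect_error(potency_shift(m, p, bad), "valid")
})

test_that("the synthetic oracle clips, repeats and respects zero noise", {
  tab <- fixture_activity()
  params <- attr(tab, "params")
  expect_true(all(tab$pIC50 >= 2 & tab$pIC50 <= 12))
  p0 <- params
  p0$sigma <- 0
  r <- parse_and_sanitize(tab$smiles[5])
  v1 <- synthetic_activity_oracle(r, p0)
  v2 <- synthetic_activity_oracle(r, p0)
  expect_identical(v1, v2)
  # equal descriptors imply equal noiseless scores
  d <- descriptor_vector(r)
  expect_identical(synthetic_activity_oracle(r, p0, descriptors = d),
                   synthetic_activity_oracle(r, p0, descriptors = d))
  # dataset generation is deterministic under a fixed seed
  t1 <- generate_activity_dataset(50, rng_seed = 123L)
  t2 <- generate_activity_dataset(50, rng_seed = 123L)
  expect_identical(t1$smiles, t2$smiles)
  expect_identical(t1$pIC50, t2$pIC50)
  expect_error(generate_activity_dataset(49), "n >= 50")
})
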