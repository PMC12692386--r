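test_that("token edits follow the uniform edit model", {
  seq <- token_sequence("SMILES", c("C", "C", "O"))
  ab <- default_alphabet("SMILES")
  # mechanics: forced single edits
  set.seed(4)
  kinds <- character(0)
  for (i in 1:3000) {
    ed <- mutate_token_sequence(seq, ab)
    kinds <- c(kinds, sub(" .*", "", ed$trace))
    L <- length(ed$seq$tokens)
    expect_true(L %in% c(2L, 3L, 4L))
    if (L == 3L) { # replacement never reproduces the original symbol
      changed <- which(ed$seq$tokens != seq$tokens)
      expect_length(changed, 1L)
    }
  }
  # edit kinds uniform at 1/3 (chi-square well inside critical value)
  freq <- table(factor(kinds, levels = c("insert", "replace", "delete"))) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.03))

  # degenerate cases
  set.seed(9)
  one <- token_sequence("SMILES", "C")
  repeat {
    ed <- mutate_token_sequence(one, ab)
    if (length(ed$seq$tokens) == 0L) break
  }
  expect_length(ed$seq$tokens, 0L)
  expect_error(mutate_token_sequence(token_sequence("SMILES", character()),
                                     ab), "empty")
})

test_that("SMILES token mutation edits from the 13-symbol alphabet without resampling", {
  p <- parse_and_sanitize("CCO", "p1")
  set.seed(21)
  allowed <- c(default_alphabet("SMILES")$symbols,
               tokenize_smiles("CCO")$tokens)
  for (i in 1:200) {
    m <- smiles_token_mutation(p)
    expect_identical(m$attempts, 1L)
    expect_s3_class(m, "mutation_record")
    toks <- tokenize_smiles(m$mutant_smiles)$tokens
    expect_true(all(toks %in% allowed), info = m$mutant_smiles)
    # external check honored: valid flag equals independent sanitization
    expect_identical(m$valid, parse_and_sanitize(m$mutant_smiles)$valid)
  }
  # an appended ring digit leaves an unclosed ring
  r <- parse_and_sanitize("CCO1")
  expect_false(r$valid)
  expect_identical(r$error, "unclosed-ring")
})

test_that("SELFIES token mutation keeps the grammar guarantee", {
  p <- parse_and_sanitize("CC(Cc1ccc2c(c1)OCO2)NC", "mdma")
  set.seed(31)
  n_empty <- 0L
  for (i in 1:300) {
    m <- selfies_token_mutation(p)
    if (!nzchar(m$mutant_smiles)) {
      n_empty <- n_empty + 1L
      expect_false(m$valid)
      expect_identical(m$error, "empty-input")
    } else {
      expect_true(m$valid, info = m$mutant_smiles)
    }
  }
  expect_lt(n_empty, 30L)
  # replace edits on a multi-token parent rarely reproduce the parent
  set.seed(32)
  diffs <- replicate(200, {
    m <- selfies_token_mutation(p)
    !identical(m$record$smiles_canonical, p$smiles_canonical)
  })
  expect_gt(mean(diffs), 0.9)
  # unencodable parent is an operator skip
  sk <- selfies_token_mutation(parse_and_sanitize("CCS", "s"))
  expect_false(sk$valid)
  expect_identical(sk$error, "operator-skip")
})

test_that("GB-GA rejects and resamples invalid candidates", {
  p <- parse_and_sanitize("CCO", "p1")
  set.seed(41)
  for (i in 1:100) {
    m <- graph_mutation_gbga(p)
    expect_lte(m$attempts, mutation_config("GB-GA")$resample_cap + 1L)
    if (m$valid) {
      expect_true(parse_and_sanitize(m$mutant_smiles)$valid)
    }
  }
  # emitted validity on the fixture population at cap 50
  seeds <- fixture_seeds()
  set.seed(42)
  ok <- vapply(seq_along(seeds), function(i) {
    cfg <- mutation_config("GB-GA", resample_cap = 50L,
                           rng_seed = 1000L + i)
    graph_mutation_gbga(seeds[[i]], cfg)$valid
  }, TRUE)
  expect_gte(mean(ok), 0.99)
  # determinism under a fixed seed
  cfg <- mutation_config("GB-GA", rng_seed = 77L)
  a <- graph_mutation_gbga(p, cfg)
  b <- graph_mutation_gbga(p, cfg)
  expect_identical(a$mutant_smiles, b$mutant_smiles)
  expect_identical(a$edit_trace, b$edit_trace)
})

test_that("edit probabilities are normalized, order-invariant and support-closed", {
  single <- estimate_edit_probabilities(list(parse_and_sanitize("CC")))
  expect_identical(names(single$attach), "C")
  expect_equal(single$attach$C$p, 1)
  expect_equal(single$attach$C$order, 1L)

  hydro <- estimate_edit_probabilities(
    lapply(c("CCC", "C=CC", "C1CCCCC1", "CC(C)C"), parse_and_sanitize))
  expect_true(all(unlist(lapply(hydro$attach, function(df) df$element)) == "C"))

  corpus <- fixture_seeds(100)
  tab <- estimate_edit_probabilities(corpus)
  for (ctx in names(tab$attach)) {
    expect_equal(sum(tab$attach[[ctx]]$p), 1, tolerance = 1e-9)
    expect_true(all(tab$attach[[ctx]]$p >= 0))
  }
  if (nrow(tab$ring_sizes)) {
    expect_equal(sum(tab$ring_sizes$p), 1, tolerance = 1e-9)
  }
  set.seed(5)
  tab2 <- estimate_edit_probabilities(corpus[sample(length(corpus))])
  expect_equal(tab[c("attach", "ring_sizes", "p_ring")],
               tab2[c("attach", "ring_sizes", "p_ring")])
  expect_error(estimate_edit_probabilities(list()), "empty")
})

test_that("GB-GM grows within the corpus support and is deterministic", {
  hydro <- estimate_edit_probabilities(
    lapply(c("CCC", "C=CC", "CC(C)C", "CCCC"), parse_and_sanitize))
  p <- parse_and_sanitize("CCO", "p1")
  set.seed(51)
  for (i in 1:50) {
    m <- graph_generative_mutation(p, hydro)
    if (m$valid) {
      added <- setdiff(tokenize_smiles(m$record$smiles_canonical)$tokens,
                       c("(", ")", "=", "#", as.character(1:9)))
      expect_true(all(added %in% c("C", "O")), info = m$mutant_smiles)
    }
  }
  # growth bias: heavy atoms never shrink, mostly grow
  tab <- fixture_edit_table()
  seeds <- fixture_seeds()
  set.seed(52)
  grown <- c()
  for (i in seq_along(seeds)) {
    cfg <- mutation_config("GB-GM", rng_seed = 7000L + i)
    m <- graph_generative_mutation(seeds[[i]], tab, cfg)
    if (m$valid) {
      grown <- c(grown, length(m$record$mol$atoms$element) >=
                   length(seeds[[i]]$mol$atoms$element))
    }
  }
  expect_gte(mean(grown), 0.9)
  cfg <- mutation_config("GB-GM", rng_seed = 99L)
  a <- graph_generative_mutation(p, tab, cfg)
  b <- graph_generative_mutation(p, tab, cfg)
  expect_identical(a$mutant_smiles, b$mutant_smiles)
})

test_that("reaction mutation applies templates with mass balance", {
  acid <- parse_and_sanitize("CCC(=O)O", "acid")
  tpl <- list(reaction_template("amide_coupling",
                                "[C:1](=[O:2])[OH1].[N!H0:3]>>[C:1](=[O:2])[N:3]",
                                "amine"))
  lib <- structure(list(amine = list(parse_and_sanitize("NCC", "bb"))),
                   class = "building_block_library")
  set.seed(61)
  m <- reaction_mutation(acid, tpl, lib)
  expect_true(m$valid)
  expect_match(m$record$smiles_canonical, "N")
  # condensation mass balance: product = parent + reagent - H2O
  mw <- function(r) molmutbench:::mol_weight(r$mol)
  expect_equal(mw(m$record), mw(acid) + mw(lib$amine[[1]]) - 18.015,
               tolerance = 0.01)
  # no matching functional group anywhere
  m2 <- reaction_mutation(parse_and_sanitize("CC(C)C", "h"), tpl, lib)
  expect_false(m2$valid)
  expect_identical(m2$error, "no-template-match")
  # packaged set: mean MW change of valid mutants is positive (additive)
  seeds <- fixture_seeds()
  set.seed(62)
  dmw <- c()
  for (i in seq_along(seeds)) {
    cfg <- mutation_config("SCC", rng_seed = 3000L + i)
    mm <- reaction_mutation(seeds[[i]], cfg = cfg)
    if (mm$valid) dmw <- c(dmw, mw(mm$record) - mw(seeds[[i]]))
  }
  expect_gt(length(dmw), 30)
  expect_gt(mean(dmw), 0)
})

test_that("generate_mutants honors the budget contract and determinism", {
  p <- parse_and_sanitize("CC(=O)O", "p1")
  cfg <- mutation_config("SM-T", rng_seed = 123L)
  m5 <- generate_mutants(p, cfg, k = 5L)
  expect_length(m5, 5L)
  m5b <- generate_mutants(p, cfg, k = 5L)
  expect_identical(vapply(m5, function(m) m$mutant_smiles, ""),
                   vapply(m5b, function(m) m$mutant_smiles, ""))
  # operator-skip still yields k records
  sk <- generate_mutants(parse_and_sanitize("CCS", "s"),
                         mutation_config("SF-T", rng_seed = 5L), k = 3L)
  expect_length(sk, 3L)
  expect_true(all(!vapply(sk, function(m) m$valid, TRUE)))
  # validity denominator convention: valid / (n * k)
  seeds <- fixture_seeds()[1:100]
  recs <- unlist(lapply(seq_along(seeds), function(i) {
    generate_mutants(seeds[[i]], mutation_config("SM-T", rng_seed = i), k = 3L)
  }), recursive = FALSE)
  expect_length(recs, 300L)
  v <- sum(vapply(recs, function(m) m$valid, TRUE))
  expect_equal(summarize_population(v, 300L, 1)$validity_percent, 100 * v / 300)
})

test_that("every mutation record's valid flag matches external sanitization", {
  seeds <- fixture_seeds()[1:40]
  tab <- fixture_edit_table()
  set.seed(81)
  for (op in c("SM-T", "SF-T", "GB-GA", "GB-GM", "SCC")) {
    for (i in seq_len(20)) {
      cfg <- mutation_config(op, rng_seed = 400L + i)
      m <- generate_mutants(seeds[[i]], cfg, k = 1L, table = tab)[[1]]
      ext <- parse_and_sanitize(m$mutant_smiles)
      expect_identical(m$valid && m$error %in% NA_character_,
                       ext$valid && isTRUE(m$valid),
                       info = paste(op, m$mutant_smiles))
      if (nzchar(m$mutant_smiles) && is.na(m$error)) {
        expect_identical(m$valid, ext$valid, info = paste(op, m$mutant_smiles))
      }
    }
  }
})
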