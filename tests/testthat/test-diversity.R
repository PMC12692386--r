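test_that("Tanimoto similarity is bounded, symmetric and self-identical", {
  recs <- fixture_records()
  fps <- lapply(recs, fingerprint)
  for (i in seq_along(fps)) {
    expect_equal(tanimoto(fps[[i]], fps[[i]]), 1)
  }
  set.seed(12)
  for (rep in 1:30) {
    ij <- sample(length(fps), 2L)
    s1 <- tanimoto(fps[[ij[1]]], fps[[ij[2]]])
    s2 <- tanimoto(fps[[ij[2]]], fps[[ij[1]]])
    expect_identical(s1, s2)
    expect_gte(s1, 0)
    expect_lte(s1, 1)
  }
  # formula arithmetic: |A^B|=2, |A|=|B|=3 -> 0.5
  a <- integer(16); a[c(1, 2, 3)] <- 1L
  b <- integer(16); b[c(2, 3, 4)] <- 1L
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, integer(16) + c(0L, 0L, 0L, 0L, 1L, rep(0L, 11))), 0)
  expect_warning(z <- tanimoto(integer(8), integer(8)), "empty")
  expect_equal(z, 1)
  # identical canonical SMILES give identical fingerprints
  expect_identical(fingerprint(parse_and_sanitize("OCC")),
                   fingerprint(parse_and_sanitize("CCO")))
})

test_that("pairwise similarity CDF enumerates all unordered pairs monotonically", {
  recs <- fixture_seeds(30)[1:4]
  cdf <- pairwise_similarity_cdf(recs)
  expect_identical(nrow(cdf), 6L)
  expect_true(all(diff(cdf$cdf) >= 0))
  expect_equal(cdf$cdf[nrow(cdf)], 1)
  same <- replicate(3, parse_and_sanitize("CCO"), simplify = FALSE)
  cdf2 <- pairwise_similarity_cdf(same)
  expect_true(all(cdf2$similarity == 1))
  expect_error(pairwise_similarity_cdf(recs[1]), "two")
})

test_that("parent-mutant similarity summarises aligned valid pairs", {
  recs <- fixture_seeds(30)[1:10]
  ident <- parent_mutant_similarity(recs, recs)
  expect_equal(ident$mean, 1)
  expect_identical(ident$n_pairs, 10L)
  mixed <- recs
  mixed[[3]] <- parse_and_sanitize("C1CC", "broken")
  ps <- parent_mutant_similarity(recs, mixed)
  expect_identical(ps$n_pairs, 9L)
  expect_length(ps$similarities, 9L)
})

test_that("PCA is orthonormal with non-increasing standardized variance", {
  set.seed(33)
  X <- matrix(rnorm(40 * 9), 40, 9)
  colnames(X) <- paste0("d", 1:9)
  pc <- pca_fit(X)
  expect_equal(t(pc$loadings) %*% pc$loadings, diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$explained_variance_ratio) <= 1e-12))
  expect_true(all(pc$explained_variance_ratio >= 0 &
                    pc$explained_variance_ratio <= 1))
  # rank-1 data: first component explains essentially everything
  t_line <- rnorm(40)
  X1 <- outer(t_line, seq_len(9)) + matrix(rnorm(40 * 9, sd = 1e-6), 40, 9)
  pc1 <- pca_fit(X1)
  expect_gte(pc1$explained_variance_ratio[1], 0.999)
  # reconstruction: scores %*% t(loadings) approximates standardized data
  Z <- scale(X)
  full <- pca_fit(X, n_components = 9L)
  recon <- full$scores %*% t(full$loadings)
  expect_lt(norm(Z - recon, "F") / norm(Z, "F"), 1e-8)
  # zero-variance column dropped with a warning
  X2 <- cbind(X, constant = 5)
  expect_warning(pc2 <- pca_fit(X2), "zero-variance")
  expect_identical(pc2$dropped, "constant")
})

test_that("KL divergence matches hand arithmetic and is asymmetric", {
  # two-bin case P=(0.5,0.5), Q=(0.9,0.1)
  p_sample <- c(rep(0.25, 5), rep(0.75, 5))
  q_sample <- c(rep(0.25, 9), 0.75)
  kl <- kl_divergence(p_sample, q_sample, n_bins = 2L)
  expect_equal(kl$value, 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-3)
  rev <- kl_divergence(q_sample, p_sample, n_bins = 2L)
  expect_equal(rev$value, 0.9 * log(0.9 / 0.5) + 0.1 * log(0.1 / 0.5),
               tolerance = 1e-3)
  expect_false(isTRUE(all.equal(kl$value, rev$value)))
  # identical samples: exactly zero
  expect_equal(kl_divergence(p_sample, p_sample)$value, 0)
  # non-negativity over random sample pairs
  set.seed(44)
  for (i in 1:200) {
    a <- rnorm(60, sample(-2:2, 1), runif(1, 0.5, 2))
    b <- rnorm(60, sample(-2:2, 1), runif(1, 0.5, 2))
    expect_gte(kl_divergence(a, b)$value, 0)
  }
  expect_error(kl_divergence(numeric(), 1:3), "non-empty")
  expect_error(kl_divergence(c(1, NA), 1:3), "finite")
})

test_that("smoothed histogram KL approaches the Gaussian closed form", {
  # D(N(0,1) || N(mu,1)) = mu^2 / 2
  set.seed(55)
  n <- 1e5
  mu <- 1
  est <- kl_divergence(rnorm(n, 0, 1), rnorm(n, mu, 1), n_bins = 50L)
  expect_equal(est$value, mu^2 / 2, tolerance = 0.05)
})

test_that("descriptor vectors are deterministic and chemically sensible", {
  eth <- descriptor_vector(parse_and_sanitize("CC"))
  expect_equal(unname(eth["NRE"]), 0)
  expect_equal(unname(eth["NRB"]), 0)
  but <- descriptor_vector(parse_and_sanitize("CCCC"))
  expect_equal(unname(but["NRB"]), 1)
  benz <- descriptor_vector(parse_and_sanitize("c1ccccc1"))
  expect_equal(unname(benz["TPSA"]), 0)
  expect_equal(unname(benz["NVE"]), 30) # 6C*4 + 6H*1
  d1 <- descriptor_vector(parse_and_sanitize("OCC(N)CO"))
  d2 <- descriptor_vector(parse_and_sanitize("C(O)C(N)CO"))
  expect_identical(d1, d2)
  # Lipinski donor/acceptor counts
  gly <- descriptor_vector(parse_and_sanitize("NCC(=O)O"))
  expect_equal(unname(gly["NHA"]), 3)
  expect_equal(unname(gly["NHD"]), 2)
})
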