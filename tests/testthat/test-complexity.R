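test_that("Wiener index matches the all-pairs shortest-path oracle", {
  skip_if_not_installed("igraph")
  expect_equal(wiener_index(parse_and_sanitize("C")), 0)
  expect_equal(wiener_index(parse_and_sanitize("CCC")), 4)
  expect_equal(wiener_index(parse_and_sanitize("c1ccccc1")), 27)
  for (r in fixture_seeds(100)) {
    if (length(unique(molmutbench:::components(r$mol))) > 1L) next
    expect_identical(wiener_index(r), wiener_oracle_igraph(r), info = r$id)
  }
  expect_error(wiener_index(parse_and_sanitize("CC.O")), "disconnected")
})

test_that("degree-factorial Bertz matches the independent adjacency-list sum", {
  expect_equal(bertz_index_degree(parse_and_sanitize("C")), 0)
  expect_equal(bertz_index_degree(parse_and_sanitize("CCC")), log(2))
  expect_equal(bertz_index_degree(parse_and_sanitize("CC(C)(C)C")), log(24))
  for (r in fixture_seeds(100)) {
    expect_equal(bertz_index_degree(r), bertz_oracle(r), tolerance = 1e-9,
                 info = r$id)
  }
})

test_that("PCI combines logP with the acceptor-donor excess linearly", {
  # NHA = NHD cancels the hydrogen-bond term
  eth <- parse_and_sanitize("CCO") # one O with H: NHA 1, NHD 1
  ob <- data.frame(logP = 2.0, TPSA = 20)
  expect_equal(pci(eth, ob = ob), 2.0)
  # molecule with logP 2, NHA 3, NHD 1 under the default (1, 1) weights
  tri <- parse_and_sanitize("COCOCO") # 3 O, one terminal OH
  expect_equal(unname(pci(tri, ob = ob)), 2.0 + (3 - 1))
  # one extra acceptor at fixed logP raises PCI by exactly 1
  four <- parse_and_sanitize("COCOCOC")
  expect_equal(unname(pci(four, ob = ob) - pci(tri, ob = ob)), 1)
  # weights configurable
  expect_equal(unname(pci(tri, w_logp = 2, w_hb = 0.5, ob = ob)), 4 + 1)
})

test_that("complexity profiles carry the ten documented fields", {
  eth <- complexity_profile(parse_and_sanitize("CCO"))
  expect_named(eth, c("MW", "NR", "NH", "QCF", "HCF", "BI", "HI", "WI",
                      "QED", "PCI"))
  expect_equal(unname(eth["HCF"]), 1)
  expect_equal(unname(eth["QCF"]), 0)
  expect_equal(unname(eth["NH"]), 1)
  expect_equal(unname(eth["NR"]), 0)
  benz <- complexity_profile(parse_and_sanitize("c1ccccc1"))
  expect_equal(unname(benz["HCF"]), 0)
  expect_equal(unname(benz["NR"]), 1)
  expect_equal(unname(benz["NH"]), 0)
  hex <- complexity_profile(parse_and_sanitize("C1CCCCC1"))
  expect_equal(unname(hex["MW"]), 84.16, tolerance = 1e-3)
  # a chiral center: bromochlorofluoromethane analogue in CNOF chemistry
  chiral <- complexity_profile(parse_and_sanitize("CC(N)(O)F"))
  expect_equal(unname(chiral["QCF"]), 0.5) # 1 chiral of 2 carbons
  # QED strictly inside (0, 1) on every fixture
  for (r in fixture_records()) {
    q <- qed(r)
    expect_true(q > 0 && q < 1, info = r$id)
  }
})

test_that("delta summaries use the magnitude-only convention", {
  p <- parse_and_sanitize("CCO", "a")
  m_same <- parse_and_sanitize("CCO", "a2")
  ds <- delta_summary(list(p), list(m_same))
  expect_true(all(ds$mean_abs_delta == 0))
  expect_identical(ds$n_pairs, 1L)

  m_big <- parse_and_sanitize("CCCCO", "a3")
  ds2 <- delta_summary(list(p), list(m_big), fields = "MW")
  expect_equal(unname(ds2$mean_abs_delta["MW"]), 2 * 14.027, tolerance = 1e-3)

  # direction is discarded: |-d| and |+d| average to d
  p2 <- parse_and_sanitize("CCCC", "b")
  up <- parse_and_sanitize("CCCCC", "b2")   # +CH2
  down <- parse_and_sanitize("CCC", "b3")   # -CH2
  ds3 <- delta_summary(list(p2, p2), list(up, down), fields = "MW")
  expect_equal(unname(ds3$mean_abs_delta["MW"]), 14.027, tolerance = 1e-3)

  # invalid mutants are excluded; all-invalid errors out
  bad <- parse_and_sanitize("C1CC", "bad")
  ds4 <- delta_summary(list(p, p), list(m_same, bad))
  expect_identical(ds4$n_pairs, 1L)
  expect_error(delta_summary(list(p), list(bad)), "empty-aggregate")
})
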