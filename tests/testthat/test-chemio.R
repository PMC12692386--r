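test_that("parse_and_sanitize classifies well-formed and malformed input", {
  ok <- parse_and_sanitize("CCO")
  expect_true(ok$valid)
  expect_identical(ok$smiles_canonical, "CCO")
  expect_true(is.na(ok$error))

  cases <- list(
    list("C1CC", "unclosed-ring"),
    list("C(C)(C)(C)(C)C", "valence"),
    list("", "empty-input"),
    list("C((C)C", "syntax"),
    list("CC)", "syntax"),
    list("C=", "syntax"),
    list("C$C", "syntax"),
    list("cc", "kekulize")
  )
  for (cs in cases) {
    r <- parse_and_sanitize(cs[[1]])
    expect_false(r$valid, info = cs[[1]])
    expect_identical(r$error, cs[[2]], info = cs[[1]])
  }
  # never raises, whatever the input
  expect_s3_class(parse_and_sanitize(NA_character_), "molecule_record")
  expect_s3_class(parse_and_sanitize("[[["), "molecule_record")
})

test_that("canonicalization is idempotent and invariant to the input writing", {
  for (r in fixture_records()) {
    expect_true(r$valid, info = r$id)
    again <- parse_and_sanitize(r$smiles_canonical)
    expect_identical(again$smiles_canonical, r$smiles_canonical, info = r$id)
  }
  same <- list(
    c("OCC", "CCO"),
    c("c1ccccc1", "C1=CC=CC=C1"),
    c("c1ccc2ccccc2c1", "C1=CC2=CC=CC=C2C=C1"),
    c("CC(Cc1ccc2c(c1)OCO2)NC", "CNC(C)Cc1ccc2OCOc2c1"),
    c("CC(=O)O", "OC(C)=O"),
    c("C(F)(F)F", "FC(F)F")
  )
  for (pair in same) {
    a <- parse_and_sanitize(pair[1])
    b <- parse_and_sanitize(pair[2])
    expect_identical(a$smiles_canonical, b$smiles_canonical,
                     info = paste(pair, collapse = " vs "))
  }
  expect_error(canonicalize(parse_and_sanitize("C1CC")), "invalid")
})

test_that("canonical SMILES is invariant to atom storage permutations", {
  set.seed(71)
  mols <- fixture_seeds(60)
  for (r in mols[1:40]) {
    mol <- r$mol
    n <- length(mol$atoms$element)
    if (n < 3) next
    perm <- sample.int(n)
    inv <- integer(n); inv[perm] <- seq_len(n)
    pm <- mol
    pm$atoms <- lapply(mol$atoms, function(v) v[perm])
    pm$bonds$a <- inv[mol$bonds$a]
    pm$bonds$b <- inv[mol$bonds$b]
    class(pm) <- "molgraph"
    out <- parse_and_sanitize(molmutbench:::write_canonical_smiles(pm))
    expect_identical(out$smiles_canonical, r$smiles_canonical, info = r$id)
  }
})

test_that("SMILES tokenizer lexes atoms, bonds, branches and ring digits", {
  expect_identical(tokenize_smiles("C(=O)N")$tokens,
                   c("C", "(", "=", "O", ")", "N"))
  expect_length(tokenize_smiles("c1ccccc1")$tokens, 8L)
  expect_identical(tokenize_smiles("CCl")$tokens, c("C", "Cl"))
  expect_identical(tokenize_smiles("C%12CC%12")$tokens,
                   c("C", "%12", "C", "C", "%12"))
  expect_identical(tokenize_smiles("[nH]1cccc1")$tokens[1], "[nH]")
  # joining reproduces the input byte-for-byte on random valid SMILES
  for (r in fixture_seeds(100)) {
    s <- r$smiles_canonical
    expect_identical(join_tokens(tokenize_smiles(s)), s)
  }
})

test_that("SELFIES decoding is grammatically safe and encoding round-trips", {
  # round trip on curated and generated molecules
  for (r in fixture_records()) {
    if (!all(r$mol$atoms$element %in% c("C", "N", "O", "F"))) next
    seq <- encode_selfies(r)
    expect_identical(parse_and_sanitize(decode_selfies(seq))$smiles_canonical,
                     r$smiles_canonical, info = r$id)
  }
  for (r in fixture_seeds(80)) {
    seq <- encode_selfies(r)
    expect_identical(parse_and_sanitize(decode_selfies(seq))$smiles_canonical,
                     r$smiles_canonical, info = r$id)
  }
  # 500 random token sequences (lengths 1-30): every non-empty decode valid
  set.seed(902)
  ab <- default_alphabet("SELFIES")$symbols
  n_nonempty <- 0L
  for (i in 1:500) {
    toks <- sample(ab, sample(1:30, 1L), replace = TRUE)
    smi <- decode_selfies(toks)
    if (!nzchar(smi)) next
    n_nonempty <- n_nonempty + 1L
    expect_true(parse_and_sanitize(smi)$valid,
                info = paste(toks, collapse = ""))
  }
  expect_gt(n_nonempty, 350L)
  # degenerate cases
  expect_identical(decode_selfies(token_sequence("SELFIES", character())), "")
  expect_false(parse_and_sanitize(decode_selfies(character()))$valid)
  expect_error(encode_selfies("CCS"), "C/N/O/F")
})

test_that("smi and csv files round-trip with line-number id defaults", {
  recs <- fixture_seeds(10)
  smi <- tempfile(fileext = ".smi")
  write_smiles_file(recs, smi)
  back <- read_smiles_file(smi)
  expect_identical(vapply(back, function(r) r$smiles_canonical, ""),
                   vapply(recs, function(r) r$smiles_canonical, ""))
  expect_identical(vapply(back, function(r) r$id, ""),
                   vapply(recs, function(r) r$id, ""))

  writeLines(c("# comment", "CCO\tmol7", "CCN", ""), smi)
  got <- read_smiles_file(smi)
  expect_identical(vapply(got, function(r) r$id, ""), c("mol7", "m3"))

  writeLines(character(), smi)
  expect_length(read_smiles_file(smi), 0L)

  csv <- tempfile(fileext = ".csv")
  df <- data.frame(smiles = c("CCO", "CCN"), pIC50 = c(6.1, 5.2))
  write_table(df, csv)
  expect_equal(read_table(csv), df)
  unlink(c(smi, csv))
})
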