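test_that("fingerprints have the configured length and canonical invariance", {
  fp <- morgan_fingerprint("CCO")
  expect_length(fp, 1024)
  expect_true(all(fp %in% 0:1))
  expect_gte(sum(fp), 1)
  # same molecule, different SMILES spellings
  expect_identical(morgan_fingerprint("CCO"), morgan_fingerprint("OCC"))
  # a single carbon still sets at least one bit
  expect_gte(sum(morgan_fingerprint("C")), 1)
  # configurable length
  expect_length(morgan_fingerprint("CCO", n_bits = 512), 512)
  expect_error(morgan_fingerprint("C((("), "invalid SMILES")
})

test_that("combination merge is the size-preserving bitwise union", {
  expect_identical(merge_combination(list(c(1, 0, 0), c(0, 1, 0))),
                   c(1L, 1L, 0L))
  fp <- morgan_fingerprint("CCO")
  expect_identical(merge_combination(list(fp, fp)), fp)   # idempotent
  expect_error(merge_combination(list(c(1, 0), c(1, 0, 0))), "lengths differ")
  # set-arithmetic bounds on random vectors
  m <- random_bits(20, 64, seed = 5)
  for (i in seq(1, 19, by = 2)) {
    a <- m[i, ]; b <- m[i + 1, ]
    mg <- merge_combination(list(a, b))
    expect_gte(sum(mg), max(sum(a), sum(b)))
    expect_lte(sum(mg), sum(a) + sum(b))
    expect_identical(which(mg == 1), sort(union(which(a == 1), which(b == 1))))
  }
  # commutative + associative
  a <- m[1, ]; b <- m[2, ]; c <- m[3, ]
  expect_identical(merge_combination(list(a, b)), merge_combination(list(b, a)))
  expect_identical(merge_combination(list(merge_combination(list(a, b)), c)),
                   merge_combination(list(a, merge_combination(list(b, c)))))
  # a combination product's fingerprint is its components' union
  expect_identical(morgan_fingerprint(c("CCO", "CCN")),
                   merge_combination(list(morgan_fingerprint("CCO"),
                                          morgan_fingerprint("CCN"))))
})

test_that("tanimoto matches the set-arithmetic oracle on random vectors", {
  expect_identical(tanimoto(c(1, 0, 1, 1, 0), c(0, 1, 1, 1, 0)), 0.5)
  m <- random_bits(2000, 128, seed = 9)
  for (i in seq(1, 1999, by = 2)) {
    a <- m[i, ]; b <- m[i + 1, ]
    expect_equal(tanimoto(a, b), oracle_tanimoto(a, b), tolerance = 1e-12)
  }
})

test_that("tanimoto is symmetric, bounded, and 1 iff equal bit sets", {
  m <- random_bits(100, 64, seed = 13)
  for (i in seq(1, 99, by = 2)) {
    a <- m[i, ]; b <- m[i + 1, ]
    t1 <- tanimoto(a, b)
    expect_identical(t1, tanimoto(b, a))
    expect_gte(t1, 0); expect_lte(t1, 1)
    if (sum(a) > 0) expect_identical(tanimoto(a, a), 1)
    if (t1 == 1) expect_identical(a, b)
  }
  expect_identical(tanimoto(c(1, 0), c(0, 1)), 0)  # disjoint
  expect_warning(z <- tanimoto(c(0, 0), c(0, 0)), "all-zero")
  expect_identical(z, 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 0)), "length mismatch")
})

test_that("reference panel is deterministic, ordered, and self-similar", {
  drugs <- toy_drugs()
  panel <- build_reference_panel(drugs)
  expect_identical(length(panel), nrow(drugs))
  expect_identical(panel$drug_id, sort(drugs$drug_id, method = "radix"))
  panel2 <- build_reference_panel(drugs[sample(nrow(drugs)), ])
  expect_identical(panel$drug_id, panel2$drug_id)
  expect_identical(panel$fingerprints, panel2$fingerprints)
  # querying a member yields 1.0 at its own position
  for (i in c(1, 5, 9)) {
    prof <- similarity_profile(panel$fingerprints[i, ], panel)
    expect_identical(unname(prof[i]), 1)
    expect_true(all(prof >= 0 & prof <= 1))
  }
  expect_error(build_reference_panel(drugs[0, ]), "0 drugs")
  expect_error(similarity_profile(c(1, 0), panel), "does not match")
})

test_that("profiles of structurally identical drugs are identical", {
  drugs <- toy_drugs()
  panel <- build_reference_panel(drugs)
  p1 <- similarity_profile(morgan_fingerprint("CCO"), panel)
  p2 <- similarity_profile(morgan_fingerprint("OCC"), panel)
  expect_identical(p1, p2)
})

test_that("panel CSV persistence round-trips fingerprints exactly", {
  panel <- build_reference_panel(toy_drugs())
  path <- withr::local_tempfile(fileext = ".csv")
  arvddi:::write_panel(panel, path)
  back <- arvddi:::read_panel(path)
  expect_identical(back$drug_id, panel$drug_id)
  expect_identical(unname(back$fingerprints), unname(panel$fingerprints))
})

test_that("pair features concatenate ARV first and swap with the drugs", {
  drugs <- toy_drugs()
  panel <- build_reference_panel(drugs)
  ftz <- featurizer("similarity", panel = panel)
  R <- length(panel)
  expect_identical(feature_length(ftz), 2L * R)
  fwd <- pair_features(tibble::tibble(arv_id = "A02", comed_id = "C03"),
                       drugs, ftz)
  rev <- pair_features(tibble::tibble(arv_id = "C03", comed_id = "A02"),
                       drugs, ftz)
  expect_identical(fwd[1, seq_len(R)], rev[1, R + seq_len(R)])
  expect_identical(fwd[1, R + seq_len(R)], rev[1, seq_len(R)])
  expect_error(pair_features(tibble::tibble(arv_id = "A02", comed_id = "zz"),
                             drugs, ftz), "unknown drug id")
})

test_that("embedding stub is a deterministic 768-vector distinguishing molecules", {
  e1 <- embed_smiles_stub("CCO")
  expect_length(e1, 768)
  expect_identical(e1, embed_smiles_stub("OCC"))   # same molecule
  # different molecules give different embeddings
  smi <- toy_smiles()
  embs <- vapply(smi, embed_smiles_stub, numeric(768))
  expect_identical(ncol(unique(t(embs))), 768L)
  expect_identical(nrow(unique(t(embs), MARGIN = 1)), length(smi))
  # stub featurizer produces pair features of length 1536
  ftz <- featurizer("embedding-stub")
  expect_identical(feature_length(ftz), 1536L)
  x <- pair_features(tibble::tibble(arv_id = "A01", comed_id = "C01"),
                     toy_drugs(), ftz)
  expect_identical(ncol(x), 1536L)
})

test_that("similarity backend refuses to run without a panel", {
  expect_error(featurizer("similarity"), "requires a reference panel")
  expect_error(featurizer("embedding-external"), "embed_fun")
})

test_that("an external embedding adapter runs behind the featurizer contract", {
  embed_fun <- function(components) rep(length(components), 768)
  ftz <- featurizer("embedding-external", embed_fun = embed_fun)
  expect_identical(feature_length(ftz), 1536L)
  x <- pair_features(tibble::tibble(arv_id = "A01", comed_id = "C02"),
                     toy_drugs(), ftz)
  # A01 is the 2-component combination, C02 a single agent
  expect_identical(unname(x[1, c(1, 769)]), c(2, 1))
})

test_that("stub embeddings separate a hundred generated molecules", {
  drugs <- universe_10x100()
  smi <- unlist(drugs$components)
  embs <- t(vapply(smi, embed_smiles_stub, numeric(768)))
  expect_identical(nrow(unique(embs)), length(smi))
})
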