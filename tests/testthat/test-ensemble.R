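test_that("network presets reproduce the two optimized architectures", {
  sim <- network_spec("sim")
  expect_identical(sim$hidden, c(1024L, 512L, 256L, 128L))
  expect_identical(sim$activation, "relu")
  emb <- network_spec("embedding")
  expect_identical(emb$hidden, c(256L, 128L))
  expect_identical(emb$activation, "tanh")
  for (s in list(sim, emb)) {
    expect_identical(s$n_classes, 4L)
    expect_identical(s$dropout, 0.2)
    expect_identical(s$learning_rate, 0.001)
    expect_identical(c(s$beta1, s$beta2, s$epsilon), c(0.9, 0.999, 1e-7))
  }
  m <- build_network(sim, input_len = 1376, seed = 1)
  dims <- vapply(m$params, function(p) ncol(p$W), integer(1))
  expect_identical(dims, c(1024L, 512L, 256L, 128L, 4L))
  expect_identical(nrow(m$params[[1]]$W), 1376L)
})

test_that("forward pass emits probability vectors; same seed, same network", {
  spec <- network_spec(hidden = c(16, 8))
  m1 <- build_network(spec, 10, seed = 5)
  m2 <- build_network(spec, 10, seed = 5)
  x <- matrix(rnorm(30), 3, 10)
  p1 <- predict(m1, x)
  expect_identical(dim(p1), c(3L, 4L))
  expect_equal(rowSums(p1), rep(1, 3), tolerance = 1e-9)
  expect_true(all(p1 >= 0))
  expect_identical(p1, predict(m2, x))
  m3 <- build_network(spec, 10, seed = 6)
  expect_false(identical(p1, predict(m3, x)))
})

test_that("activation functions implement their stated formulas", {
  z <- c(-2, -0.5, 0, 0.5, 2)
  expect_identical(arvddi:::act_fun(z, "relu"), pmax(z, 0))
  expect_equal(arvddi:::act_fun(z, "tanh"),
               (exp(2 * z) - 1) / (exp(2 * z) + 1), tolerance = 1e-12)
})

test_that("class weights scale each sample's loss contribution linearly", {
  # fixed probabilities on a 4-sample batch, recomputed by hand
  probs <- matrix(c(0.7, 0.1, 0.1, 0.1,
                    0.2, 0.5, 0.2, 0.1,
                    0.1, 0.2, 0.6, 0.1,
                    0.4, 0.3, 0.2, 0.1), 4, 4, byrow = TRUE)
  y <- c(0L, 1L, 2L, 3L)
  base <- arvddi:::weighted_ce(probs, y, rep(1, 4))
  expect_equal(base, mean(-log(c(0.7, 0.5, 0.6, 0.1))), tolerance = 1e-12)
  # doubling one class's weight doubles its per-sample term
  w <- c(1, 1, 1, 2)
  expect_equal(arvddi:::weighted_ce(probs, y, w[y + 1]),
               mean(-log(c(0.7, 0.5, 0.6, 0.1)) * c(1, 1, 1, 2)),
               tolerance = 1e-12)
  # all-ones weights equal the unweighted loss by construction
  expect_equal(arvddi:::weighted_ce(probs, y, rep(1, 4)), base)
})

test_that("training fits linearly separable blobs to full accuracy", {
  withr::with_seed(21, {
    n <- 240
    y <- sample(0:3, n, replace = TRUE)
    x <- matrix(rnorm(n * 2, sd = 0.25), n, 2) +
      cbind(c(0, 3, 0, 3)[y + 1], c(0, 0, 3, 3)[y + 1])
  })
  spec <- network_spec(hidden = c(16), epochs = 200, dropout = 0,
                       batch_size = 64)
  m <- train_member(spec, x, y, seed = 4)
  acc <- mean(max.col(predict(m, x)) - 1 == y)
  expect_identical(acc, 1)
  expect_true(m$trained)
  expect_s3_class(m$history, "tbl_df")
})

test_that("training is deterministic given the seed", {
  withr::with_seed(8, {
    x <- matrix(rnorm(200), 50, 4)
    y <- sample(0:3, 50, replace = TRUE)
  })
  spec <- network_spec(hidden = c(8), epochs = 15)
  m1 <- train_member(spec, x, y, seed = 11)
  m2 <- train_member(spec, x, y, seed = 11)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("soft voting averages members and breaks ties toward severity", {
  members <- list(c(0.6, 0.2, 0.1, 0.1), c(0.2, 0.5, 0.2, 0.1),
                  c(0.1, 0.2, 0.6, 0.1), c(0.25, 0.25, 0.25, 0.25),
                  c(0.4, 0.3, 0.2, 0.1))
  v <- soft_vote(members)
  expect_equal(unname(v$prob[1, ]), c(0.31, 0.29, 0.27, 0.13),
               tolerance = 1e-12)
  expect_identical(as.character(v$predicted), "Green")
  # idempotence
  one <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(unname(soft_vote(list(one, one))$prob[1, ]), one,
               tolerance = 1e-12)
  # exact tie resolves to the more severe grade
  tie <- soft_vote(list(c(1, 0, 0, 0), c(0, 0, 0, 1)))
  expect_identical(as.character(tie$predicted), "Red")
  expect_error(soft_vote(list(c(0.5, 0.2, 0.2, 0.2))), "sum to 1")
  expect_error(soft_vote(list()), "at least one")
})

test_that("vote is simplex-preserving and invariant to member order", {
  withr::with_seed(17, {
    mats <- lapply(1:5, function(i) {
      m <- matrix(rexp(40), 10, 4)
      m / rowSums(m)
    })
  })
  v1 <- soft_vote(mats)
  expect_equal(rowSums(v1$prob), rep(1, 10), tolerance = 1e-9)
  v2 <- soft_vote(rev(mats))
  expect_equal(v1$prob, v2$prob, tolerance = 1e-12)
  expect_identical(v1$predicted, v2$predicted)
})

test_that("ensemble training wires partition, weights, and derived seeds", {
  drugs <- toy_drugs()
  pairs <- toy_pairs()
  spec <- network_spec(hidden = c(8), epochs = 8, dropout = 0)
  fit <- train_ensemble(pairs, drugs, k = 3, spec = spec, seed = 20)
  expect_s3_class(fit, "ddi_ensemble")
  expect_length(fit$members, 3)
  info <- tidy(fit)
  expect_identical(info$seed, 21:23)
  expect_identical(length(unique(info$n_train)), 1L)
  # members differ because their majority chunks differ
  x <- pair_features(pairs[1:5, ], drugs, fit$ftz)
  p1 <- predict(fit$members[[1]], x)
  p2 <- predict(fit$members[[2]], x)
  expect_false(identical(p1, p2))
  g <- glance(fit)
  expect_identical(g$k, 3)
  expect_identical(g$backend, "similarity")
  pred <- predict(fit, pairs, drugs)
  expect_named(pred, c("arv_id", "comed_id", "p_green", "p_yellow",
                       "p_amber", "p_red", "predicted"))
  expect_equal(pred$p_green + pred$p_yellow + pred$p_amber + pred$p_red,
               rep(1, nrow(pred)), tolerance = 1e-9)
})

test_that("k = 1 without weighting degenerates to a single plain classifier", {
  drugs <- toy_drugs()
  pairs <- toy_pairs()
  spec <- network_spec(hidden = c(8), epochs = 8, dropout = 0)
  single <- train_ensemble(pairs, drugs, k = 1, spec = spec, seed = 2,
                           class_weighting = FALSE)
  expect_length(single$members, 1)
  expect_identical(single$members[[1]]$class_weights, rep(1, 4))
  expect_identical(nrow(single$dropped), 0L)
  expect_identical(tidy(single)$n_train, nrow(pairs))
})

test_that("ensemble training refuses single-grade data", {
  drugs <- toy_drugs()
  pairs <- toy_pairs()
  pairs$grade <- as_grade(rep("Green", nrow(pairs)))
  expect_error(train_ensemble(pairs, drugs, k = 2), "at least 2 grades")
})

test_that("orientation augmentation doubles member data and changes the fit", {
  drugs <- toy_drugs()
  pairs <- toy_pairs()
  spec <- network_spec(hidden = c(8), epochs = 8, dropout = 0)
  plain <- train_ensemble(pairs, drugs, k = 2, spec = spec, seed = 6)
  both <- train_ensemble(pairs, drugs, k = 2, spec = spec, seed = 6,
                         both_orientations = TRUE)
  expect_identical(tidy(both)$n_train, 2L * tidy(plain)$n_train)
  p1 <- predict(plain, pairs[1:6, ], drugs, type = "prob")
  p2 <- predict(both, pairs[1:6, ], drugs, type = "prob")
  expect_false(identical(p1, p2))
})
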