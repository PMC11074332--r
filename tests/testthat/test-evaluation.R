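test_that("stratified folds preserve class balance within one pair", {
  pairs <- tibble::tibble(
    arv_id = sprintf("a%02d", 1:10), comed_id = sprintf("c%02d", 1:10),
    grade = as_grade(c(rep("Green", 8), rep("Red", 2)))
  )
  folded <- stratified_kfold(pairs, k = 2, seed = 1)
  for (f in 1:2) {
    tab <- table(folded$grade[folded$fold == f])
    expect_identical(as.integer(tab[c("Green", "Red")]), c(4L, 1L))
  }
  expect_error(stratified_kfold(pairs, k = 1), "k >= 2")
})

test_that("fold sizes and per-class proportionality hold on random datasets", {
  withr::with_seed(55, {
    for (rep in 1:40) {
      counts <- sample(3:40, 4, replace = TRUE)
      k <- sample(2:5, 1)
      pairs <- tibble::tibble(
        arv_id = sprintf("a%04d", seq_len(sum(counts))),
        comed_id = sprintf("c%04d", seq_len(sum(counts))),
        grade = as_grade(rep(0:3, times = counts))
      )
      folded <- suppressWarnings(stratified_kfold(pairs, k = k, seed = rep))
      sizes <- tabulate(folded$fold, k)
      expect_lte(max(sizes) - min(sizes), 1)
      for (g in grade_levels()) {
        per <- tabulate(folded$fold[folded$grade == g], k)
        expect_lte(max(per) - min(per), 1)   # within 1 pair of proportionality
      }
    }
  })
})

test_that("drug-anchored split quarantines the held-out ARVs", {
  pairs <- tibble::tibble(
    arv_id = c("A", "A", "B"), comed_id = c("x", "y", "x"),
    grade = as_grade(c("Green", "Red", "Amber"))
  )
  sp <- drug_anchored_split(pairs, "A")
  expect_identical(nrow(sp$test), 2L)
  expect_identical(sort(sp$test$comed_id), c("x", "y"))
  expect_identical(sp$train$arv_id, "B")
  expect_length(intersect(sp$train$arv_id, "A"), 0)
  expect_error(drug_anchored_split(pairs, "Z"), "not present")
  expect_warning(drug_anchored_split(pairs, "x"), "empty test set")
})

test_that("confusion counts and row normalization match a hand count", {
  true <- c("Green", "Green", "Green", "Yellow", "Amber", "Red")
  pred <- c("Green", "Green", "Yellow", "Yellow", "Amber", "Amber")
  cm <- confusion(true, pred)
  expect_identical(unname(cm$counts["Green", ]), c(2L, 1L, 0L, 0L))
  expect_identical(unname(cm$counts["Red", ]), c(0L, 0L, 1L, 0L))
  expect_identical(unname(cm$normalized["Red", ]), c(0, 0, 1, 0))
  expect_identical(sum(cm$counts), 6L)
  nz <- rowSums(cm$counts) > 0
  expect_equal(unname(rowSums(cm$normalized)[nz]), rep(1, sum(nz)),
               tolerance = 1e-12)
  # perfect predictions give an identity pattern
  cmp <- confusion(true, true)
  expect_identical(sum(diag(cmp$counts)), 6L)
  expect_identical(sum(cmp$counts) - sum(diag(cmp$counts)), 0L)
  expect_error(confusion(true, pred[-1]), "length mismatch")
})

test_that("per-class metrics match hand evaluation of the worked example", {
  true <- c("Green", "Green", "Green", "Yellow", "Amber", "Red")
  pred <- c("Green", "Green", "Yellow", "Yellow", "Amber", "Amber")
  pc <- per_class_metrics(confusion(true, pred))
  g <- pc[pc$grade == "Green", ]
  expect_equal(g$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(g$specificity, 1, tolerance = 1e-12)
  expect_equal(g$balanced_accuracy, (2 / 3 + 1) / 2, tolerance = 1e-12)
  # perfect classifier scores 1 everywhere
  pcp <- per_class_metrics(confusion(true, true))
  for (col in c("accuracy", "precision", "sensitivity", "specificity", "f1",
                "balanced_accuracy")) {
    expect_equal(pcp[[col]], rep(1, 4), tolerance = 1e-12)
  }
})

test_that("F1 dual formula and accuracy identities hold on random matrices", {
  withr::with_seed(77, {
    for (rep in 1:100) {
      n <- sample(20:60, 1)
      true <- as_grade(sample(0:3, n, replace = TRUE))
      pred <- as_grade(sample(0:3, n, replace = TRUE))
      cm <- confusion(true, pred)
      oc <- arvddi:::ovr_counts(cm)
      pc <- per_class_metrics(cm)
      # F1 == 2PR/(P+R) wherever defined, and == 2TP/(2TP+FP+FN) always
      pr <- pc$precision; rc <- pc$sensitivity
      defined <- (pr + rc) > 0
      expect_equal(pc$f1[defined],
                   (2 * pr * rc / (pr + rc))[defined], tolerance = 1e-12)
      # accuracy recomputed from raw labels matches matrix-derived values
      for (ci in 1:4) {
        g <- grade_levels()[ci]
        raw <- mean((true == g) == (pred == g))
        expect_equal(pc$accuracy[ci], raw, tolerance = 1e-12)
      }
      # micro consistency: sum of TP equals number of correct predictions
      expect_identical(sum(oc$tp), sum(true == pred))
    }
  })
})

test_that("macro and weighted macro aggregate per published formulas", {
  pc <- tibble::tibble(grade = as_grade(0:3), n = c(3221, 358, 1146, 378),
                       metric_x = c(1, 0, 0, 0))
  agg <- weighted_macro(pc)
  expect_equal(agg$weighted[agg$metric == "metric_x"], 3221 / 5103,
               tolerance = 1e-9)
  expect_equal(agg$macro[agg$metric == "metric_x"], 0.25, tolerance = 1e-12)
  # equal per-class metric passes through the weighting unchanged
  pc$metric_x <- rep(0.63, 4)
  agg <- weighted_macro(pc)
  expect_equal(agg$weighted, c(0.63), tolerance = 1e-12)
  # weights always sum to one
  withr::with_seed(5, {
    for (rep in 1:10) {
      counts <- sample(1:1000, 4)
      expect_equal(sum(counts / sum(counts)), 1, tolerance = 1e-12)
    }
  })
})

test_that("concordance AUC matches hand-worked and degenerate cases", {
  # scores (0.9, 0.8, 0.4, 0.3), positives at 0.9 and 0.4 -> 3/4
  expect_equal(arvddi:::auc_concordance(c(0.9, 0.4), c(0.8, 0.3)), 3 / 4,
               tolerance = 1e-12)
  # perfect separation
  expect_identical(arvddi:::auc_concordance(c(0.9, 0.8), c(0.2, 0.1)), 1)
  # constant scores -> 0.5
  expect_identical(arvddi:::auc_concordance(rep(0.3, 5), rep(0.3, 7)), 0.5)
})

test_that("concordance AUC equals trapezoidal curve integration", {
  trapezoid <- function(curve) {
    sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  }
  withr::with_seed(99, {
    for (rep in 1:100) {
      n <- sample(10:80, 1)
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(pos) || all(pos)) next
      # duplicate some scores so tie handling is exercised
      score <- round(runif(n), 2)
      a1 <- arvddi:::auc_concordance(score[pos], score[!pos])
      a2 <- trapezoid(arvddi:::roc_points(score, pos))
      expect_equal(a1, a2, tolerance = 1e-9)
    }
  })
})

test_that("one-vs-rest ROC report flags absent classes and bounds AUC", {
  withr::with_seed(12, {
    true <- as_grade(sample(0:2, 50, replace = TRUE))   # no Red
    p <- matrix(rexp(200), 50, 4); p <- p / rowSums(p)
  })
  roc <- roc_auc_ovr(true, p)
  expect_true(is.na(roc$auc[["Red"]]))
  expect_true(all(roc$auc[1:3] >= 0 & roc$auc[1:3] <= 1))
  td <- tidy(roc)
  expect_identical(nrow(td), 4L)
  expect_error(roc_auc_ovr(true, p * 2), "normalized")
})

test_that("metrics report bundles confusion, per-class, aggregates and ROC", {
  withr::with_seed(41, {
    true <- as_grade(sample(0:3, 80, replace = TRUE, prob = c(.7, .1, .15, .05)))
    p <- matrix(rexp(320), 80, 4); p <- p / rowSums(p)
    pred <- as_grade(max.col(p) - 1)
  })
  rep <- metrics_report(true, pred, p)
  expect_s3_class(tidy(rep), "tbl_df")
  g <- glance(rep)
  expect_identical(g$n, 80L)
  expect_true(all(vapply(g[-1], function(v) v >= 0 && v <= 1, logical(1))))
  expect_equal(g$accuracy, mean(true == pred), tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$accuracy, g$accuracy, tolerance = 1e-9)
  expect_length(parsed$per_class, 4)
})

test_that("cross-validation runs the full pipeline per fold, reproducibly", {
  drugs <- toy_drugs()
  pairs <- toy_pairs()
  spec <- network_spec(hidden = c(8), epochs = 6, dropout = 0)
  cv1 <- suppressWarnings(
    crossval(pairs, drugs, k_folds = 2, k = 2, spec = spec, seed = 9))
  expect_length(cv1$fold_reports, 2)
  expect_identical(nrow(tidy(cv1)), 2L)
  expect_true(all(c("mean", "sd") %in% names(cv1$summary)))
  cv2 <- suppressWarnings(
    crossval(pairs, drugs, k_folds = 2, k = 2, spec = spec, seed = 9))
  expect_identical(cv1$summary, cv2$summary)
  expect_identical(glance(cv1), glance(cv2))
})

test_that("result objects render as ggplots", {
  withr::with_seed(3, {
    true <- as_grade(sample(0:3, 60, replace = TRUE))
    p <- matrix(rexp(240), 60, 4); p <- p / rowSums(p)
  })
  rep <- metrics_report(true, as_grade(max.col(p) - 1), p)
  expect_s3_class(autoplot(rep$confusion), "ggplot")
  expect_s3_class(autoplot(rep$roc), "ggplot")
  expect_s3_class(autoplot(rep), "ggplot")
})
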