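#' Stratified k-fold assignment
#'
#' Assigns every pair to one of `k` folds so that each fold preserves the
#' grade distribution: within each grade the pairs are shuffled (seeded) and
#' dealt round-robin, with the dealing pointer carried across grades so fold
#' sizes also differ by at most one pair overall. Per-fold class counts
#' differ from perfect proportionality by less than one pair per class.
#'
#' @param pairs labeled pair table.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return the pair tibble with an added integer `fold` column in `1..k`.
#' @export
stratified_kfold <- function(pairs, k = 5, seed = 1L) {
  pairs <- check_pair_table(pairs)
  if (k < 2) abort("stratified k-fold needs k >= 2")
  small <- names(which(table(pairs$grade) > 0 & table(pairs$grade) < k))
  if (length(small) > 0) {
    warn(sprintf("grade(s) with fewer pairs than folds: %s",
                 paste(small, collapse = ", ")))
  }
  pairs$fold <- strat_folds(as.character(pairs$grade), k, seed)
  pairs
}

# per-class seeded shuffle + round-robin dealing; the dealing pointer carries
# across classes so overall fold sizes also differ by <= 1
strat_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    start <- 0L
    for (g in unique(labels)) {
      idx <- which(labels == g)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
  })
  fold
}

#' Drug-anchored independent split
#'
#' Holds out all pairs involving the selected ARVs, so test drugs are never
#' seen during training: the test set is every pair whose `arv_id` is in
#' `holdout_ids`, the training set is the remainder.
#'
#' @param pairs labeled pair table.
#' @param holdout_ids character vector of held-out ARV ids.
#' @return list with `train` and `test` pair tibbles.
#' @export
drug_anchored_split <- function(pairs, holdout_ids) {
  pairs <- check_pair_table(pairs)
  missing_ids <- setdiff(holdout_ids, c(pairs$arv_id, pairs$comed_id))
  if (length(missing_ids) > 0) {
    abort(sprintf("holdout id(s) not present in the pair table: %s",
                  paste(missing_ids, collapse = ", ")))
  }
  is_test <- pairs$arv_id %in% holdout_ids
  if (!any(is_test)) warn("drug-anchored split produced an empty test set")
  list(train = pairs[!is_test, ], test = pairs[is_test, ])
}

#' Confusion matrix with one-vs-rest reductions
#'
#' Rows are the true grade, columns the predicted grade. The row-normalized
#' form divides each nonzero row by its sum, as used to report per-grade
#' correct-prediction rates.
#'
#' @param true,pred equal-length grade vectors.
#' @return a `ddi_confusion`: list with `counts` (4x4 integer matrix) and
#'   `normalized` (row-proportions).
#' @export
confusion <- function(true, pred) {
  true <- as_grade(true); pred <- as_grade(pred)
  if (length(true) != length(pred)) {
    abort(sprintf("length mismatch: %d true vs %d predicted labels",
                  length(true), length(pred)))
  }
  counts <- table(true = true, pred = pred)
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(true = grade_levels(),
                                   pred = grade_levels()))
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, normalized = normalized, n = length(true)),
            class = "ddi_confusion")
}

#' @export
print.ddi_confusion <- function(x, ...) {
  cat(sprintf("<ddi_confusion> %d pairs (rows = true, cols = predicted)\n", x$n))
  print(x$counts)
  invisible(x)
}

#' @describeIn confusion long-form tibble: `true`, `pred`, `n`, `proportion`
#'   (row-normalized).
#' @param x a `ddi_confusion`.
#' @param ... unused.
#' @method tidy ddi_confusion
#' @export
tidy.ddi_confusion <- function(x, ...) {
  tb <- as_tibble(as.data.frame.table(x$counts, responseName = "n"))
  tb$proportion <- as.vector(x$normalized)  # same (true, pred) expansion order
  tb$true <- as_grade(as.character(tb$true))
  tb$pred <- as_grade(as.character(tb$pred))
  tb
}

# one-vs-rest TP/TN/FP/FN per class from a confusion matrix
ovr_counts <- function(cm) {
  counts <- cm$counts
  total <- sum(counts)
  tibble(
    grade = as_grade(grade_levels()),
    tp = unname(diag(counts)),
    fn = unname(rowSums(counts) - diag(counts)),
    fp = unname(colSums(counts) - diag(counts)),
    tn = unname(total - rowSums(counts) - colSums(counts) + diag(counts))
  )
}

#' Per-class one-vs-rest metrics
#'
#' Each grade is scored as its own binary problem (that grade vs the rest):
#' accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, sensitivity (recall)
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' `F1 = 2*precision*recall/(precision+recall) = 2TP/(2TP+FP+FN)` and
#' balanced accuracy `(sensitivity+specificity)/2`. 0/0 conventions:
#' precision and F1 are 0 when the class is never predicted; sensitivity is 0
#' when the class is absent from the truth (its aggregate weight is then 0
#' anyway).
#'
#' @param cm a [confusion()] object.
#' @return tibble with one row per grade and columns `n`, `accuracy`,
#'   `precision`, `sensitivity`, `specificity`, `f1`, `balanced_accuracy`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "ddi_confusion"))
  oc <- ovr_counts(cm)
  safe <- function(num, den) ifelse(den == 0, 0, num / den)
  tibble(
    grade = oc$grade,
    n = oc$tp + oc$fn,
    accuracy = (oc$tp + oc$tn) / cm$n,
    precision = safe(oc$tp, oc$tp + oc$fp),
    sensitivity = safe(oc$tp, oc$tp + oc$fn),
    specificity = safe(oc$tn, oc$tn + oc$fp),
    f1 = safe(2 * oc$tp, 2 * oc$tp + oc$fp + oc$fn),
    balanced_accuracy = (safe(oc$tp, oc$tp + oc$fn) +
                           safe(oc$tn, oc$tn + oc$fp)) / 2
  )
}

#' Macro and frequency-weighted macro aggregates
#'
#' The plain macro aggregate is the unweighted mean of the per-class metric
#' over the four grades; the weighted macro multiplies each class's metric by
#' its frequency `Weight_i = n_i / N` and sums. Weights always sum to 1.
#'
#' @param per_class a [per_class_metrics()] tibble (or any tibble with a
#'   `grade` column and numeric metric columns).
#' @param counts per-grade counts; defaults to the `n` column of `per_class`.
#' @return tibble with `metric`, `macro`, `weighted`.
#' @export
weighted_macro <- function(per_class, counts = NULL) {
  stopifnot(is.data.frame(per_class), "grade" %in% names(per_class))
  if (is.null(counts)) counts <- setNames(per_class$n, as.character(per_class$grade))
  n <- as.numeric(counts[as.character(per_class$grade)])
  if (anyNA(n)) abort("counts must cover every class in `per_class`")
  wt <- n / sum(n)
  metric_cols <- setdiff(names(per_class)[vapply(per_class, is.numeric, logical(1))],
                         "n")
  bind_rows(lapply(metric_cols, function(mc) {
    v <- per_class[[mc]]
    tibble(metric = mc, macro = mean(v), weighted = sum(wt * v))
  }))
}

#' One-vs-rest ROC curves and AUC
#'
#' For each grade, the soft-voted probability of that grade is used as the
#' score of a binary problem (that grade vs the rest). AUC is computed by
#' pairwise concordance — the probability that a random positive scores above
#' a random negative, ties counting 1/2 — which equals the trapezoidal area
#' under the ROC curve. Grades absent from the truth get `NA`.
#'
#' @param true grade vector.
#' @param probs probability matrix with 4 columns (Green..Red), rows summing
#'   to 1.
#' @return a `ddi_roc`: list with `auc` (named numeric) and `curves`
#'   (tibble of `grade`, `threshold`, `tpr`, `fpr`).
#' @export
roc_auc_ovr <- function(true, probs) {
  true <- as_grade(true)
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4, nrow(probs) == length(true))
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    abort("probabilities must be normalized")
  }
  curves <- list()
  auc <- setNames(rep(NA_real_, 4), grade_levels())
  for (ci in 1:4) {
    g <- grade_levels()[ci]
    pos <- as.character(true) == g
    score <- probs[, ci]
    if (!any(pos) || all(pos)) next
    auc[g] <- auc_concordance(score[pos], score[!pos])
    curves[[g]] <- roc_points(score, pos) |> mutate(grade = as_grade(g))
  }
  structure(list(auc = auc, curves = bind_rows(curves)), class = "ddi_roc")
}

#' @export
print.ddi_roc <- function(x, ...) {
  cat("<ddi_roc> one-vs-rest AUC:\n")
  print(round(x$auc, 4))
  invisible(x)
}

#' @describeIn roc_auc_ovr tibble of per-grade AUCs.
#' @param x a `ddi_roc`.
#' @param ... unused.
#' @method tidy ddi_roc
#' @export
tidy.ddi_roc <- function(x, ...) {
  tibble(grade = as_grade(names(x$auc)), auc = as.numeric(x$auc))
}

# rank-based concordance AUC (ties count 1/2)
auc_concordance <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# ROC curve points at every distinct score threshold (descending)
roc_points <- function(score, pos) {
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]; pos <- pos[ord]
  keep <- c(diff(score) != 0, TRUE)   # last index of each tie group
  tp <- cumsum(pos)[keep]
  fp <- cumsum(!pos)[keep]
  tibble(
    threshold = c(Inf, score[keep]),
    tpr = c(0, tp / sum(pos)),
    fpr = c(0, fp / sum(!pos))
  )
}

#' Full metrics report for a set of predictions
#'
#' Bundles the confusion matrix, per-class one-vs-rest metrics, macro and
#' frequency-weighted macro aggregates, one-vs-rest ROC-AUC on the
#' soft-voted probabilities, and two overall conveniences: `accuracy`
#' (fraction correct) and `macro_sensitivity` (mean per-class recall, the
#' four-class chance level of which is 0.25).
#'
#' @param true grade vector (ground truth).
#' @param pred predicted grade vector.
#' @param probs optional probability matrix for ROC-AUC.
#' @return a `ddi_metrics` object; see [tidy.ddi_metrics()] and
#'   [glance.ddi_metrics()].
#' @export
metrics_report <- function(true, pred, probs = NULL) {
  cm <- confusion(true, pred)
  pc <- per_class_metrics(cm)
  roc <- if (!is.null(probs)) roc_auc_ovr(true, probs) else NULL
  if (!is.null(roc)) pc$roc_auc <- as.numeric(roc$auc[as.character(pc$grade)])
  agg_input <- pc
  if (!is.null(roc)) {
    # classes absent from the truth have NA AUC and weight 0; drop them from
    # the aggregate rather than propagating NA
    agg_input$roc_auc[is.na(agg_input$roc_auc)] <- 0
  }
  agg <- weighted_macro(agg_input)
  structure(
    list(confusion = cm, per_class = pc, aggregates = agg, roc = roc,
         accuracy = sum(diag(cm$counts)) / cm$n,
         macro_sensitivity = mean(pc$sensitivity[pc$n > 0])),
    class = "ddi_metrics"
  )
}

#' @export
print.ddi_metrics <- function(x, ...) {
  cat(sprintf("<ddi_metrics> %d pairs; accuracy %.3f\n", x$confusion$n,
              x$accuracy))
  print(x$per_class, n = 4)
  cat("aggregates:\n")
  print(x$aggregates)
  invisible(x)
}

#' @describeIn metrics_report per-class metric tibble.
#' @param x a `ddi_metrics`.
#' @param ... unused.
#' @method tidy ddi_metrics
#' @export
tidy.ddi_metrics <- function(x, ...) x$per_class

#' @describeIn metrics_report one-row summary with the weighted macro
#'   aggregates.
#' @method glance ddi_metrics
#' @export
glance.ddi_metrics <- function(x, ...) {
  wt <- setNames(x$aggregates$weighted, x$aggregates$metric)
  tibble(
    n = x$confusion$n,
    accuracy = x$accuracy,
    macro_sensitivity = x$macro_sensitivity,
    weighted_accuracy = wt[["accuracy"]],
    weighted_precision = wt[["precision"]],
    weighted_sensitivity = wt[["sensitivity"]],
    weighted_specificity = wt[["specificity"]],
    weighted_f1 = wt[["f1"]],
    weighted_balanced_accuracy = wt[["balanced_accuracy"]],
    weighted_roc_auc = if ("roc_auc" %in% x$aggregates$metric)
      wt[["roc_auc"]] else NA_real_
  )
}

#' Write a metrics report to JSON
#'
#' @param report a [metrics_report()] object.
#' @param path output path.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "ddi_metrics"))
  obj <- list(
    n = report$confusion$n,
    accuracy = report$accuracy,
    macro_sensitivity = report$macro_sensitivity,
    per_class = report$per_class |> mutate(grade = as.character(.data$grade)),
    aggregates = report$aggregates,
    confusion = report$confusion$counts,
    confusion_normalized = report$confusion$normalized
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Stratified cross-validated evaluation of the ensemble pipeline
#'
#' Runs the full training scheme inside each fold: the pairs are split by
#' [stratified_kfold()], and for each fold an ensemble is trained on the
#' other `k - 1` folds (undersampling, class weights, soft voting, with the
#' fold-specific seed `seed + 100 * fold`) and evaluated on the held fold.
#' The reference panel is built once from the full drug table (features leak
#' nothing: they are per-drug structure only).
#'
#' @param pairs labeled pair table.
#' @param drugs drug table.
#' @param k_folds number of CV folds.
#' @param ftz,k,spec,class_weighting,seed see [train_ensemble()].
#' @return a `ddi_crossval`: list with `fold_reports` (list of
#'   [metrics_report()]s), `folds` (assignment tibble) and `summary`
#'   (mean and sample sd of each weighted aggregate across folds).
#' @export
crossval <- function(pairs, drugs, k_folds = 5, ftz = NULL, k = 5,
                     spec = NULL, class_weighting = TRUE, seed = 1L) {
  pairs <- check_pair_table(pairs)
  drugs <- check_drug_table(drugs)
  if (is.null(ftz)) {
    ftz <- featurizer("similarity", panel = build_reference_panel(drugs))
  }
  folded <- stratified_kfold(pairs, k = k_folds, seed = seed)
  reports <- vector("list", k_folds)
  glances <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folded[folded$fold != f, ]
    te <- folded[folded$fold == f, ]
    fit <- train_ensemble(tr, drugs, ftz = ftz, k = k, spec = spec,
                          seed = as.integer(seed) + 100L * f,
                          class_weighting = class_weighting)
    pr <- predict(fit, te, drugs)
    reports[[f]] <- metrics_report(te$grade, pr$predicted,
                                   as.matrix(pr[, c("p_green", "p_yellow",
                                                    "p_amber", "p_red")]))
    glances[[f]] <- glance(reports[[f]]) |> mutate(fold = f, seed = fit$seed)
  }
  per_fold <- bind_rows(glances)
  summary <- per_fold |>
    tidyr::pivot_longer(-c("fold", "seed", "n"), names_to = "metric") |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")
  structure(
    list(fold_reports = reports, folds = folded, per_fold = per_fold,
         summary = summary, k_folds = k_folds, seed = as.integer(seed)),
    class = "ddi_crossval"
  )
}

#' @export
print.ddi_crossval <- function(x, ...) {
  cat(sprintf("<ddi_crossval> %d folds (seed %d); mean +/- sd across folds:\n",
              x$k_folds, x$seed))
  print(x$summary)
  invisible(x)
}

#' @describeIn crossval per-fold weighted aggregates.
#' @param x a `ddi_crossval`.
#' @param ... unused.
#' @method tidy ddi_crossval
#' @export
tidy.ddi_crossval <- function(x, ...) x$per_fold

#' @describeIn crossval fold-averaged summary (mean +/- sample sd).
#' @method glance ddi_crossval
#' @export
glance.ddi_crossval <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  bind_cols(tibble(k_folds = x$k_folds, seed = x$seed), wide)
}
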