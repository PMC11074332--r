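#' Hyperparameter grids of the comparison models
#'
#' The three classical baselines are tuned by exhaustive grid search over the
#' published lists:
#'
#' * `"gnb"` (Gaussian naive Bayes): `priors` in \{(0.72, 0.076, 0.16, 0.044),
#'   (0.1, 0.1, 0.3, 0.5)\} (positions map Green, Yellow, Amber, Red),
#'   `var_smoothing` in \{1e-9, 1e-8, 1e-7\} — 6 candidates;
#' * `"dt"` (decision tree): `max_depth` \{None, 5, 10, 20\},
#'   `min_samples_split` \{2, 5, 10\}, `min_samples_leaf` \{1, 2, 4\},
#'   `max_features` \{sqrt, log2\}, `criterion` \{gini, entropy\} — 144;
#' * `"rf"` (random forest): `n_estimators` \{100, 200, 300\} plus the
#'   tree-style ranges and `bootstrap` \{TRUE, FALSE\} — 432.
#'
#' `None` is encoded as `NA`. Two knobs have no equivalent in the fitting
#' engines used here and are enumerated but non-operative: `max_features`
#' for the single decision tree (rpart always considers all features; the
#' random forest's `mtry` does implement it) and `min_samples_split` for the
#' random forest (ranger controls leaves only). Candidates that collapse to
#' the same effective configuration are fitted once.
#'
#' @param name `"gnb"`, `"dt"` or `"rf"`.
#' @return tibble of candidate parameter rows (`priors` is a list column).
#' @export
baseline_grid <- function(name = c("gnb", "dt", "rf")) {
  name <- match.arg(name)
  switch(name,
    gnb = tidyr::crossing(
      priors = list(c(0.72, 0.076, 0.16, 0.044), c(0.1, 0.1, 0.3, 0.5)),
      var_smoothing = c(1e-9, 1e-8, 1e-7)
    ),
    dt = tidyr::crossing(
      max_depth = c(NA, 5, 10, 20),
      min_samples_split = c(2, 5, 10),
      min_samples_leaf = c(1, 2, 4),
      max_features = c("sqrt", "log2"),
      criterion = c("gini", "entropy")
    ),
    rf = tidyr::crossing(
      n_estimators = c(100, 200, 300),
      max_depth = c(NA, 5, 10, 20),
      min_samples_split = c(2, 5, 10),
      min_samples_leaf = c(1, 2, 4),
      max_features = c("sqrt", "log2"),
      bootstrap = c(TRUE, FALSE)
    ))
}

#' Grid-searched baseline classifier
#'
#' Exhaustive grid search with stratified internal cross-validation (mean
#' accuracy across folds, the conventional grid-search score), then a refit
#' of the best candidate on the full training data. The estimator engines
#' are established libraries — e1071 (Gaussian NB), rpart (tree), ranger
#' (forest) — with the Gaussian NB adjusted for the `priors` and
#' `var_smoothing` semantics (variances are smoothed by
#' `var_smoothing * max feature variance`).
#'
#' @param name `"gnb"`, `"dt"` or `"rf"`.
#' @param x numeric feature matrix.
#' @param y grade labels.
#' @param grid candidate tibble; defaults to the full published grid
#'   ([baseline_grid()]); pass a subset for quicker searches.
#' @param cv_k internal CV folds (default 5, stratified, seeded).
#' @param seed seed for fold assignment and the forest.
#' @return a `ddi_baseline` with the refit `model`, `best_params` and the
#'   full `cv_results`.
#' @export
fit_baseline <- function(name, x, y, grid = baseline_grid(name), cv_k = 5,
                         seed = 1L) {
  name <- match.arg(name, c("gnb", "dt", "rf"))
  x <- named_features(as.matrix(x))
  y <- factor(as.character(as_grade(y)), levels = grade_levels())
  if (length(unique(y)) < 2) {
    abort("baseline training needs at least 2 classes")
  }
  folds <- strat_folds(as.character(y), cv_k, seed)
  keys <- vapply(seq_len(nrow(grid)),
                 function(i) engine_key(name, grid[i, ]), character(1))
  uniq_keys <- unique(keys)
  scores_by_key <- setNames(numeric(length(uniq_keys)), uniq_keys)
  for (key in uniq_keys) {
    row <- grid[match(key, keys), ]
    acc <- vapply(seq_len(cv_k), function(f) {
      tr <- folds != f; te <- folds == f
      fit <- engine_fit(name, row, x[tr, , drop = FALSE], y[tr], seed)
      pred <- engine_predict(name, fit, x[te, , drop = FALSE], type = "class")
      mean(as.character(pred) == as.character(y[te]))
    }, numeric(1))
    scores_by_key[[key]] <- mean(acc)
  }
  cv_results <- grid
  cv_results$mean_accuracy <- unname(scores_by_key[keys])
  best_i <- which.max(cv_results$mean_accuracy)
  best <- grid[best_i, ]
  model <- engine_fit(name, best, x, y, seed)
  structure(
    list(name = name, model = model, best_params = best,
         cv_results = cv_results, cv_k = cv_k, seed = as.integer(seed)),
    class = "ddi_baseline"
  )
}

#' @export
print.ddi_baseline <- function(x, ...) {
  cat(sprintf("<ddi_baseline> %s; best of %d candidates (mean CV accuracy %.3f)\n",
              x$name, nrow(x$cv_results), max(x$cv_results$mean_accuracy)))
  print(x$best_params)
  invisible(x)
}

#' @export
predict.ddi_baseline <- function(object, newdata,
                                 type = c("class", "prob"), ...) {
  type <- match.arg(type)
  engine_predict(object$name, object$model,
                 named_features(as.matrix(newdata)), type)
}

# engines address features by name, so train and query names must agree
named_features <- function(x) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

#' @describeIn fit_baseline grid-search results, one row per candidate.
#' @method tidy ddi_baseline
#' @export
tidy.ddi_baseline <- function(x, ...) x$cv_results

#' Benchmark all models on the drug-anchored split
#'
#' Trains each requested model on the training side of the drug-anchored
#' split with each featurizer backend, evaluates on the held-out side, and
#' reports the five frequency-weighted macro metrics (precision,
#' sensitivity, specificity, F1, balanced accuracy). All models are scored
#' through the same [metrics_report()] code path so conventions match.
#'
#' @param drugs drug table.
#' @param pairs labeled pair table.
#' @param holdout_ids held-out ARV ids defining the split.
#' @param models subset of `c("gnb", "dt", "rf", "ensemble")`.
#' @param backends subset of `c("similarity", "embedding-stub")`.
#' @param grids optional named list of reduced grids per model.
#' @param k,spec ensemble settings (see [train_ensemble()]); `spec` defaults
#'   to the preset matching each backend.
#' @param cv_k internal grid-search folds.
#' @param seed master seed.
#' @return tibble with one row per model x backend and the five weighted
#'   metrics.
#' @export
benchmark <- function(drugs, pairs, holdout_ids,
                      models = c("gnb", "dt", "rf", "ensemble"),
                      backends = c("similarity", "embedding-stub"),
                      grids = NULL, k = 5, spec = NULL, cv_k = 5, seed = 1L) {
  drugs <- check_drug_table(drugs)
  pairs <- check_pair_table(pairs)
  split <- drug_anchored_split(pairs, holdout_ids)
  rows <- list()
  for (backend in backends) {
    ftz <- if (backend == "similarity") {
      featurizer("similarity", panel = build_reference_panel(drugs))
    } else {
      featurizer(backend)
    }
    x_tr <- pair_features(split$train, drugs, ftz)
    x_te <- pair_features(split$test, drugs, ftz)
    for (model in models) {
      if (model == "ensemble") {
        sp <- spec %||%
          network_spec(if (backend == "similarity") "sim" else "embedding")
        fit <- train_ensemble(split$train, drugs, ftz = ftz, k = k, spec = sp,
                              seed = seed)
        pr <- predict(fit, split$test, drugs)
        rep <- metrics_report(split$test$grade, pr$predicted,
                              as.matrix(pr[, c("p_green", "p_yellow",
                                               "p_amber", "p_red")]))
      } else {
        grid <- if (!is.null(grids[[model]])) grids[[model]] else
          baseline_grid(model)
        fit <- fit_baseline(model, x_tr, split$train$grade, grid = grid,
                            cv_k = cv_k, seed = seed)
        pred <- predict(fit, x_te)
        rep <- metrics_report(split$test$grade, pred)
      }
      wt <- setNames(rep$aggregates$weighted, rep$aggregates$metric)
      rows[[paste(model, backend)]] <- tibble(
        model = model, backend = backend,
        precision = wt[["precision"]], sensitivity = wt[["sensitivity"]],
        specificity = wt[["specificity"]], f1 = wt[["f1"]],
        balanced_accuracy = wt[["balanced_accuracy"]]
      )
    }
  }
  bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- engines -----------------------------------------------------------------

# operative-parameter signature; candidates sharing it are fitted once
engine_key <- function(name, row) {
  drop_cols <- switch(name, dt = "max_features", rf = "min_samples_split",
                      character(0))
  keep <- setdiff(names(row), drop_cols)
  paste(vapply(keep, function(cn) {
    v <- row[[cn]][[1]]
    paste0(cn, "=", paste(format(v, digits = 12), collapse = ","))
  }, character(1)), collapse = ";")
}

engine_fit <- function(name, row, x, y, seed) {
  switch(name,
    gnb = fit_gnb(x, y, priors = row$priors[[1]],
                  var_smoothing = row$var_smoothing),
    dt = fit_dt(x, y, row),
    rf = fit_rf(x, y, row, seed))
}

engine_predict <- function(name, fit, x, type) {
  switch(name,
    gnb = predict_gnb(fit, x, type),
    dt = predict_dt(fit, x, type),
    rf = predict_rf(fit, x, type))
}

# Gaussian NB: e1071 engine with class priors and variance smoothing applied
# to the fitted tables (var' = var + var_smoothing * max_j Var(x_j))
fit_gnb <- function(x, y, priors, var_smoothing) {
  df <- as.data.frame(x)
  m <- e1071::naiveBayes(df, y)
  eps <- var_smoothing * max(apply(x, 2, stats::var))
  m$tables <- lapply(m$tables, function(tb) {
    # single-sample classes give sd = NA (sklearn semantics: variance 0);
    # absent classes give NaN rows and are silenced by a zero prior below
    tb[is.na(tb)] <- 0
    tb[, 2] <- sqrt(tb[, 2]^2 + eps)
    tb
  })
  counts <- m$apriori
  new_priors <- priors[match(names(counts), grade_levels())]
  new_priors[counts == 0] <- 0
  m$apriori <- counts * 0 + new_priors * sum(counts)
  attr(m, "feature_names") <- colnames(df)
  m
}

predict_gnb <- function(m, x, type) {
  df <- as.data.frame(x)
  colnames(df) <- attr(m, "feature_names")
  # eps = 0 with a denormal threshold replaces only exact underflows, keeping
  # the Gaussian likelihood intact at all representable densities
  p <- predict(m, df, type = "raw", eps = 0,
               threshold = .Machine$double.xmin)
  # columns of absent classes (zero prior) can come back NaN; they carry no
  # posterior mass, so zero them and renormalize
  p[!is.finite(p)] <- 0
  rs <- rowSums(p)
  p[rs == 0, ] <- 1
  p <- p / rowSums(p)
  if (type == "prob") return(align_prob(p))
  as_grade(colnames(p)[max.col(p, ties.method = "first")])
}

fit_dt <- function(x, y, row) {
  df <- as.data.frame(x)
  df$.grade <- y
  ctl <- rpart::rpart.control(
    maxdepth = if (is.na(row$max_depth)) 30 else row$max_depth,
    minsplit = row$min_samples_split,
    minbucket = row$min_samples_leaf,
    cp = 0, xval = 0)
  rpart::rpart(.grade ~ ., data = df, method = "class",
               parms = list(split = if (row$criterion == "gini") "gini"
                            else "information"),
               control = ctl)
}

predict_dt <- function(m, x, type) {
  df <- as.data.frame(x)
  if (type == "prob") {
    return(align_prob(predict(m, df, type = "prob")))
  }
  as_grade(as.character(predict(m, df, type = "class")))
}

fit_rf <- function(x, y, row, seed) {
  p <- ncol(x)
  mtry <- if (row$max_features == "sqrt") max(1, floor(sqrt(p))) else
    max(1, floor(log2(p)))
  ranger::ranger(
    x = x, y = y, num.trees = row$n_estimators, mtry = mtry,
    min.node.size = row$min_samples_leaf,
    max.depth = if (is.na(row$max_depth)) 0 else row$max_depth,
    replace = row$bootstrap,
    sample.fraction = 1,
    splitrule = "gini", probability = TRUE,
    seed = as.integer(seed), num.threads = 1)
}

predict_rf <- function(m, x, type) {
  p <- predict(m, data = x, num.threads = 1)$predictions
  if (type == "prob") return(align_prob(p))
  as_grade(colnames(p)[max.col(p, ties.method = "first")])
}

# reorder probability columns to Green..Red, filling absent classes with 0
align_prob <- function(p) {
  out <- matrix(0, nrow(p), 4, dimnames = list(NULL, grade_levels()))
  out[, colnames(p)] <- p
  out
}
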