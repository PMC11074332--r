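#' Train the undersampling soft-voting ensemble
#'
#' The full training scheme for one model: the majority grade is
#' undersampled into `k` subsets ([partition_majority()]), each subset gets
#' its own inverse-frequency class weights ([class_weights()]), and one
#' network member is trained per subset with a derived seed
#' (`seed + member index`). Prediction averages the members' class
#' probability vectors (soft voting).
#'
#' With `k = 1` and `class_weighting = FALSE` the pipeline degenerates to a
#' plain softmax classifier on the full training data — the "single model"
#' baseline the ensemble is compared against.
#'
#' @param pairs labeled pair table (`arv_id`, `comed_id`, `grade`).
#' @param drugs drug table resolving every id.
#' @param ftz a [featurizer()]; by default a similarity featurizer over a
#'   reference panel built from `drugs`.
#' @param k ensemble size (default 5).
#' @param spec a [network_spec()]; defaults to the preset matching the
#'   backend (`"sim"` for similarity, `"embedding"` for embeddings).
#' @param seed master seed; member `i` trains with seed `seed + i`.
#' @param class_weighting apply inverse-frequency class weights (`TRUE`,
#'   the published scheme) or train unweighted.
#' @param both_orientations also train every member on the
#'   (comedication, ARV)-flipped copy of each pair feature with the same
#'   label; prediction stays ARV-first. Off by default: the database is
#'   asymmetric by construction.
#' @param config optional [run_config()] supplying all of the above.
#' @return a `ddi_ensemble` object.
#' @export
train_ensemble <- function(pairs, drugs, ftz = NULL, k = 5, spec = NULL,
                           seed = 1L, class_weighting = TRUE,
                           both_orientations = FALSE, config = NULL) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "ddi_config"))
    k <- config$ensemble_size
    seed <- config$seed
    class_weighting <- config$class_weighting
    both_orientations <- config$both_orientations
    if (is.null(spec)) spec <- network_spec(config$network)
    if (is.null(ftz) && config$backend != "similarity") {
      ftz <- featurizer(config$backend,
                        radius = config$fingerprint_radius,
                        n_bits = config$fingerprint_bits)
    }
  }
  pairs <- check_pair_table(pairs)
  drugs <- check_drug_table(drugs)
  if (length(unique(pairs$grade)) < 2) {
    abort("training needs at least 2 grades present")
  }
  if (is.null(ftz)) {
    ftz <- featurizer("similarity", panel = build_reference_panel(drugs))
  }
  if (is.null(spec)) {
    spec <- network_spec(if (ftz$backend == "similarity") "sim" else "embedding")
  }
  x <- pair_features(pairs, drugs, ftz)
  part <- partition_majority(pairs, k = k, seed = seed)
  row_key <- paste(pairs$arv_id, pairs$comed_id, sep = "\r")
  members <- vector("list", k)
  member_info <- vector("list", k)
  half <- ncol(x) / 2
  for (i in seq_len(k)) {
    sub <- part$subsets[[i]]
    idx <- match(paste(sub$arv_id, sub$comed_id, sep = "\r"), row_key)
    w <- if (class_weighting) class_weights(sub) else NULL
    x_i <- x[idx, , drop = FALSE]
    y_i <- sub$grade
    if (isTRUE(both_orientations)) {
      x_i <- rbind(x_i, x_i[, c(half + seq_len(half), seq_len(half)),
                            drop = FALSE])
      y_i <- c(y_i, y_i)   # same class fractions, so weights are unchanged
    }
    members[[i]] <- train_member(spec, x_i, y_i,
                                 weights = w, seed = as.integer(seed) + i)
    member_info[[i]] <- tibble(
      member = i, seed = as.integer(seed) + i, n_train = nrow(x_i),
      best_epoch = members[[i]]$best_epoch,
      val_loss = min(members[[i]]$history$val_loss)
    )
  }
  structure(
    list(members = members, ftz = ftz, spec = spec, k = k,
         seed = as.integer(seed), class_weighting = class_weighting,
         both_orientations = isTRUE(both_orientations),
         feature_length = ncol(x),
         majority = part$majority, dropped = part$dropped,
         train_counts = table(pairs$grade),
         member_info = bind_rows(member_info),
         version = bundle_version()),
    class = "ddi_ensemble"
  )
}

bundle_version <- function() "arvddi-bundle-1"

#' @export
print.ddi_ensemble <- function(x, ...) {
  cat(sprintf(
    "<ddi_ensemble> %d member(s), '%s' backend (%d features), '%s' network, %s\n",
    x$k, x$ftz$backend, x$feature_length, x$spec$preset,
    if (x$class_weighting) "class-weighted" else "unweighted"))
  invisible(x)
}

#' Predict DDI severity for drug pairs
#'
#' Featurizes the pairs with the ensemble's frozen featurizer, collects each
#' member's class probabilities, and soft-votes.
#'
#' @param object a trained [train_ensemble()] model.
#' @param pairs data frame with `arv_id`, `comed_id`.
#' @param drugs drug table resolving every id (held-out drugs are fine: they
#'   are simply absent from the reference panel).
#' @param type `"table"` (default; tibble with probabilities and predicted
#'   grade), `"prob"` (bare probability matrix) or `"class"` (grade factor).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.ddi_ensemble <- function(object, pairs, drugs,
                                 type = c("table", "prob", "class"), ...) {
  type <- match.arg(type)
  x <- pair_features(pairs, drugs, object$ftz)
  if (ncol(x) != object$feature_length) {
    abort(sprintf("feature length %d does not match the model's %d",
                  ncol(x), object$feature_length))
  }
  member_probs <- lapply(object$members, function(m) predict(m, x))
  vote <- soft_vote(member_probs)
  switch(type,
    prob = vote$prob,
    class = vote$predicted,
    table = {
      p <- vote$prob
      tibble(
        arv_id = pairs$arv_id, comed_id = pairs$comed_id,
        p_green = p[, 1], p_yellow = p[, 2], p_amber = p[, 3], p_red = p[, 4],
        predicted = vote$predicted
      )
    })
}

#' Soft voting over ensemble members
#'
#' Averages the members' class probability vectors elementwise and predicts
#' the grade with the highest mean probability. The mean preserves the
#' probability simplex, and permuting member order never changes the vote.
#' Exact argmax ties are broken toward the more severe grade — clinically
#' conservative, mirroring the asymmetric cost of missing a Red interaction.
#'
#' @param member_probs list of member outputs: each a probability 4-vector or
#'   a matrix with 4 columns (rows = pairs, columns Green..Red). Rows must
#'   sum to 1 (tolerance 1e-6).
#' @return list with `prob` (averaged matrix) and `predicted` (grade factor).
#' @examples
#' soft_vote(list(c(1, 0, 0, 0), c(0, 0, 0, 1)))$predicted  # tie -> Red
#' @export
soft_vote <- function(member_probs) {
  if (length(member_probs) == 0) abort("need at least one member")
  mats <- lapply(member_probs, function(p) {
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    if (ncol(p) != 4) abort("probability vectors must have 4 classes")
    if (any(p < -1e-12) || any(abs(rowSums(p) - 1) > 1e-6)) {
      abort("member probabilities must be non-negative and sum to 1")
    }
    p
  })
  nr <- unique(vapply(mats, nrow, integer(1)))
  if (length(nr) != 1) abort("member probability matrices differ in rows")
  prob <- Reduce(`+`, mats) / length(mats)
  predicted <- as_grade(max.col(prob, ties.method = "last") - 1L)
  colnames(prob) <- grade_levels()
  list(prob = prob, predicted = predicted)
}

#' Persist / restore a trained ensemble
#'
#' The bundle stores the members, the featurizer (including the frozen
#' reference panel), the network spec and a format version, so
#' `load_model(save_model(x))` reproduces identical predictions. Truncated or
#' foreign files raise a corrupt-bundle error; a bundle written by a
#' different format version raises a version error.
#'
#' @param ensemble a `ddi_ensemble`.
#' @param path file path (single-file bundle).
#' @export
save_model <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ddi_ensemble"))
  saveRDS(list(version = bundle_version(), ensemble = ensemble), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("no model bundle at %s", path))
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("corrupt model bundle %s: %s", path, conditionMessage(e)))
  })
  if (!is.list(obj) || is.null(obj$version) ||
      !inherits(obj$ensemble, "ddi_ensemble")) {
    abort(sprintf("corrupt model bundle %s: not an arvddi bundle", path))
  }
  if (!identical(obj$version, bundle_version())) {
    abort(sprintf("bundle version mismatch: file has '%s', this build expects '%s'",
                  obj$version, bundle_version()))
  }
  obj$ensemble
}

#' @describeIn train_ensemble per-member summary: training subset size, seed,
#'   best epoch and monitored validation loss.
#' @param x a `ddi_ensemble`.
#' @method tidy ddi_ensemble
#' @export
tidy.ddi_ensemble <- function(x, ...) x$member_info

#' @describeIn train_ensemble one-row model summary.
#' @method glance ddi_ensemble
#' @export
glance.ddi_ensemble <- function(x, ...) {
  tibble(
    k = x$k, backend = x$ftz$backend, network = x$spec$preset,
    feature_length = x$feature_length,
    n_train = sum(x$train_counts), majority = as.character(x$majority),
    majority_dropped = nrow(x$dropped),
    class_weighting = x$class_weighting, seed = x$seed
  )
}
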