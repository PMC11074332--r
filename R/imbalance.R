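#' Undersample the majority grade into k ensemble subsets
#'
#' The skewed grade distribution (Green dominates curated DDI databases) is
#' handled without discarding information: the majority class is shuffled and
#' split into `k` equal chunks of `floor(n_majority / k)` pairs (the
#' remainder, at most `k - 1` pairs, is dropped and logged), while every
#' minority-class pair is copied whole into all `k` subsets. Each ensemble
#' member trains on one subset, so all subsets are equal-sized and together
#' they cover the full majority class.
#'
#' The majority class is detected from the data as the most frequent grade,
#' not hard-coded.
#'
#' @param pairs labeled pair table (`arv_id`, `comed_id`, `grade`).
#' @param k number of subsets / ensemble members.
#' @param seed seed for the majority shuffle.
#' @return a `ddi_partition`: list with `subsets` (list of `k` pair tibbles),
#'   `majority` (the grade), and `dropped` (tibble of remainder pairs).
#' @export
partition_majority <- function(pairs, k = 5, seed = 1L) {
  pairs <- check_pair_table(pairs)
  stopifnot(k >= 1)
  counts <- table(pairs$grade)
  zero <- names(counts)[counts == 0]
  if (length(zero) > 0) {
    warn(sprintf("grade(s) with zero pairs: %s (class weights handle absence)",
                 paste(zero, collapse = ", ")))
  }
  majority <- names(counts)[which.max(counts)]
  n_maj <- max(counts)
  if (k > n_maj) {
    abort(sprintf("k = %d exceeds the majority class size %d", k, n_maj))
  }
  is_maj <- as.character(pairs$grade) == majority
  maj <- pairs[is_maj, ]
  mino <- pairs[!is_maj, ]
  k <- as.integer(k)
  per <- as.integer(n_maj) %/% k
  shuffled <- withr::with_seed(as.integer(seed),
                               maj[sample.int(nrow(maj)), , drop = FALSE])
  used <- shuffled[seq_len(per * k), , drop = FALSE]
  dropped <- shuffled[setdiff(seq_len(nrow(shuffled)), seq_len(per * k)), ,
                      drop = FALSE]
  subsets <- lapply(seq_len(k), function(i) {
    chunk <- used[((i - 1L) * per + 1L):(i * per), , drop = FALSE]
    bind_rows(chunk, mino)
  })
  structure(
    list(subsets = subsets, majority = as_grade(majority),
         dropped = dropped, k = k, seed = as.integer(seed),
         majority_per_subset = per),
    class = "ddi_partition"
  )
}

#' @export
print.ddi_partition <- function(x, ...) {
  cat(sprintf(
    "<ddi_partition> k = %d; majority %s: %d per subset (%d dropped); subset size %d\n",
    x$k, as.character(x$majority), x$majority_per_subset, nrow(x$dropped),
    nrow(x$subsets[[1]])))
  invisible(x)
}

#' @describeIn partition_majority audit manifest: one row per (pair, subset)
#'   membership, written as `pair_id,subset_index` for auditability.
#' @param x a `ddi_partition`.
#' @param ... unused.
#' @method as_tibble ddi_partition
#' @export
as_tibble.ddi_partition <- function(x, ...) {
  bind_rows(lapply(seq_along(x$subsets), function(i) {
    s <- x$subsets[[i]]
    tibble(pair_id = paste(s$arv_id, s$comed_id, sep = ":"), subset_index = i)
  }))
}

#' Inverse-frequency class weights
#'
#' The training loss of each ensemble member multiplies every sample's
#' cross-entropy term by its class weight
#' \deqn{w_c = N_{total} / (C \times n_c)}
#' where \eqn{N_{total}} is the subset size, \eqn{C} the number of classes
#' present, and \eqn{n_c} the class count — inversely proportional to class
#' frequency, so the rare Red grade costs the most to misclassify. Weighted
#' counts are equalized: \eqn{n_c w_c} is the same for every present class,
#' and equal counts give all weights 1. Absent classes get weight 0 and are
#' excluded from the training loss.
#'
#' @param counts named vector/table of per-grade counts, or a pair table
#'   (then counts are taken from its `grade` column).
#' @return tibble with `grade`, `n`, `weight` for all four grades.
#' @examples
#' class_weights(c(Green = 10, Yellow = 10, Amber = 10, Red = 10))
#' @export
class_weights <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- table(check_pair_table(counts)$grade)
  }
  lv <- grade_levels()
  n <- setNames(rep(0, 4), lv)
  idx <- match(names(counts), lv)
  if (anyNA(idx)) {
    abort(sprintf("unknown grade(s) in counts: %s",
                  paste(names(counts)[is.na(idx)], collapse = ", ")))
  }
  n[idx] <- as.numeric(counts)
  if (all(n == 0)) abort("all class counts are zero")
  present <- n > 0
  total <- sum(n)
  w <- rep(0, 4)
  w[present] <- total / (sum(present) * n[present])
  tibble(grade = as_grade(lv), n = as.numeric(n), weight = w)
}
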