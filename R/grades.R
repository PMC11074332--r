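#' The four-level traffic-light DDI severity scale
#'
#' Clinical drug-drug interaction (DDI) resources for antiretroviral therapy
#' grade every drug pair on an ordered "traffic light" scale:
#' Green (no clinically significant interaction expected), Yellow (weak
#' relevance, no action needed), Amber (clinically relevant but manageable by
#' monitoring or dose adjustment) and Red (do not co-administer). The ordering
#' Green < Yellow < Amber < Red is total and is used for the
#' severity-conservative tie-break in soft voting.
#'
#' Internally grades are integer codes 0-3 in that order; in files they are
#' serialized as names.
#'
#' @return `grade_levels()` returns the four level names in severity order.
#' @examples
#' grade_levels()
#' as_grade(c("green", "RED", 1))
#' @export
grade_levels <- function() c("Green", "Yellow", "Amber", "Red")

#' @rdname grade_levels
#' @param x a vector of grade names (case-insensitive), integer codes 0-3, or
#'   an existing grade factor.
#' @return `as_grade()` returns an ordered factor with the four levels;
#'   unrecognized tokens raise an error naming them.
#' @export
as_grade <- function(x) {
  lv <- grade_levels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% 0:3)
    if (any(bad)) {
      abort(sprintf("invalid grade code(s): %s (expected 0-3)",
                    paste(unique(x[bad]), collapse = ", ")))
    }
    return(factor(lv[x + 1L], levels = lv, ordered = TRUE))
  }
  xl <- tolower(trimws(x))
  idx <- match(xl, tolower(lv))
  num <- suppressWarnings(as.integer(xl))
  idx[is.na(idx) & !is.na(num) & num %in% 0:3] <-
    num[is.na(idx) & !is.na(num) & num %in% 0:3] + 1L
  bad <- is.na(idx) & !is.na(x)
  if (any(bad)) {
    abort(sprintf("unknown grade token(s): %s",
                  paste(unique(x[bad]), collapse = ", ")))
  }
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' @rdname grade_levels
#' @return `grade_code()` returns the integer code 0-3 (Green = 0, Red = 3).
#' @export
grade_code <- function(x) as.integer(as_grade(x)) - 1L
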