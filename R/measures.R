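#' Define a multi-item scale
#'
#' @param name Scale name.
#' @param items Character vector of item column names (non-empty).
#' @param bounds Length-2 numeric item bounds.
#' @param min_items Minimum answered items required to score (default: all).
#' @return A `scale_definition` object.
#' @export
scale_definition <- function(name, items, bounds, min_items = length(items)) {
  if (length(items) == 0) pm_stop("scale '%s': item list is empty", name)
  if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    pm_stop("scale '%s': bounds must be ordered (min < max)", name)
  }
  structure(list(name = name, items = items, bounds = as.numeric(bounds),
                 min_items = as.integer(min_items)),
            class = "scale_definition")
}

#' Default scale definitions
#'
#' The multi-item scales scored as the mean of their items: the experimental
#' injunctive norms scale (P2S2-P2S9), experimental descriptive norms
#' (P3Q1-P3Q2), self-report injunctive norms (IN1-IN7) and the two
#' self-report descriptive norms scales (DN1.1-DN1.5, DN2.1-DN2.3).
#'
#' @return Named list of [scale_definition()] objects.
#' @export
default_scale_definitions <- function() {
  defs <- list(
    scale_definition("exp_injunctive_scale", paste0("p2s", 2:9), c(-1, 1),
                     min_items = 6L),
    scale_definition("exp_descriptive_scale", c("p3q1", "p3q2"), c(-1, 1),
                     min_items = 2L),
    scale_definition("sr_injunctive_scale", paste0("in", 1:7), c(-2, 2),
                     min_items = 5L),
    scale_definition("sr_descriptive_scale1", paste0("dn1_", 1:5), c(1, 5),
                     min_items = 4L),
    scale_definition("sr_descriptive_scale2", paste0("dn2_", 1:3), c(1, 5),
                     min_items = 2L)
  )
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Score a scale as the mean of its items
#'
#' Means over non-missing items when at least `min_items` are answered,
#' otherwise missing. Out-of-bounds item values are an error naming the item.
#'
#' @param items Numeric vector (one respondent) or matrix/data frame
#'   (respondents x items, columns matching `definition$items`).
#' @param definition A [scale_definition()].
#' @return Numeric vector of scale scores (or a single value for a vector
#'   input), `NA` where too few items were answered.
#' @export
score_scale <- function(items, definition) {
  stopifnot(inherits(definition, "scale_definition"))
  single <- is.null(dim(items))
  x <- if (single) matrix(items, nrow = 1) else as.matrix(items)
  if (!is.null(colnames(x)) && all(definition$items %in% colnames(x))) {
    x <- x[, definition$items, drop = FALSE]
  }
  if (ncol(x) != length(definition$items)) {
    pm_stop("scale '%s' expects %d items, got %d", definition$name,
            length(definition$items), ncol(x))
  }
  lo <- definition$bounds[1]; hi <- definition$bounds[2]
  bad <- which(!is.na(x) & (x < lo | x > hi), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    pm_stop("item '%s' out of bounds [%g, %g]",
            definition$items[bad[1, 2]], lo, hi)
  }
  answered <- rowSums(!is.na(x))
  score <- rowMeans(x, na.rm = TRUE)
  score[answered < definition$min_items] <- NA_real_
  score[answered == 0] <- NA_real_
  if (single) score[[1]] else score
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability `alpha = k/(k-1) * (1 - sum(item
#' variances) / variance(total))`, computed on complete cases with sample
#' variances.
#'
#' @param items Matrix or data frame, respondents x items (>= 2 items and
#'   >= 3 complete rows required).
#' @return Alpha, or `NA` with a warning when the total score has zero
#'   variance.
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  if (ncol(x) < 2) pm_stop("cronbach_alpha(): need >= 2 items")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) pm_stop("cronbach_alpha(): need >= 3 complete rows")
  k <- ncol(x)
  tot <- stats::var(rowSums(x))
  if (tot == 0) {
    pm_warn("ZERO_VARIANCE", "total score has zero variance; alpha undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / tot)
}

#' Quartile a school deprivation measure into an ordinal 1-4 SES
#'
#' Bins school-level deprivation scores into quartiles (inclusive
#' linear-interpolation quantiles, R type 7) and orients the categories so
#' 1 = lowest SES (most deprived) and 4 = highest SES. Scores tied exactly
#' on a quartile boundary fall to the lower bin before orientation.
#'
#' @param scores Numeric deprivation scores, one per school.
#' @param higher_is_more_deprived Orientation of `scores` (default TRUE:
#'   larger values mean greater deprivation, as for a deprivation-measure
#'   score; set FALSE for rank-style measures where 1 = most deprived).
#' @return Integer vector of SES categories 1-4 (1 = lowest SES).
#' @export
derive_school_ses <- function(scores, higher_is_more_deprived = TRUE) {
  if (any(is.na(scores))) pm_stop("derive_school_ses(): missing scores")
  if (length(scores) < 4) {
    pm_warn("SMALL_N", "fewer than 4 schools; quartile bins may be degenerate")
  }
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  bin <- 1L + (scores > q[1]) + (scores > q[2]) + (scores > q[3])
  if (higher_is_more_deprived) 5L - bin else bin
}
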