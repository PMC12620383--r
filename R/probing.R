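# Interaction probing: simple slopes / marginal effects and Johnson-Neyman
# regions of significance, on the robust (sandwich) covariance used for
# fitting. For logistic fits both are computed on the linear-predictor
# (log-odds) scale, where the Wald machinery carries over exactly.

.slope_parts <- function(fit) {
  if (!is.null(fit$unfit_reason)) pm_stop("cannot probe an unfit model")
  vc <- fit$vcov
  need <- c("peer_exposure", "peer_x_moderator")
  if (is.null(vc) || !all(need %in% rownames(vc))) {
    pm_stop("fit lacks the robust covariance entries required for probing")
  }
  list(b1 = fit$coefficients["peer_exposure"],
       b3 = fit$coefficients["peer_x_moderator"],
       v11 = vc["peer_exposure", "peer_exposure"],
       v33 = vc["peer_x_moderator", "peer_x_moderator"],
       v13 = vc["peer_exposure", "peer_x_moderator"])
}

.crit_value <- function(fit, level) {
  a <- 1 - level / 100
  if (fit$family == "linear") stats::qt(1 - a / 2, fit$df_residual)
  else stats::qnorm(1 - a / 2)
}

#' Simple slopes (marginal effects) of peer exposure at moderator levels
#'
#' The conditional slope of the peer-exposure predictor at moderator value
#' `w` is `b1 + b3 w` with variance `var(b1) + w^2 var(b3) + 2 w
#' cov(b1, b3)` from the robust covariance. Default levels are the two
#' levels (0, 1) for a dichotomous moderator and one standard deviation
#' below/above the mean (i.e. -SD and +SD of the centered moderator) for a
#' continuous one.
#'
#' @param fit A `peer_fit`.
#' @param levels Optional numeric moderator values (on the model's,
#'   i.e. centered, scale).
#' @param conf_level Confidence level for the interval (default 95).
#' @return Data frame with `level`, `label`, `slope`, `se`, `ci_lower`,
#'   `ci_upper`, `p_value`.
#' @export
simple_slopes <- function(fit, levels = NULL, conf_level = 95) {
  sp <- .slope_parts(fit)
  if (is.null(levels)) {
    if (identical(fit$moderator_type, "dichotomous")) {
      levels <- c(0, 1)
      labels <- c(as.character(fit$level0), as.character(fit$level1))
    } else {
      s <- fit$moderator_sd
      levels <- c(-s, s)
      labels <- c("low (-1 SD)", "high (+1 SD)")
    }
  } else {
    labels <- as.character(levels)
  }
  slope <- sp$b1 + sp$b3 * levels
  v <- sp$v11 + levels^2 * sp$v33 + 2 * levels * sp$v13
  se <- sqrt(pmax(v, 0))
  crit <- .crit_value(fit, conf_level)
  p <- if (fit$family == "linear") {
    2 * stats::pt(-abs(slope / se), fit$df_residual)
  } else {
    2 * stats::pnorm(-abs(slope / se))
  }
  data.frame(level = unname(levels), label = labels, slope = unname(slope),
             se = unname(se),
             ci_lower = unname(slope - crit * se),
             ci_upper = unname(slope + crit * se),
             p_value = unname(p), stringsAsFactors = FALSE)
}

#' Johnson-Neyman region of significance
#'
#' Finds the moderator values at which the conditional peer-influence slope
#' is statistically significant at the requested level. Boundaries are the
#' real roots, within the observed moderator range, of
#' `(b1 + b3 w)^2 = t_crit^2 (var(b1) + w^2 var(b3) + 2 w cov(b1, b3))` -- a
#' quadratic in `w`; the significance pattern is evaluated at the midpoints
#' of the resulting intervals. With no roots in range the slope is uniformly
#' significant or uniformly non-significant. Roots outside the observed
#' range are reported separately as extrapolated.
#'
#' @param fit A `peer_fit`.
#' @param level Confidence level, 95 or 99.
#' @param moderator_range Observed (centered) moderator range; defaults to
#'   the estimation sample's range stored on the fit.
#' @return A `jn_region`: `level`, `t_crit`, `boundaries` (sorted, possibly
#'   empty), `extrapolated` (roots outside the range), and `pattern` (data
#'   frame of intervals with a `significant` flag).
#' @export
johnson_neyman <- function(fit, level = 95, moderator_range = NULL) {
  if (!level %in% c(95, 99)) pm_stop("level must be 95 or 99")
  sp <- .slope_parts(fit)
  rng <- moderator_range %||% fit$moderator_range
  if (is.null(rng) || any(is.na(rng))) {
    pm_stop("observed moderator range unavailable")
  }
  tc <- .crit_value(fit, level)
  # quadratic a w^2 + b w + c = 0
  a <- sp$b3^2 - tc^2 * sp$v33
  b <- 2 * (sp$b1 * sp$b3 - tc^2 * sp$v13)
  cc <- sp$b1^2 - tc^2 * sp$v11
  roots <- numeric(0)
  if (abs(a) < 1e-300) {
    if (abs(b) > 0) roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc >= 0) roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  }
  inside <- roots[roots > rng[1] & roots < rng[2]]
  outside <- setdiff(roots, inside)
  pts <- sort(unique(c(rng[1], inside, rng[2])))
  mids <- (pts[-1] + pts[-length(pts)]) / 2
  sig_at <- function(w) {
    se <- sqrt(max(sp$v11 + w^2 * sp$v33 + 2 * w * sp$v13, 0))
    if (se == 0) return(abs(sp$b1 + sp$b3 * w) > 0)
    abs(sp$b1 + sp$b3 * w) / se >= tc
  }
  pattern <- data.frame(lower = pts[-length(pts)], upper = pts[-1],
                        significant = vapply(mids, sig_at, logical(1)))
  structure(list(level = level, t_crit = tc, boundaries = unname(inside),
                 extrapolated = unname(outside), range = rng,
                 pattern = pattern, fit_family = fit$family),
            class = "jn_region")
}

#' @export
print.jn_region <- function(x, ...) {
  cat(sprintf("<jn_region> %d%% level (t_crit = %.4f), range [%.3g, %.3g]\n",
              x$level, x$t_crit, x$range[1], x$range[2]))
  if (length(x$boundaries) == 0) {
    cat(sprintf("  no boundaries in range; slope %s throughout\n",
                if (x$pattern$significant[1]) "significant" else "not significant"))
  } else {
    cat("  boundaries:", paste(signif(x$boundaries, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Conditional-effects plotting data
#'
#' Predicted outcome (or log-odds) at low/high peer exposure across a grid
#' of moderator values, with pointwise confidence bands for the conditional
#' slope -- the data behind conditional-effects graphs.
#'
#' @param fit A `peer_fit`.
#' @param moderator_values Numeric grid (default 50 points over the observed
#'   centered range, or the two levels for a dichotomous moderator).
#' @param conf_level Confidence level (default 95).
#' @return Data frame with `moderator`, `slope`, `se`, `ci_lower`,
#'   `ci_upper`, `significant`.
#' @export
conditional_effects <- function(fit, moderator_values = NULL,
                                conf_level = 95) {
  if (is.null(moderator_values)) {
    moderator_values <- if (identical(fit$moderator_type, "dichotomous")) {
      c(0, 1)
    } else {
      seq(fit$moderator_range[1], fit$moderator_range[2], length.out = 50)
    }
  }
  ss <- simple_slopes(fit, levels = moderator_values, conf_level = conf_level)
  data.frame(moderator = ss$level, slope = ss$slope, se = ss$se,
             ci_lower = ss$ci_lower, ci_upper = ss$ci_upper,
             significant = ss$p_value <= 1 - conf_level / 100)
}
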