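# Per-moderator aggregation of the model grid: significance tallies with
# direction, Holm-Bonferroni adjustment, exact one-sided binomial
# meta-tests, and multiverse-style summaries.

#' Holm-Bonferroni step-down adjustment
#'
#' Sorted ascending, the adjusted value is `max_{j <= i} min(1,
#' (m - j + 1) p_(j))`; hypotheses are rejected while the adjusted value
#' stays at or below the family alpha.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA`s are carried
#'   through unadjusted and never rejected).
#' @param alpha Family-wise error level (default 0.05).
#' @return List with `adjusted` (same order as input) and `reject` (logical).
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (length(p) == 0) {
    return(list(adjusted = numeric(0), reject = logical(0)))
  }
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) pm_stop("p-values must lie in [0, 1]")
  m <- sum(ok)
  adjusted <- rep(NA_real_, length(p))
  reject <- rep(FALSE, length(p))
  if (m > 0) {
    ord <- order(p[ok])
    ps <- p[ok][ord]
    adj <- cummax(pmin(1, (m - seq_len(m) + 1) * ps))
    back <- integer(m)
    back[ord] <- seq_len(m)
    adjusted[ok] <- adj[back]
    reject[ok] <- adjusted[ok] <= alpha
  }
  list(adjusted = adjusted, reject = reject)
}

#' Exact one-sided binomial meta-test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`: the chance
#' of observing at least the tallied number of significant interactions if
#' each of the grid's models had probability `p0` of a (spurious)
#' significant interaction. Computed by log-space summation of the binomial
#' mass.
#'
#' @param n_models Grid size.
#' @param k_sig Number of significant interactions observed.
#' @param p0 Null per-model significance rate (default 0.01, the
#'   interaction significance criterion).
#' @return One-sided p-value.
#' @export
binomial_meta_test <- function(n_models, k_sig, p0 = 0.01) {
  if (!is_count(n_models) || !is_count(k_sig) || k_sig < 0 ||
      n_models < 0 || k_sig > n_models) {
    pm_stop("binomial_meta_test(): need 0 <= k_sig <= n_models (counts)")
  }
  if (k_sig == 0) return(1)
  j <- k_sig:n_models
  sum(exp(lchoose(n_models, j) + j * log(p0) + (n_models - j) * log1p(-p0)))
}

.direction_labels <- function(fit_or_row) {
  if (identical(fit_or_row$moderator_type, "dichotomous")) {
    c(pos = as.character(fit_or_row$level1), neg = as.character(fit_or_row$level0))
  } else {
    c(pos = "higher", neg = "lower")
  }
}

#' Summarize the model grid for one moderator
#'
#' Tallies significant interactions (p <= `alpha_sig`) in total and per peer
#' group, splits them by direction (sign of the interaction coefficient,
#' mapped to the moderator's substantive labels: the level-1 label for a
#' positive coefficient of a dichotomous moderator, "higher"/"lower" for a
#' continuous one), runs the exact binomial meta-test on the total and on
#' each directional count against the full grid size, and flags which models
#' survive Holm-Bonferroni at the family alpha. Unfit models stay in the
#' denominator and count as non-significant.
#'
#' @param grid A `model_grid` from [run_model_grid()], or its `results`
#'   data frame.
#' @param alpha_sig Interaction significance criterion (default 0.01).
#' @param family_alpha Holm-Bonferroni family level (default 0.05).
#' @return A `moderator_summary` list mirroring a results-overview table
#'   row: grid size, counts (total, per peer group, per direction),
#'   percentages, binomial p-values, Holm survivor count and flags, and a
#'   conclusion label.
#' @export
summarize_moderator <- function(grid, alpha_sig = 0.01, family_alpha = 0.05) {
  r <- if (inherits(grid, "model_grid")) grid$results else grid
  if (length(unique(r$moderator)) != 1) {
    pm_stop("summarize_moderator(): results mix %d moderators",
            length(unique(r$moderator)))
  }
  if (inherits(grid, "model_grid")) alpha_sig <- grid$alpha_sig %||% alpha_sig
  n_unfit <- sum(r$unfit)
  if (n_unfit > 0) {
    pm_warn("UNFIT_IN_DENOMINATOR",
            "%d unfit model(s) counted as non-significant", n_unfit)
  }
  sig <- !is.na(r$p_interaction) & r$p_interaction <= alpha_sig
  n <- nrow(r)
  k <- sum(sig)
  by_group <- vapply(c("friends", "class", "year"),
                     function(g) sum(sig & r$peer_group == g), integer(1))
  k_pos <- sum(sig & r$b_interaction > 0)
  k_neg <- sum(sig & r$b_interaction < 0)
  mt <- list(moderator_type = "continuous", level0 = NA, level1 = NA)
  if (inherits(grid, "model_grid")) {
    for (ft in grid$fits) {
      if (!is.na(ft$moderator_type %||% NA)) {
        mt <- list(moderator_type = ft$moderator_type, level0 = ft$level0,
                   level1 = ft$level1)
        break
      }
    }
  }
  lab <- .direction_labels(mt)
  holm <- holm_bonferroni(r$p_interaction, alpha = family_alpha)
  p_total <- binomial_meta_test(n, k, alpha_sig)
  structure(list(
    moderator = r$moderator[1], n_models = n, k_sig = k,
    pct_sig = 100 * k / n, k_sig_by_group = by_group,
    k_pos = k_pos, k_neg = k_neg,
    direction_labels = lab,
    binom_p = p_total,
    binom_p_pos = binomial_meta_test(n, k_pos, alpha_sig),
    binom_p_neg = binomial_meta_test(n, k_neg, alpha_sig),
    holm_reject = holm$reject, holm_adjusted = holm$adjusted,
    n_holm_survivors = sum(holm$reject),
    n_unfit = n_unfit, alpha_sig = alpha_sig, family_alpha = family_alpha,
    conclusion = if (p_total <= 0.05) "significant moderator"
                 else "not a significant moderator"
  ), class = "moderator_summary")
}

#' @export
print.moderator_summary <- function(x, ...) {
  cat(sprintf("<moderator_summary> %s: %d/%d significant (%.1f%%), binomial p = %.4g [%s]\n",
              x$moderator, x$k_sig, x$n_models, x$pct_sig, x$binom_p,
              x$conclusion))
  cat(sprintf("  direction: %d %s / %d %s (binomial p %.3g / %.3g); Holm survivors: %d\n",
              x$k_pos, x$direction_labels["pos"], x$k_neg,
              x$direction_labels["neg"], x$binom_p_pos, x$binom_p_neg,
              x$n_holm_survivors))
  invisible(x)
}

#' Multiverse-style summaries of a grid's interaction effects
#'
#' Distribution statistics of the interaction p-values, volcano coordinates
#' (standardized interaction coefficient against -log10 p; logistic models,
#' which have no standardized coefficient, are excluded from the volcano and
#' coefficient grid but kept in the p-value summaries), per-cell
#' (outcome x peer group x wave) grids, and heatmap percentages of
#' significant models per outcome family.
#'
#' @param grid A `model_grid` or results data frame (may span moderators;
#'   heatmap cells are per moderator x outcome family).
#' @param alpha_sig Significance criterion for heatmap cells.
#' @param outcome_specs Outcome specification table supplying outcome
#'   families (default [default_outcome_specs()]).
#' @return A `multiverse_summary` list: `p_values`, `stats` (mean/median p,
#'   proportions at 0.01 and 0.05), `volcano`, `cells`, `heatmap`.
#' @export
multiverse_tables <- function(grid, alpha_sig = 0.01,
                              outcome_specs = default_outcome_specs()) {
  r <- if (inherits(grid, "model_grid")) grid$results else grid
  p <- r$p_interaction
  stats_ <- list(
    n = length(p), n_missing = sum(is.na(p)),
    mean_p = mean(p, na.rm = TRUE), median_p = stats::median(p, na.rm = TRUE),
    prop_le_01 = mean(p <= 0.01, na.rm = TRUE),
    prop_le_05 = mean(p <= 0.05, na.rm = TRUE))
  lin <- r[r$family == "linear" & !r$unfit, ]
  volcano <- data.frame(
    moderator = lin$moderator, outcome = lin$outcome,
    peer_group = lin$peer_group, wave = lin$wave,
    beta_std = lin$beta_std,
    neg_log10_p = -log10(lin$p_interaction),
    significant_01 = lin$p_interaction <= 0.01,
    significant_05 = lin$p_interaction <= 0.05,
    stringsAsFactors = FALSE)
  cells <- r[, c("moderator", "outcome", "family", "peer_group", "wave",
                 "beta_std", "p_interaction", "unfit")]
  fam <- outcome_specs$family[match(r$outcome, outcome_specs$name)]
  fam[is.na(fam)] <- "other"
  sig <- !is.na(p) & p <= alpha_sig
  agg <- stats::aggregate(sig, by = list(moderator = r$moderator,
                                         outcome_family = fam),
                          FUN = function(z) 100 * mean(z))
  names(agg)[3] <- "pct_significant"
  counts <- stats::aggregate(sig, by = list(moderator = r$moderator,
                                            outcome_family = fam), FUN = sum)
  agg$k_sig <- counts$x
  agg$n_models <- stats::aggregate(sig, by = list(moderator = r$moderator,
                                                  outcome_family = fam),
                                   FUN = length)$x
  structure(list(p_values = p, stats = stats_, volcano = volcano,
                 cells = cells, heatmap = agg, alpha_sig = alpha_sig),
            class = "multiverse_summary")
}

#' @export
print.multiverse_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<multiverse_summary> %d models: mean p = %.3f, median p = %.3f, %.1f%% at p<=0.01, %.1f%% at p<=0.05\n",
              s$n, s$mean_p, s$median_p, 100 * s$prop_le_01,
              100 * s$prop_le_05))
  invisible(x)
}
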