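# Moderated-regression engine: design construction, OLS/logistic fits with
# Huber-White robust covariance, VIFs, standardized interaction
# coefficients, interaction R-squared increments, and the model grid.

#' Specify one moderated regression model
#'
#' @param outcome Outcome name (response measured at follow-up).
#' @param peer_group `"friends"`, `"class"` or `"year"`.
#' @param wave Wave of peer measurement (0 or 1).
#' @param moderator Moderator name (must differ from the outcome).
#' @param family `"linear"` or `"logistic"`.
#' @param alpha_sig Interaction significance criterion (default 0.01).
#' @return A `model_spec` object.
#' @export
model_spec <- function(outcome, peer_group, wave, moderator,
                       family = c("linear", "logistic"), alpha_sig = 0.01) {
  family <- match.arg(family)
  if (identical(outcome, moderator)) {
    pm_stop("moderator must differ from the outcome ('%s')", outcome)
  }
  if (!peer_group %in% c("friends", "class", "year")) {
    pm_stop("unknown peer group '%s'", peer_group)
  }
  structure(list(outcome = outcome, peer_group = peer_group,
                 wave = as.integer(wave), moderator = moderator,
                 family = family, alpha_sig = alpha_sig),
            class = "model_spec")
}

#' Mean-center a numeric vector
#'
#' Subtracts the mean of the non-missing values (the estimation-sample mean
#' when applied after listwise deletion). Idempotent.
#'
#' @param x Numeric vector with at least one non-missing value.
#' @return Centered vector.
#' @export
mean_center <- function(x) {
  if (all(is.na(x))) pm_stop("mean_center(): all values missing")
  x - mean(x, na.rm = TRUE)
}

.moderator_values <- function(cohort, mrow, wave) {
  col <- switch(mrow$source,
                attribute = mrow$name,
                network_node = paste0(mrow$name, "_w", wave),
                network_school = paste0(mrow$name, "_w", wave),
                outcome_baseline = outcome_col(mrow$name, 0),
                pm_stop("unknown moderator source '%s'", mrow$source))
  v <- cohort[[col]]
  if (is.null(v)) pm_stop("moderator column '%s' not found in cohort", col)
  if (mrow$type == "dichotomous") {
    as.numeric(v == mrow$level1)
  } else {
    as.numeric(v)
  }
}

.covariate_frame <- function(cohort, drop = character(0)) {
  cv <- data.frame(row.names = seq_len(nrow(cohort)))
  if (!"gender" %in% drop) {
    cv$cov_gender_girl <- as.numeric(cohort$gender == "girl_pnts")
  }
  cv$cov_age_13 <- as.numeric(cohort$age_band == "13")
  cv$cov_age_14_15 <- as.numeric(cohort$age_band == "14-15")
  if (!"intervention" %in% drop) {
    cv$cov_intervention_assist <- as.numeric(cohort$intervention == "ASSIST")
  }
  cv$cov_ethnicity_minority <- as.numeric(cohort$ethnicity == "minority")
  cv$cov_ses_2 <- as.numeric(cohort$ses_individual == 2)
  cv$cov_ses_3 <- as.numeric(cohort$ses_individual == 3)
  cv
}

#' Build the design for one moderated regression
#'
#' Assembles response and predictors for a [model_spec()]: centered peer
#' exposure, the moderator (centered if continuous, 0/1 if dichotomous),
#' their product (formed after centering), baseline covariates (gender, age
#' band, intervention, ethnicity, individual SES as indicator contrasts) and
#' the centered baseline outcome. Rows with any missing entry are deleted
#' listwise; centering uses the estimation sample. When the moderator is
#' itself a model covariate (gender, intervention) the duplicate covariate
#' is dropped.
#'
#' @param spec A [model_spec()].
#' @param cohort Cohort data frame.
#' @param exposures Exposure table from [build_exposure_table()] covering
#'   the spec's outcome, peer group and wave.
#' @param moderator_specs Moderator specification table (default
#'   [default_moderator_specs()]).
#' @return A `model_design` object: `data` (response `y` plus predictor
#'   columns), `spec`, sample metadata (`n`, `n_dropped`, `sd_exposure`,
#'   `sd_outcome`, moderator SD/range/type/labels); or an object with
#'   `unfit_reason` set when fewer rows than predictors + 5 survive
#'   deletion.
#' @export
build_design <- function(spec, cohort, exposures,
                         moderator_specs = default_moderator_specs()) {
  stopifnot(inherits(spec, "model_spec"))
  mrow <- moderator_specs[moderator_specs$name == spec$moderator, ]
  if (nrow(mrow) != 1) pm_stop("unknown moderator '%s'", spec$moderator)
  mrow <- as.list(mrow)
  ex <- exposures[exposures$outcome == spec$outcome &
                    exposures$peer_group == spec$peer_group &
                    exposures$wave == spec$wave, ]
  if (nrow(ex) == 0) {
    pm_stop("no exposures for outcome '%s', group '%s', wave %d",
            spec$outcome, spec$peer_group, spec$wave)
  }
  x <- ex$exposure[match(cohort$pupil_id, ex$pupil_id)]
  w <- .moderator_values(cohort, mrow, spec$wave)
  y <- .outcome_values(cohort, spec$outcome, 1)
  base <- .outcome_values(cohort, spec$outcome, 0)
  cv <- .covariate_frame(cohort, drop = spec$moderator)
  d <- cbind(data.frame(y = y, peer_exposure = x, moderator = w,
                        baseline_outcome = base), cv)
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  # covariates constant on the estimation sample carry no information and
  # would only make the design singular (e.g. intervention in a
  # single-programme subset); dropped silently
  if (nrow(d) > 1) {
    cov_cols <- grep("^cov_", names(d), value = TRUE)
    const <- cov_cols[vapply(cov_cols,
                             function(cl) stats::var(d[[cl]]) == 0,
                             logical(1))]
    if (length(const) > 0) d[const] <- NULL
  }
  n <- nrow(d)
  k <- ncol(d) + 1L  # predictors + interaction + intercept, minus response
  meta <- list(spec = spec, moderator_type = mrow$type,
               level0 = mrow$level0, level1 = mrow$level1,
               n = n, n_dropped = sum(!keep))
  if (n < k + 5L) {
    return(structure(c(meta, list(data = NULL,
                                  unfit_reason = sprintf(
                                    "insufficient rows (%d) for %d columns",
                                    n, k))),
                     class = "model_design"))
  }
  d$peer_exposure <- mean_center(d$peer_exposure)
  d$baseline_outcome <- mean_center(d$baseline_outcome)
  if (mrow$type == "continuous") d$moderator <- mean_center(d$moderator)
  d$peer_x_moderator <- d$peer_exposure * d$moderator
  ord <- c("y", "peer_exposure", "moderator", "peer_x_moderator",
           setdiff(names(d), c("y", "peer_exposure", "moderator",
                               "peer_x_moderator")))
  d <- d[, ord]
  meta$sd_exposure <- stats::sd(d$peer_exposure)
  meta$sd_outcome <- stats::sd(d$y)
  meta$moderator_sd <- stats::sd(d$moderator)
  meta$moderator_range <- range(d$moderator)
  structure(c(meta, list(data = d, unfit_reason = NULL)),
            class = "model_design")
}

.design_matrix <- function(design) {
  as.matrix(design$data[, setdiff(names(design$data), "y"), drop = FALSE])
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor `j` on the remaining
#' predictors (with intercept); computed as the diagonal of the inverse
#' correlation matrix. Perfectly collinear predictors report `Inf` with a
#' warning.
#'
#' @param x A `model_design`, or a numeric predictor matrix (no intercept
#'   column).
#' @return Named vector of VIFs.
#' @export
vif <- function(x) {
  X <- if (inherits(x, "model_design")) .design_matrix(x) else as.matrix(x)
  sds <- apply(X, 2, stats::sd)
  out <- rep(Inf, ncol(X))
  names(out) <- colnames(X)
  live <- sds > 0
  if (sum(live) == 1) { out[live] <- 1; return(out) }
  R <- stats::cor(X[, live, drop = FALSE])
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) {
    pm_warn("RANK_DEFICIENT", "collinear predictors; VIFs reported as Inf")
    # recover the non-collinear subset via pseudo-inverse diagnostics
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < 1e-12) return(out)
  } else {
    out[live] <- diag(inv)
  }
  out
}

.robust_p <- function(est, se, df = NULL) {
  stat <- est / se
  if (is.null(df)) 2 * stats::pnorm(-abs(stat)) else 2 * stats::pt(-abs(stat), df)
}

#' Standardized interaction coefficient
#'
#' The estimated difference, in standard deviations of the outcome, between
#' two pupils one standard deviation apart on the peer-exposure predictor:
#' `b3 * SD(exposure) / SD(outcome)`, with sample SDs over the estimation
#' sample.
#'
#' @param b3 Interaction coefficient.
#' @param sd_exposure,sd_outcome Estimation-sample standard deviations.
#' @return The standardized coefficient, `NA` when the outcome SD is zero.
#' @export
standardized_interaction <- function(b3, sd_exposure, sd_outcome) {
  if (is.na(sd_outcome) || sd_outcome == 0) return(NA_real_)
  b3 * sd_exposure / sd_outcome
}

#' R-squared increment of the interaction term
#'
#' `R^2(full) - R^2(without the product column)`, both fitted on the
#' identical estimation sample.
#'
#' @param design A fit-ready `model_design` (linear family).
#' @return Non-negative increment (up to numerical tolerance).
#' @export
interaction_delta_r2 <- function(design) {
  d <- design$data
  full <- stats::lm(y ~ ., data = d)
  red <- stats::lm(y ~ ., data = d[, setdiff(names(d), "peer_x_moderator")])
  summary(full)$r.squared - summary(red)$r.squared
}

.fit_result <- function(design, coefs, vc, df_residual, family,
                        r_squared = NA_real_, delta_r2 = NA_real_,
                        unfit_reason = NULL) {
  se <- sqrt(pmax(diag(vc), 0))
  p <- .robust_p(coefs, se, if (family == "linear") df_residual else NULL)
  vifs <- vif(design)
  b3 <- unname(coefs["peer_x_moderator"])
  structure(list(
    spec = design$spec, family = family, n = design$n,
    n_dropped = design$n_dropped,
    coefficients = coefs, vcov = vc, se = se, p_values = p,
    df_residual = df_residual,
    b_peer = unname(coefs["peer_exposure"]),
    b_moderator = unname(coefs["moderator"]),
    b_interaction = b3,
    se_interaction = unname(se["peer_x_moderator"]),
    p_interaction = unname(p["peer_x_moderator"]),
    beta_std = if (family == "linear") {
      standardized_interaction(b3, design$sd_exposure, design$sd_outcome)
    } else NA_real_,
    delta_r2 = delta_r2, r_squared = r_squared,
    vif = vifs, vif_gt5 = any(vifs > 5), vif_gt10 = any(vifs > 10),
    sd_exposure = design$sd_exposure, sd_outcome = design$sd_outcome,
    moderator_type = design$moderator_type,
    level0 = design$level0, level1 = design$level1,
    moderator_sd = design$moderator_sd,
    moderator_range = design$moderator_range,
    unfit_reason = unfit_reason
  ), class = "peer_fit")
}

#' @export
print.peer_fit <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<peer_fit> %s ~ %s peers (wave %d) x %s [%s, n=%d]\n",
              s$outcome, s$peer_group, s$wave, s$moderator, x$family, x$n))
  if (!is.null(x$unfit_reason)) {
    cat("  UNFIT:", x$unfit_reason, "\n")
  } else {
    cat(sprintf("  interaction b3=%.4g (robust SE %.4g, p=%.4g)\n",
                x$b_interaction, x$se_interaction, x$p_interaction))
  }
  invisible(x)
}

#' Fit a moderated linear regression with Huber-White robust errors
#'
#' Ordinary least squares with heteroskedasticity-consistent (sandwich)
#' covariance; the HC1 variant `n/(n - k) (X'X)^{-1} X' diag(e^2) X
#' (X'X)^{-1}` is the default, matching the robust estimator conventional in
#' the field's statistical software. P-values use the t distribution with
#' `n - k` degrees of freedom.
#'
#' @param design A fit-ready `model_design` (from [build_design()]).
#' @param hc Robust variant: `"HC1"` (default), `"HC0"` or `"HC3"`.
#' @return A `peer_fit` with coefficients, robust covariance, p-values,
#'   VIFs, the standardized interaction coefficient and the interaction
#'   R-squared increment.
#' @export
ols_fit_hc <- function(design, hc = c("HC1", "HC0", "HC3")) {
  hc <- match.arg(hc)
  if (!is.null(design$unfit_reason)) {
    return(.unfit_result(design, "linear"))
  }
  d <- design$data
  fit <- stats::lm(y ~ ., data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    pm_stop("rank-deficient design; collinear column(s): %s",
            paste(bad, collapse = ", "))
  }
  vc <- sandwich::vcovHC(fit, type = hc)
  coefs <- stats::coef(fit)
  .fit_result(design, coefs, vc, df_residual = fit$df.residual,
              family = "linear", r_squared = summary(fit)$r.squared,
              delta_r2 = interaction_delta_r2(design))
}

.unfit_result <- function(design, family) {
  structure(list(spec = design$spec, family = family, n = design$n,
                 n_dropped = design$n_dropped,
                 b_interaction = NA_real_, se_interaction = NA_real_,
                 p_interaction = NA_real_, beta_std = NA_real_,
                 delta_r2 = NA_real_, r_squared = NA_real_,
                 vif = NULL, vif_gt5 = NA, vif_gt10 = NA,
                 moderator_type = design$moderator_type,
                 level0 = design$level0, level1 = design$level1,
                 unfit_reason = design$unfit_reason %||% "unfit"),
            class = "peer_fit")
}

#' Fit a moderated logistic regression with robust errors
#'
#' Maximum-likelihood logit (iteratively reweighted least squares) with a
#' sandwich covariance built from score outer products around the inverse
#' information; Wald z p-values. Models showing perfect separation
#' (diverging coefficients or degenerate fitted probabilities) are flagged
#' unfit rather than reported.
#'
#' @param design A fit-ready `model_design` whose response is binary.
#' @return A `peer_fit`.
#' @export
logit_fit_robust <- function(design) {
  if (!is.null(design$unfit_reason)) {
    return(.unfit_result(design, "logistic"))
  }
  d <- design$data
  if (length(unique(d$y)) < 2) {
    design$unfit_reason <- "single outcome class"
    return(.unfit_result(design, "logistic"))
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep || !fit$converged || any(abs(stats::coef(fit)) > 20, na.rm = TRUE)) {
    design$unfit_reason <- "perfect separation or non-convergence"
    return(.unfit_result(design, "logistic"))
  }
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    pm_stop("rank-deficient design; collinear column(s): %s",
            paste(bad, collapse = ", "))
  }
  vc <- sandwich::vcovHC(fit, type = "HC0")
  .fit_result(design, stats::coef(fit), vc, df_residual = fit$df.residual,
              family = "logistic")
}

#' Enumerate the model grid for one moderator
#'
#' One [model_spec()] per outcome x peer group x wave. Grids for a
#' self-efficacy moderator exclude the three self-efficacy outcomes.
#'
#' @param moderator Moderator name.
#' @param outcomes Character vector of outcome names.
#' @param moderator_specs Moderator specification table.
#' @param peer_groups,waves Grid axes.
#' @return List of `model_spec`s.
#' @export
grid_specs <- function(moderator, outcomes,
                       moderator_specs = default_moderator_specs(),
                       peer_groups = c("friends", "class", "year"),
                       waves = c(0L, 1L)) {
  mrow <- moderator_specs[moderator_specs$name == moderator, ]
  if (nrow(mrow) != 1) pm_stop("unknown moderator '%s'", moderator)
  if (mrow$source == "outcome_baseline") {
    outcomes <- outcomes[!startsWith(outcomes, "self_efficacy")]
  }
  out <- list()
  for (o in outcomes) {
    for (pg in peer_groups) {
      for (w in waves) {
        fam <- if (o == "susceptibility") "logistic" else "linear"
        out[[length(out) + 1L]] <- model_spec(o, pg, w, moderator, fam)
      }
    }
  }
  out
}

#' Fit the full model grid for one moderator
#'
#' Fits one moderated regression per outcome x peer group x wave (linear
#' with HC1 robust errors; logistic with robust errors for the binary
#' susceptibility outcome). Per-model failures are collected as unfit
#' results, not raised.
#'
#' @param moderator Moderator name.
#' @param cohort Cohort data frame.
#' @param exposures Exposure table covering all requested outcomes, groups
#'   and waves.
#' @param outcomes Character vector of outcome names.
#' @param moderator_specs Moderator specification table.
#' @param peer_groups,waves Grid axes.
#' @param hc Robust variant for linear fits.
#' @param alpha_sig Interaction significance criterion.
#' @return A `model_grid`: `moderator`, `fits` (list of `peer_fit`s),
#'   `results` (tidy one-row-per-model data frame) and `alpha_sig`.
#' @export
run_model_grid <- function(moderator, cohort, exposures, outcomes,
                           moderator_specs = default_moderator_specs(),
                           peer_groups = c("friends", "class", "year"),
                           waves = c(0L, 1L), hc = "HC1", alpha_sig = 0.01) {
  specs <- grid_specs(moderator, outcomes, moderator_specs, peer_groups, waves)
  fits <- lapply(specs, function(sp) {
    des <- tryCatch(build_design(sp, cohort, exposures, moderator_specs),
                    error = function(e) e)
    if (inherits(des, "error")) {
      des <- structure(list(spec = sp, n = 0L, n_dropped = NA_integer_,
                            moderator_type = NA, level0 = NA, level1 = NA,
                            unfit_reason = conditionMessage(des)),
                       class = "model_design")
    }
    fitter <- if (sp$family == "logistic") logit_fit_robust else {
      function(d) ols_fit_hc(d, hc = hc)
    }
    tryCatch(fitter(des), error = function(e) {
      des$unfit_reason <- conditionMessage(e)
      .unfit_result(des, sp$family)
    })
  })
  results <- do.call(rbind, lapply(fits, .fit_row))
  rownames(results) <- NULL
  structure(list(moderator = moderator, fits = fits, results = results,
                 alpha_sig = alpha_sig),
            class = "model_grid")
}

.fit_row <- function(f) {
  s <- f$spec
  data.frame(
    moderator = s$moderator, outcome = s$outcome, family = f$family,
    peer_group = s$peer_group, wave = s$wave, n = f$n,
    b_interaction = f$b_interaction, se_interaction = f$se_interaction,
    p_interaction = f$p_interaction, beta_std = f$beta_std,
    delta_r2 = f$delta_r2, r_squared = f$r_squared,
    max_vif = if (is.null(f$vif)) NA_real_ else max(f$vif),
    vif_gt5 = isTRUE(f$vif_gt5), vif_gt10 = isTRUE(f$vif_gt10),
    unfit = !is.null(f$unfit_reason),
    unfit_reason = f$unfit_reason %||% "",
    stringsAsFactors = FALSE)
}

#' @export
print.model_grid <- function(x, ...) {
  r <- x$results
  cat(sprintf("<model_grid> moderator '%s': %d models (%d unfit), %d with interaction p <= %g\n",
              x$moderator, nrow(r), sum(r$unfit),
              sum(r$p_interaction <= x$alpha_sig, na.rm = TRUE), x$alpha_sig))
  invisible(x)
}
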