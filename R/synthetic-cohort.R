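#' Generate a synthetic school cohort with friendship nominations
#'
#' Draws a pupil roster with the clustered structure the moderation analysis
#' assumes (pupils nested in classes nested in schools across two settings
#' and two intervention programmes), baseline moderator scores and outcome
#' values (truncated normal within each outcome's scale bounds), homophilous
#' friendship nominations at both waves, and follow-up outcomes from a
#' linear data-generating process with a planted peer-influence effect and a
#' planted peer-by-moderator interaction:
#'
#' \deqn{y_{i1} = b_0 + b_{base} y_{i0} + b_{peer} \bar{x}_i +
#'       b_{mod} (w_i - \bar w) + b_{int} (\bar{x}_i - \bar{\bar x})(w_i -
#'       \bar w) + \epsilon_i,}
#'
#' where \eqn{\bar{x}_i} is the mean baseline value of pupil i's nominated
#' friends, \eqn{w_i} the configured moderator, and \eqn{\epsilon_i}
#' Gaussian noise; results are truncated to the outcome's bounds. The binary
#' susceptibility outcome follows the logistic analogue with a standardized
#' percent-susceptible peer predictor. Follow-up values are set missing
#' completely at random for a `missing_rate` fraction of pupils.
#'
#' @param config A [cohort_config()] object.
#' @return A list with elements `cohort` (one row per pupil: ids, school and
#'   class membership, attributes, moderator scores, and `<outcome>_w0` /
#'   `<outcome>_w1` value columns) and `nominations` (a data frame with
#'   columns `nominator_id`, `nominee_id`, `wave`).
#' @examples
#' cfg <- cohort_config(seed = 1, n_schools = 2, classes_per_school = 2,
#'                      pupils_per_class = 10)
#' cohort <- generate_cohort(cfg)
#' table(cohort$cohort$school_id)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- withr::with_seed(config$seed, .draw_baseline(config))
  noms0 <- generate_nominations(cohort, config, wave = 0L)
  cohort <- withr::with_seed(config$seed + 31L,
                             .draw_follow_up(cohort, noms0, config))
  noms1 <- generate_nominations(cohort, config, wave = 1L)
  cohort <- withr::with_seed(config$seed + 57L,
                             .apply_missingness(cohort, config))
  list(cohort = cohort, nominations = rbind(noms0, noms1))
}

.draw_baseline <- function(config) {
  cps <- config$classes_per_school
  n_sch <- config$n_schools
  ppc <- config$pupils_per_class
  school_id <- rep(seq_len(n_sch), times = cps * ppc)
  class_in_school <- unlist(lapply(cps, function(k) rep(seq_len(k), each = ppc)))
  n <- length(school_id)
  cohort <- data.frame(
    pupil_id = seq_len(n),
    school_id = school_id,
    class_id = sprintf("S%02d_C%02d", school_id, class_in_school),
    stringsAsFactors = FALSE
  )
  n_ni <- round(n_sch * config$setting_split)
  school_setting <- rep("Bogota", n_sch)
  if (n_ni > 0) school_setting[seq_len(n_ni)] <- "NI"
  # interventions allocated within setting
  school_intervention <- rep("DeadCool", n_sch)
  for (st in unique(school_setting)) {
    idx <- which(school_setting == st)
    k <- round(length(idx) * config$intervention_split)
    if (k > 0) school_intervention[idx[seq_len(k)]] <- "ASSIST"
  }
  cohort$setting <- school_setting[cohort$school_id]
  cohort$intervention <- school_intervention[cohort$school_id]
  cohort$gender <- sample(c("boy", "girl_pnts"), n, TRUE, prob = c(0.465, 0.535))
  cohort$age_band <- sample(c("11-12", "13", "14-15"), n, TRUE,
                            prob = c(0.36, 0.50, 0.14))
  cohort$ethnicity <- sample(c("minority", "majority"), n, TRUE,
                             prob = c(0.103, 0.897))
  cohort$ses_individual <- sample(1:3, n, TRUE, prob = c(0.50, 0.39, 0.11))
  # school-level SES: NI schools carry a raw deprivation score (higher =
  # more deprived) quartiled into 1-4; Bogota schools an index drawn 1-4
  ni_schools <- which(school_setting == "NI")
  school_dep <- rep(NA_real_, n_sch)
  school_ses <- rep(NA_real_, n_sch)
  if (length(ni_schools) > 0) {
    school_dep[ni_schools] <- stats::runif(length(ni_schools), 5.7, 80.2)
    if (length(ni_schools) >= 4) {
      school_ses[ni_schools] <- derive_school_ses(school_dep[ni_schools])
    } else {
      school_ses[ni_schools] <- sample(1:4, length(ni_schools), TRUE)
    }
  }
  bog <- which(school_setting == "Bogota")
  school_ses[bog] <- sample(1:4, length(bog), TRUE, prob = c(.15, .35, .35, .15))
  cohort$school_deprivation <- school_dep[cohort$school_id]
  cohort$school_ses <- school_ses[cohort$school_id]
  # attribute moderators: truncated normal per configured range/mean/sd
  mspec <- config$moderator_specs
  gen <- mspec[mspec$source == "attribute" & !is.na(mspec$gen_mean), ]
  for (i in seq_len(nrow(gen))) {
    cohort[[gen$name[i]]] <- rtrunc_norm(n, gen$gen_mean[i], gen$gen_sd[i],
                                         gen$range_min[i], gen$range_max[i])
  }
  # baseline outcomes
  ospec <- config$outcome_specs
  for (i in seq_len(nrow(ospec))) {
    nm <- outcome_col(ospec$name[i], 0)
    if (ospec$is_binary[i]) {
      cohort[[nm]] <- stats::rbinom(n, 1, ospec$baseline_mean[i])
    } else {
      cohort[[nm]] <- rtrunc_norm(n, ospec$baseline_mean[i],
                                  ospec$baseline_sd[i],
                                  ospec$scale_min[i], ospec$scale_max[i])
    }
  }
  cohort
}

.dgp_moderator_values <- function(cohort, config) {
  w <- cohort[[config$dgp$moderator]]
  if (is.null(w)) {
    pm_stop("dgp moderator '%s' not found in cohort", config$dgp$moderator)
  }
  if (!is.numeric(w)) w <- as.numeric(factor(w)) - 1
  w
}

.friend_baseline_means <- function(cohort, noms, values) {
  # mean of nominated friends' baseline values; pupils with no informative
  # friends fall back to the cohort mean so the DGP is defined everywhere
  v <- values[match(noms$nominee_id, cohort$pupil_id)]
  ok <- !is.na(v)
  out <- rep(NA_real_, nrow(cohort))
  if (any(ok)) {
    s <- rowsum(v[ok], noms$nominator_id[ok])
    k <- rowsum(rep(1, sum(ok)), noms$nominator_id[ok])
    idx <- match(as.integer(rownames(s)), cohort$pupil_id)
    out[idx] <- s / k
  }
  out[is.na(out)] <- mean(values, na.rm = TRUE)
  out
}

.draw_follow_up <- function(cohort, noms0, config) {
  n <- nrow(cohort)
  dg <- config$dgp
  w <- .dgp_moderator_values(cohort, config)
  wc <- w - mean(w)
  ospec <- config$outcome_specs
  for (i in seq_len(nrow(ospec))) {
    o <- ospec$name[i]
    y0 <- cohort[[outcome_col(o, 0)]]
    if (ospec$is_binary[i]) {
      pct <- .friend_baseline_means(cohort, noms0, 100 * y0)
      z <- pct - mean(pct)
      if (stats::sd(pct) > 0) z <- z / stats::sd(pct)
      eta <- stats::qlogis(dg$follow_up_rate) +
        dg$b_base_binary * (y0 - mean(y0)) +
        dg$b_peer_binary * z + dg$b_mod * wc + dg$b_int * z * wc
      cohort[[outcome_col(o, 1)]] <- stats::rbinom(n, 1, stats::plogis(eta))
    } else {
      xbar <- .friend_baseline_means(cohort, noms0, y0)
      xc <- xbar - mean(xbar)
      b0 <- dg$b0 + (1 - dg$b_base - dg$b_peer) * ospec$baseline_mean[i]
      mu <- b0 + dg$b_base * y0 + dg$b_peer * xbar +
        dg$b_mod * wc + dg$b_int * xc * wc
      noise_sd <- dg$noise_scale * ospec$baseline_sd[i]
      y1 <- mu + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
      cohort[[outcome_col(o, 1)]] <- clamp(y1, ospec$scale_min[i],
                                           ospec$scale_max[i])
    }
  }
  cohort
}

.apply_missingness <- function(cohort, config) {
  if (config$missing_rate <= 0) return(cohort)
  drop <- stats::runif(nrow(cohort)) < config$missing_rate
  w1_cols <- grep("_w1$", names(cohort), value = TRUE)
  for (cl in w1_cols) cohort[[cl]][drop] <- NA
  cohort
}

#' Generate friendship nominations for a cohort
#'
#' Each pupil names up to ten friends from their school-year roster. The
#' out-degree is Binomial(10, mean/10), which enforces the nomination cap by
#' construction; nominees are sampled without replacement from schoolmates
#' with weights multiplied by the within-class and same-gender homophily
#' ratios. Nominations are restricted to the pupil's own school, contain no
#' self-nominations and no duplicates.
#'
#' @param cohort Cohort data frame (from [generate_cohort()]'s `cohort`).
#' @param config A [cohort_config()].
#' @param wave Wave label (0 baseline, 1 follow-up); also offsets the seed so
#'   the two waves are independent draws from the same nomination model.
#' @return Data frame with columns `nominator_id`, `nominee_id`, `wave`.
#' @export
generate_nominations <- function(cohort, config, wave = 0L) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(cohort) == 0) pm_stop("generate_nominations(): empty roster")
  m <- config$nomination_mean_outdegree
  if (m > 10) pm_stop("nomination_mean_outdegree exceeds the cap of 10")
  withr::with_seed(config$seed + 7919L * (as.integer(wave) + 1L), {
    if (m == 0) {
      return(data.frame(nominator_id = integer(0), nominee_id = integer(0),
                        wave = integer(0)))
    }
    k <- stats::rbinom(nrow(cohort), 10L, m / 10)
    nominee <- vector("list", nrow(cohort))
    by_school <- split(seq_len(nrow(cohort)), cohort$school_id)
    rc <- config$within_class_nomination_prob_ratio
    rg <- config$same_gender_nomination_prob_ratio
    for (rows in by_school) {
      cls <- cohort$class_id[rows]
      gen <- cohort$gender[rows]
      ids <- cohort$pupil_id[rows]
      for (j in seq_along(rows)) {
        i <- rows[j]
        if (k[i] == 0 || length(rows) < 2) next
        cand <- seq_along(rows)[-j]
        wts <- ifelse(cls[cand] == cls[j], rc, 1) *
               ifelse(gen[cand] == gen[j], rg, 1)
        if (all(wts == 0)) next
        take <- min(k[i], sum(wts > 0))
        pick <- cand[wts > 0]
        sel <- if (length(pick) == 1L) pick else {
          sample(pick, take, prob = wts[wts > 0])
        }
        nominee[[i]] <- ids[sel]
      }
    }
    counts <- lengths(nominee)
    out <- data.frame(
      nominator_id = rep(cohort$pupil_id, counts),
      nominee_id = unlist(nominee[counts > 0], use.names = FALSE) %||%
        integer(0),
      wave = as.integer(wave))
    rownames(out) <- NULL
    out
  })
}

#' Generate item-level responses from a scale score
#'
#' Builds an item matrix around a latent scale score for testing reliability
#' computations: each item is `loading * latent + (1 - loading) * noise`
#' with the noise SD matched to the latent SD, so the expected inter-item
#' correlation is `loading^2 / (loading^2 + (1 - loading)^2)` and increases
#' monotonically with the loading.
#'
#' @param scale_score Numeric vector of latent scores (one per respondent).
#' @param n_items Number of items (>= 2).
#' @param loading Common loading in `[0, 1]`.
#' @param seed Optional seed for the noise draws.
#' @param bounds Optional length-2 numeric; items are truncated into these
#'   scale bounds (left untruncated when `NULL`).
#' @return Numeric matrix, respondents x items.
#' @export
generate_item_responses <- function(scale_score, n_items, loading,
                                    seed = NULL, bounds = NULL) {
  if (!is_count(n_items) || n_items < 2) pm_stop("n_items must be >= 2")
  if (loading < 0 || loading > 1) pm_stop("loading must lie in [0, 1]")
  draw <- function() {
    n <- length(scale_score)
    s <- stats::sd(scale_score)
    if (is.na(s)) s <- 0
    noise <- matrix(stats::rnorm(n * n_items, 0, s), n, n_items)
    items <- loading * scale_score + (1 - loading) * noise
    if (!is.null(bounds)) items <- clamp(items, bounds[1], bounds[2])
    colnames(items) <- paste0("item", seq_len(n_items))
    items
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Write cohort and nomination tables as CSV
#'
#' @param x List from [generate_cohort()].
#' @param cohort_path,nominations_path Output file paths.
#' @return Invisibly, the input `x`.
#' @export
write_cohort <- function(x, cohort_path, nominations_path) {
  utils::write.csv(x$cohort, cohort_path, row.names = FALSE)
  utils::write.csv(x$nominations, nominations_path, row.names = FALSE)
  invisible(x)
}
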