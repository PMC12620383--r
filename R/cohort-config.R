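#' Default outcome specifications
#'
#' The 46 smoking/vaping outcomes tracked by the pipeline: experimentally
#' measured injunctive norms (eight social-appropriateness vignettes P2S2-P2S9
#' plus their scale mean), experimentally measured descriptive norms (P3Q1,
#' P3Q2 plus scale), experimental donations, self-report injunctive norms
#' (IN1-IN7 plus scale), self-report descriptive norms (DN1.1-DN1.5 and
#' DN2.1-DN2.3 plus scales), self-report smoking behaviour, intentions,
#' knowledge, attitudes, the three self-efficacy subscales, perceived risks
#' (physical, social, addiction), perceived benefits, the two perceived
#' behavioural control items, objectively measured expelled-air carbon
#' monoxide, and the binary susceptibility-to-smoking flag. Baseline means
#' and standard deviations are the generator's defaults for drawing baseline
#' values.
#'
#' @return A data frame with one row per outcome: `name`, `family`
#'   (`"experimental_norms"`, `"self_report_norms"` or `"other"`),
#'   `scale_min`, `scale_max`, `baseline_mean`, `baseline_sd`, `is_binary`.
#' @export
default_outcome_specs <- function() {
  spec <- function(name, family, lo, hi, m, s, bin = FALSE) {
    data.frame(name = name, family = family, scale_min = lo, scale_max = hi,
               baseline_mean = m, baseline_sd = s, is_binary = bin,
               stringsAsFactors = FALSE)
  }
  rbind(
    spec("p2s2", "experimental_norms", -1, 1, -0.9, 0.3),
    spec("p2s3", "experimental_norms", -1, 1, -0.7, 0.4),
    spec("p2s4", "experimental_norms", -1, 1, -0.9, 0.3),
    spec("p2s5", "experimental_norms", -1, 1, -0.4, 0.4),
    spec("p2s6", "experimental_norms", -1, 1, -0.5, 0.4),
    spec("p2s7", "experimental_norms", -1, 1, -0.5, 0.4),
    spec("p2s8", "experimental_norms", -1, 1, -0.5, 0.4),
    spec("p2s9", "experimental_norms", -1, 1, -0.8, 0.3),
    spec("exp_injunctive_scale", "experimental_norms", -1, 1, -0.6, 0.2),
    spec("p3q1", "experimental_norms", -1, 1, -0.5, 0.5),
    spec("p3q2", "experimental_norms", -1, 1, -0.4, 0.6),
    spec("exp_descriptive_scale", "experimental_norms", -1, 1, -0.4, 0.5),
    spec("donation", "experimental_norms", 0, 10, 3.7, 2.9),
    spec("in1", "self_report_norms", -2, 2, 1.7, 0.7),
    spec("in2", "self_report_norms", -2, 2, 1.9, 0.4),
    spec("in3", "self_report_norms", -2, 2, 1.7, 0.7),
    spec("in4", "self_report_norms", -2, 2, 1.4, 0.9),
    spec("in5", "self_report_norms", -2, 2, 1.4, 0.9),
    spec("in6", "self_report_norms", -2, 2, 1.4, 0.9),
    spec("in7", "self_report_norms", -2, 2, 1.6, 0.8),
    spec("sr_injunctive_scale", "self_report_norms", -2, 2, 1.6, 0.5),
    spec("dn1_1", "self_report_norms", 1, 5, 4.8, 0.7),
    spec("dn1_2", "self_report_norms", 1, 5, 4.4, 1.2),
    spec("dn1_3", "self_report_norms", 1, 5, 4.3, 1.3),
    spec("dn1_4", "self_report_norms", 1, 5, 4.7, 0.8),
    spec("dn1_5", "self_report_norms", 1, 5, 4.8, 0.7),
    spec("sr_descriptive_scale1", "self_report_norms", 1, 5, 4.6, 0.6),
    spec("dn2_1", "self_report_norms", 1, 5, 4.7, 0.7),
    spec("dn2_2", "self_report_norms", 1, 5, 4.3, 1.0),
    spec("dn2_3", "self_report_norms", 1, 5, 4.8, 0.6),
    spec("sr_descriptive_scale2", "self_report_norms", 1, 5, 4.6, 0.5),
    spec("smoking_behavior", "other", 1, 4, 3.8, 0.6),
    spec("intentions", "other", 1, 6, 5.6, 1.0),
    spec("knowledge", "other", 0, 6, 2.6, 1.5),
    spec("attitudes", "other", 1, 5, 3.9, 0.6),
    spec("self_efficacy_emotional", "other", 1, 6, 5.6, 0.8),
    spec("self_efficacy_friends", "other", 1, 6, 5.6, 0.8),
    spec("self_efficacy_opportunity", "other", 1, 6, 5.8, 0.6),
    spec("perceived_physical_risks", "other", 0, 100, 60.9, 24.2),
    spec("perceived_social_risks", "other", 0, 100, 68.1, 26.8),
    spec("perceived_addiction_risks", "other", 0, 100, 35.2, 26.1),
    spec("perceived_benefits", "other", 0, 100, 23.6, 21.5),
    spec("pbc_easy_quit", "other", 1, 5, 3.0, 1.4),
    spec("pbc_avoid", "other", 1, 5, 4.2, 1.2),
    spec("co_reading", "other", 0, 30, 2.5, 1.7),
    spec("susceptibility", "other", 0, 1, 0.341, NA, bin = TRUE)
  )
}

#' Default moderator specifications
#'
#' The moderators examined by the pipeline. `type` is `"dichotomous"` or
#' `"continuous"`; `source` records where the moderator value lives:
#' `"attribute"` (a cohort column), `"network_node"` (per-pupil network
#' metric at the wave of peer measurement), `"network_school"` (school-level
#' Gini degree coefficient at the wave of peer measurement) or
#' `"outcome_baseline"` (a baseline outcome doubling as a moderator, i.e.
#' the self-efficacy subscales, whose grids exclude the self-efficacy
#' outcomes). For dichotomous moderators `level0`/`level1` give the 0/1
#' coding labels; for continuous moderators the positive interaction
#' direction reads "stronger peer influence at higher moderator values".
#' `gen_mean`/`gen_sd` parameterise the synthetic generator's truncated
#' normal draws for attribute moderators.
#'
#' @return A data frame with one row per moderator.
#' @export
default_moderator_specs <- function() {
  ms <- function(name, type, source, level0 = NA, level1 = NA,
                 lo = NA, hi = NA, m = NA, s = NA, hypothesis = NA) {
    data.frame(name = name, type = type, source = source,
               level0 = level0, level1 = level1,
               range_min = lo, range_max = hi, gen_mean = m, gen_sd = s,
               hypothesis = hypothesis, stringsAsFactors = FALSE)
  }
  rbind(
    ms("setting", "dichotomous", "attribute", "NI", "Bogota",
       hypothesis = "positive"),
    ms("intervention", "dichotomous", "attribute", "DeadCool", "ASSIST",
       hypothesis = "positive"),
    ms("gender", "dichotomous", "attribute", "boy", "girl_pnts",
       hypothesis = "positive"),
    ms("school_ses", "continuous", "attribute", lo = 1, hi = 4,
       hypothesis = "negative"),
    ms("rule_following", "continuous", "attribute", lo = 0, hi = 5,
       m = 3.1, s = 1.8, hypothesis = "positive"),
    ms("pro_sociality", "continuous", "attribute", lo = 0, hi = 10,
       m = 7.7, s = 2.1, hypothesis = "positive"),
    ms("fne", "continuous", "attribute", lo = 1, hi = 5,
       m = 2.7, s = 0.7, hypothesis = "positive"),
    ms("ntb", "continuous", "attribute", lo = 1, hi = 5,
       m = 3.0, s = 0.6, hypothesis = "positive"),
    ms("openness", "continuous", "attribute", lo = 0, hi = 4,
       m = 2.6, s = 0.7, hypothesis = "exploratory"),
    ms("extraversion", "continuous", "attribute", lo = 0, hi = 4,
       m = 2.6, s = 0.7, hypothesis = "exploratory"),
    ms("agreeableness", "continuous", "attribute", lo = 0, hi = 4,
       m = 2.6, s = 0.7, hypothesis = "exploratory"),
    ms("conscientiousness", "continuous", "attribute", lo = 0, hi = 4,
       m = 2.3, s = 0.7, hypothesis = "exploratory"),
    ms("emotional_stability", "continuous", "attribute", lo = 0, hi = 4,
       m = 2.0, s = 0.8, hypothesis = "exploratory"),
    ms("clustering", "continuous", "network_node", lo = 0, hi = 10,
       hypothesis = "positive"),
    ms("eigenvector", "continuous", "network_node", lo = 0, hi = 10,
       hypothesis = "positive"),
    ms("closeness", "continuous", "network_node", lo = 0, hi = 10,
       hypothesis = "positive"),
    ms("betweenness", "continuous", "network_node", lo = 0, hi = 10,
       hypothesis = "positive"),
    ms("gini_degree", "continuous", "network_school", lo = 0, hi = 10,
       hypothesis = "negative"),
    ms("self_efficacy_emotional", "continuous", "outcome_baseline",
       lo = 1, hi = 6, hypothesis = "negative"),
    ms("self_efficacy_friends", "continuous", "outcome_baseline",
       lo = 1, hi = 6, hypothesis = "negative"),
    ms("self_efficacy_opportunity", "continuous", "outcome_baseline",
       lo = 1, hi = 6, hypothesis = "negative")
  )
}

#' Synthetic cohort configuration
#'
#' Defines the statistical structure of a synthetic school cohort: 12
#' schools split across two settings, 55 classes, 25 pupils per class
#' (~1,375 pupils), homophilous friendship nominations capped at 10 per
#' pupil, bounded outcomes with autoregressive baseline dependence, and a
#' planted peer-influence/moderation data-generating process for follow-up
#' values.
#'
#' @param seed Integer seed; identical `(config, seed)` pairs produce
#'   byte-identical cohorts.
#' @param n_schools Number of schools (split across the two settings).
#' @param classes_per_school Classes per school; a scalar or a vector of
#'   length `n_schools`. The default gives 55 classes over 12 schools.
#' @param pupils_per_class Pupils per class.
#' @param setting_split Fraction of schools assigned to the first setting
#'   (`"NI"`); the remainder are `"Bogota"`.
#' @param intervention_split Fraction of schools per setting assigned to
#'   `"ASSIST"`; the remainder run `"DeadCool"`.
#' @param nomination_mean_outdegree Expected nominations per pupil; the
#'   draw is Binomial(10, mean/10) so the cap of 10 holds by construction.
#' @param within_class_nomination_prob_ratio Multiplier on the sampling
#'   weight of same-class schoolmates.
#' @param same_gender_nomination_prob_ratio Multiplier for same-gender
#'   schoolmates.
#' @param outcome_specs Data frame as returned by
#'   [default_outcome_specs()]; may be subset or replaced.
#' @param moderator_specs Data frame as returned by
#'   [default_moderator_specs()].
#' @param dgp Named list of data-generating-process coefficients:
#'   `b0` (intercept offset), `b_base` (autoregression on the baseline
#'   value), `b_peer` (main peer-exposure effect), `b_mod` (moderator main
#'   effect), `b_int` (peer-by-moderator interaction), `noise_scale`
#'   (residual SD as a multiple of the outcome's baseline SD), `moderator`
#'   (name of the attribute moderator driving the planted interaction),
#'   `b_base_binary`, `b_peer_binary` (logit-scale analogues for the binary
#'   susceptibility outcome) and `follow_up_rate` (target marginal
#'   susceptibility rate at follow-up).
#' @param missing_rate Fraction of pupils missing the entire follow-up
#'   assessment, completely at random.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(seed,
                          n_schools = 12L,
                          classes_per_school = c(6L, 6L, 5L, 5L, 5L, 4L,
                                                 4L, 4L, 4L, 4L, 4L, 4L),
                          pupils_per_class = 25L,
                          setting_split = 0.5,
                          intervention_split = 0.5,
                          nomination_mean_outdegree = 5,
                          within_class_nomination_prob_ratio = 8,
                          same_gender_nomination_prob_ratio = 3,
                          outcome_specs = default_outcome_specs(),
                          moderator_specs = default_moderator_specs(),
                          dgp = list(),
                          missing_rate = 0.07) {
  if (missing(seed) || !is_count(seed)) {
    pm_stop("cohort_config(): an integer `seed` is required")
  }
  if (!is_count(n_schools) || n_schools < 1) {
    pm_stop("n_schools must be a positive count")
  }
  if (length(classes_per_school) == 1L) {
    classes_per_school <- rep(classes_per_school, n_schools)
  }
  if (length(classes_per_school) != n_schools ||
      !is_count(classes_per_school) || any(classes_per_school < 1)) {
    pm_stop("classes_per_school must be positive counts of length 1 or n_schools")
  }
  if (!is_count(pupils_per_class) || pupils_per_class < 2) {
    pm_stop("pupils_per_class must be a count >= 2")
  }
  for (p in c(setting_split, intervention_split, missing_rate)) {
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
      pm_stop("splits and missing_rate must lie in [0, 1]")
    }
  }
  if (nomination_mean_outdegree < 0 || nomination_mean_outdegree > 10) {
    pm_stop("nomination_mean_outdegree must lie in [0, 10] (nomination cap)")
  }
  if (within_class_nomination_prob_ratio < 0 ||
      same_gender_nomination_prob_ratio < 0) {
    pm_stop("homophily ratios must be non-negative")
  }
  stopifnot(is.data.frame(outcome_specs),
            all(c("name", "scale_min", "scale_max", "is_binary") %in%
                  names(outcome_specs)))
  bad <- outcome_specs$scale_min >= outcome_specs$scale_max
  if (any(bad)) {
    pm_stop("outcome_specs: scale_min >= scale_max for %s",
            paste(outcome_specs$name[bad], collapse = ", "))
  }
  dgp_def <- list(b0 = 0, b_base = 0.5, b_peer = 0.25, b_mod = 0.1,
                  b_int = 0.1, noise_scale = 0.6,
                  moderator = "pro_sociality",
                  b_base_binary = 2, b_peer_binary = 0.5,
                  follow_up_rate = 0.38)
  dgp <- utils::modifyList(dgp_def, dgp)
  structure(list(
    seed = as.integer(seed),
    n_schools = as.integer(n_schools),
    classes_per_school = as.integer(classes_per_school),
    pupils_per_class = as.integer(pupils_per_class),
    setting_split = setting_split,
    intervention_split = intervention_split,
    nomination_mean_outdegree = nomination_mean_outdegree,
    within_class_nomination_prob_ratio = within_class_nomination_prob_ratio,
    same_gender_nomination_prob_ratio = same_gender_nomination_prob_ratio,
    outcome_specs = outcome_specs,
    moderator_specs = moderator_specs,
    dgp = dgp,
    missing_rate = missing_rate
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d schools, %d classes, %d pupils (seed %d)\n",
              x$n_schools, sum(x$classes_per_school),
              sum(x$classes_per_school) * x$pupils_per_class, x$seed))
  cat(sprintf("  %d outcomes (%d binary), %d moderators\n",
              nrow(x$outcome_specs), sum(x$outcome_specs$is_binary),
              nrow(x$moderator_specs)))
  cat(sprintf("  dgp: b_base=%.3g b_peer=%.3g b_mod=%.3g b_int=%.3g on %s\n",
              x$dgp$b_base, x$dgp$b_peer, x$dgp$b_mod, x$dgp$b_int,
              x$dgp$moderator))
  invisible(x)
}
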