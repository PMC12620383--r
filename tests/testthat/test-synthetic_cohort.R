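test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(seed = 1, n_schools = 0), "positive count")
  expect_error(cohort_config(seed = 1, pupils_per_class = 1), ">= 2")
  expect_error(cohort_config(seed = 1, nomination_mean_outdegree = 11),
               "cap")
  expect_error(cohort_config(seed = 1, missing_rate = 1.2), "\\[0, 1\\]")
  bad <- default_outcome_specs()
  bad$scale_min[1] <- bad$scale_max[1]
  expect_error(cohort_config(seed = 1, outcome_specs = bad), "scale_min")
})

test_that("identical seed and config give byte-identical output", {
  cfg <- small_cohort_config(seed = 404)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$nominations, b$nominations)
  c2 <- generate_cohort(small_cohort_config(seed = 405))
  expect_false(identical(a$cohort, c2$cohort))
})

test_that("default cohort reproduces the assumed study structure", {
  gen <- generate_cohort(cohort_config(seed = 7))
  co <- gen$cohort
  expect_equal(length(unique(co$school_id)), 12)
  expect_equal(length(unique(co$class_id)), 55)
  expect_gte(nrow(co), 1300)
  expect_setequal(unique(co$setting), c("NI", "Bogota"))
  expect_setequal(unique(co$intervention), c("ASSIST", "DeadCool"))
  # class nested in school
  expect_true(all(rowSums(table(co$class_id, co$school_id) > 0) == 1))
  # every outcome within its declared bounds (or missing)
  ospec <- default_outcome_specs()
  for (i in seq_len(nrow(ospec))) {
    for (w in 0:1) {
      v <- co[[paste0(ospec$name[i], "_w", w)]]
      v <- v[!is.na(v)]
      expect_true(all(v >= ospec$scale_min[i] & v <= ospec$scale_max[i]),
                  label = sprintf("%s wave %d in bounds", ospec$name[i], w))
    }
  }
  expect_true(all(co$susceptibility_w0 %in% 0:1))
  expect_true(all(co$susceptibility_w1 %in% c(0, 1, NA)))
  # missingness applied at roughly the configured rate
  miss <- mean(is.na(co$p2s2_w1))
  expect_gt(miss, 0.03)
  expect_lt(miss, 0.12)
})

test_that("identity DGP returns follow-up equal to baseline", {
  cfg <- small_cohort_config(
    seed = 11,
    dgp = list(b_base = 1, b_peer = 0, b_mod = 0, b_int = 0,
               noise_scale = 0),
    missing_rate = 0)
  gen <- generate_cohort(cfg)
  ospec <- cfg$outcome_specs
  for (o in ospec$name[!ospec$is_binary]) {
    expect_equal(gen$cohort[[paste0(o, "_w1")]],
                 gen$cohort[[paste0(o, "_w0")]],
                 label = paste(o, "identity"))
  }
})

test_that("nominations respect cap, roster, and no self/duplicate rules", {
  cfg <- small_cohort_config(seed = 5, pupils_per_class = 20L)
  gen <- generate_cohort(cfg)
  co <- gen$cohort
  noms <- gen$nominations
  expect_setequal(unique(noms$wave), c(0, 1))
  for (w in 0:1) {
    nw <- noms[noms$wave == w, ]
    expect_true(all(table(nw$nominator_id) <= 10))
    expect_false(any(nw$nominator_id == nw$nominee_id))
    expect_false(any(duplicated(nw[, c("nominator_id", "nominee_id")])))
    same_school <- co$school_id[match(nw$nominator_id, co$pupil_id)] ==
      co$school_id[match(nw$nominee_id, co$pupil_id)]
    expect_true(all(same_school))
  }
})

test_that("zero mean out-degree gives an empty nomination list", {
  cfg <- small_cohort_config(seed = 2, nomination_mean_outdegree = 0)
  gen <- generate_cohort(cfg)
  expect_equal(nrow(gen$nominations), 0)
})

test_that("extreme within-class homophily keeps all nominations in class", {
  cfg <- small_cohort_config(seed = 3,
                             within_class_nomination_prob_ratio = 1e6,
                             same_gender_nomination_prob_ratio = 1)
  gen <- generate_cohort(cfg)
  co <- gen$cohort
  noms <- gen$nominations
  same_class <- co$class_id[match(noms$nominator_id, co$pupil_id)] ==
    co$class_id[match(noms$nominee_id, co$pupil_id)]
  # class size 15 > cap 10, so weight mass ~entirely in class
  expect_true(mean(same_class) > 0.999)
})

test_that("without homophily nominees are uniform over schoolmates", {
  # one school, two classes; ratios 1 => every schoolmate equally likely.
  # chi-square goodness of fit over all nominations at alpha = 0.01.
  cfg <- cohort_config(seed = 13, n_schools = 1L, classes_per_school = 2L,
                       pupils_per_class = 25L,
                       nomination_mean_outdegree = 5,
                       within_class_nomination_prob_ratio = 1,
                       same_gender_nomination_prob_ratio = 1)
  gen <- generate_cohort(cfg)
  counts <- rep(0, 50)
  # accumulate nominee counts over repeated waves for power
  for (w in 0:19) {
    noms <- generate_nominations(gen$cohort, cfg, wave = w)
    tab <- table(factor(noms$nominee_id, levels = 1:50))
    counts <- counts + as.numeric(tab)
  }
  expect_gt(sum(counts), 4000)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("item generator reproduces closed-form reliability", {
  # loading 1: identical items, alpha exactly 1
  lat <- rnorm(50)
  it1 <- generate_item_responses(lat, 4, loading = 1, seed = 1)
  expect_equal(cronbach_alpha(it1), 1)
  # loading 0: independent items, alpha ~ 0 in expectation over many draws
  a0 <- mean(sapply(1:40, function(s) {
    cronbach_alpha(generate_item_responses(rnorm(200), 4, 0, seed = s))
  }))
  expect_lt(abs(a0), 0.1)
  # loading 0.7, 8 items: alpha within 0.03 of the generator-implied
  # closed form rho = l^2/(l^2 + (1-l)^2), alpha = k rho / (1 + (k-1) rho)
  l <- 0.7; k <- 8
  rho <- l^2 / (l^2 + (1 - l)^2)
  alpha_cf <- k * rho / (1 + (k - 1) * rho)
  it <- generate_item_responses(rnorm(5000), k, l, seed = 99)
  expect_equal(cronbach_alpha(it), alpha_cf, tolerance = 0.03)
  expect_error(generate_item_responses(rnorm(10), 1, 0.5), ">= 2")
})

test_that("planted interaction is recovered by the moderation engine", {
  # parameter-recovery oracle at reduced scale: mean fitted interaction
  # coefficient across replicates within Monte-Carlo error of the truth
  b_true <- 0.5
  ospec <- data.frame(name = "score", family = "other", scale_min = 0,
                      scale_max = 100, baseline_mean = 50, baseline_sd = 10,
                      is_binary = FALSE, stringsAsFactors = FALSE)
  est <- sapply(1:30, function(s) {
    cfg <- cohort_config(seed = 1000 + s, n_schools = 2L,
                         classes_per_school = 4L, pupils_per_class = 25L,
                         outcome_specs = ospec,
                         dgp = list(b_int = b_true, moderator = "pro_sociality"),
                         missing_rate = 0)
    gen <- generate_cohort(cfg)
    ex <- build_exposure_table(gen$cohort, gen$nominations, "score",
                               peer_groups = "friends", waves = 0L)
    sp <- model_spec("score", "friends", 0L, "pro_sociality")
    fit <- ols_fit_hc(build_design(sp, gen$cohort, ex))
    fit$b_interaction
  })
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - b_true), 4 * mcse)
})
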