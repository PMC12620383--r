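test_that("mean centering subtracts the sample mean and is idempotent", {
  expect_equal(mean_center(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(mean_center(rep(4, 5)), rep(0, 5))
  x <- rnorm(10)
  expect_equal(mean_center(mean_center(x)), mean_center(x))
  expect_equal(mean_center(c(1, NA, 3)), c(-1, NA, 1))
  expect_error(mean_center(c(NA_real_, NA_real_)), "all values missing")
})

test_that("design construction centers, codes and deletes listwise", {
  cfg <- small_cohort_config(seed = 31, pupils_per_class = 20L,
                             missing_rate = 0)
  gen <- generate_cohort(cfg)
  co <- gen$cohort
  ex <- build_exposure_table(co, gen$nominations, "intentions")
  # dichotomous moderator coded 0/1; product equals exposure on level-1 rows
  sp <- model_spec("intentions", "class", 0L, "setting")
  d <- build_design(sp, co, ex)
  expect_null(d$unfit_reason)
  dd <- d$data
  expect_setequal(unique(dd$moderator), c(0, 1))
  expect_equal(dd$peer_x_moderator[dd$moderator == 1],
               dd$peer_exposure[dd$moderator == 1])
  expect_true(all(dd$peer_x_moderator[dd$moderator == 0] == 0))
  # centered columns have mean zero on the estimation sample
  expect_equal(mean(dd$peer_exposure), 0, tolerance = 1e-12)
  expect_equal(mean(dd$baseline_outcome), 0, tolerance = 1e-12)
  # no missing data: all pupils retained
  expect_equal(d$n, nrow(co))
  # one missing moderator value drops exactly one row
  co2 <- co; co2$pro_sociality[5] <- NA
  sp2 <- model_spec("intentions", "class", 0L, "pro_sociality")
  d2 <- build_design(sp2, co2, ex)
  expect_equal(d2$n, nrow(co) - 1)
  # moderator-as-covariate deduplication
  expect_false("cov_gender_girl" %in%
                 names(build_design(model_spec("intentions", "class", 0L,
                                               "gender"), co, ex)$data))
  # continuous moderators are centered
  expect_equal(mean(build_design(sp2, co, ex)$data$moderator), 0,
               tolerance = 1e-12)
})

test_that("OLS + HC1 match the explicit matrix-algebra oracle", {
  set.seed(11)
  # fixed small bivariate dataset
  df <- random_moderation_data(6)
  fit <- ols_fit_hc(manual_design(df))
  o <- oracle_ols_hc1(as.matrix(df[, -1]), df$y)
  expect_equal(unname(fit$coefficients), o$coefficients, tolerance = 1e-10)
  expect_equal(unname(fit$se), o$se, tolerance = 1e-10)
  # property: random designs, n <= 50, k <= 6
  for (r in 1:200) {
    n <- sample(15:50, 1)
    k <- sample(2:6, 1)
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("x", 1:k)))
    colnames(X)[1:2] <- c("peer_exposure", "peer_x_moderator")
    y <- rnorm(n, X %*% runif(k, -1, 1), exp(rnorm(1)))
    d <- manual_design(data.frame(y = y, X, check.names = FALSE))
    fit <- ols_fit_hc(d)
    o <- oracle_ols_hc1(X, y)
    expect_equal(unname(fit$coefficients), o$coefficients, tolerance = 1e-8)
    expect_equal(unname(fit$se), o$se, tolerance = 1e-8)
    expect_true(all(fit$p_values >= 0 & fit$p_values <= 1))
    # robust covariance symmetric PSD
    expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
    expect_gte(min(eigen(fit$vcov, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
  }
})

test_that("exact linear data give zero robust SEs and R^2 = 1", {
  x <- seq(-2, 2, length.out = 20)
  df <- data.frame(y = 1 + 2 * x, peer_exposure = x)
  fit <- suppressWarnings(ols_fit_hc(manual_design(df)))
  expect_equal(unname(fit$se), c(0, 0), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
})

test_that("HC1 tracks the classical SE under homoskedasticity", {
  set.seed(12)
  rat <- replicate(400, {
    x <- rnorm(80)
    y <- 1 + 0.5 * x + rnorm(80)
    d <- manual_design(data.frame(y = y, peer_exposure = x))
    f <- ols_fit_hc(d)
    cls <- summary(lm(y ~ x))$coefficients["x", "Std. Error"]
    f$se["peer_exposure"] / cls
  })
  expect_equal(mean(rat), 1, tolerance = 0.03)
})

test_that("logistic fit reproduces the closed-form log odds ratio", {
  # collapsible 2x2: counts (x=0: 30/70 events, x=1: 60/40)
  x <- rep(c(0, 1), each = 100)
  y <- c(rep(1, 30), rep(0, 70), rep(1, 60), rep(0, 40))
  d <- manual_design(data.frame(y = y, peer_exposure = x))
  fit <- logit_fit_robust(d)
  lor <- log((60 / 40) / (30 / 70))
  expect_equal(unname(fit$coefficients["peer_exposure"]), lor,
               tolerance = 1e-6)
  # balanced outcome with zero predictors: intercept 0 by symmetry
  d0 <- manual_design(data.frame(y = rep(c(0, 1), 50),
                                 peer_exposure = rep(c(-1, 1), each = 50)))
  f0 <- logit_fit_robust(d0)
  expect_equal(unname(f0$coefficients["(Intercept)"]), 0, tolerance = 1e-8)
  # parameter recovery from a known logit DGP
  set.seed(4)
  n <- 5000
  xs <- rnorm(n)
  ys <- rbinom(n, 1, plogis(-0.3 + 0.8 * xs))
  fr <- logit_fit_robust(manual_design(data.frame(y = ys, peer_exposure = xs)))
  expect_equal(unname(fr$coefficients["peer_exposure"]), 0.8,
               tolerance = 0.15)
  # separation flagged as unfit, not reported
  sep <- manual_design(data.frame(y = rep(c(0, 1), each = 20),
                                  peer_exposure = c(rnorm(20, -3),
                                                    rnorm(20, 3))))
  expect_false(is.null(logit_fit_robust(sep)$unfit_reason))
  one <- manual_design(data.frame(y = rep(1, 30), peer_exposure = rnorm(30)))
  expect_match(logit_fit_robust(one)$unfit_reason, "single outcome class")
})

test_that("VIFs follow the 1/(1 - R^2) closed form", {
  set.seed(5)
  # orthogonal predictors: all VIF 1
  # columns orthogonal to the constant and to each other: correlations 0
  X <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 3), 100, 3))))[, 2:4]
  colnames(X) <- paste0("x", 1:3)
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-8)
  # two correlated predictors: VIF = 1/(1-r^2)
  for (r in 1:20) {
    a <- rnorm(60); b <- 0.6 * a + rnorm(60)
    X2 <- cbind(p = a, q = b)
    rr <- cor(a, b)
    expect_equal(unname(vif(X2)), rep(1 / (1 - rr^2), 2), tolerance = 1e-8)
  }
  # duplicated column: infinite with a warning
  expect_warning(v <- vif(cbind(a = a, b = a)), "RANK_DEFICIENT")
  expect_true(all(is.infinite(v)))
})

test_that("standardized interaction and delta R^2 follow their identities", {
  expect_equal(standardized_interaction(0.4, 2, 2), 0.4)
  expect_equal(standardized_interaction(0.4, 1, 2), 0.2)
  expect_true(is.na(standardized_interaction(0.4, 1, 0)))
  set.seed(6)
  df <- random_moderation_data(200, b3 = 0.3)
  d <- manual_design(df)
  fit <- ols_fit_hc(d)
  expect_equal(fit$beta_std,
               fit$b_interaction * sd(df$peer_exposure) / sd(df$y),
               tolerance = 1e-12)
  # delta R^2 equals the squared semipartial correlation of the
  # orthogonalised product column: sr^2 = R^2(full) - R^2(reduced)
  res_prod <- resid(lm(peer_x_moderator ~ peer_exposure + moderator, df))
  dr2 <- interaction_delta_r2(d)
  expect_equal(dr2, cor(df$y, res_prod)^2, tolerance = 1e-10)
  expect_gte(dr2, 0)
  # under a true null interaction, delta R^2 is near zero at large n
  dfn <- random_moderation_data(20000, b3 = 0)
  expect_lt(interaction_delta_r2(manual_design(dfn)), 0.002)
})

test_that("interaction p-value is invariant to affine moderator rescaling", {
  set.seed(8)
  for (r in 1:20) {
    x <- rnorm(60); w <- rnorm(60)
    y <- 0.2 + 0.4 * x + 0.1 * w + 0.3 * x * w + rnorm(60)
    d1 <- manual_design(data.frame(y = y, peer_exposure = x, moderator = w,
                                   peer_x_moderator = x * w))
    w2 <- 3 * w + 5
    w2c <- w2 - mean(w2)
    xc <- x - mean(x)
    # rebuild exactly as build_design would: center, then product
    d2 <- manual_design(data.frame(y = y, peer_exposure = xc,
                                   moderator = w2c,
                                   peer_x_moderator = xc * w2c))
    d1c <- manual_design(data.frame(y = y, peer_exposure = xc,
                                    moderator = w - mean(w),
                                    peer_x_moderator = xc * (w - mean(w))))
    f1 <- ols_fit_hc(d1c); f2 <- ols_fit_hc(d2)
    expect_equal(f1$p_interaction, f2$p_interaction, tolerance = 1e-9)
  }
})

test_that("model grid cardinalities match the study arithmetic", {
  outcomes <- default_outcome_specs()$name
  expect_length(outcomes, 46)
  expect_length(grid_specs("setting", outcomes), 276)
  expect_length(grid_specs("setting", outcomes, peer_groups = "friends"), 92)
  se_mods <- paste0("self_efficacy_", c("emotional", "friends", "opportunity"))
  per <- vapply(se_mods, function(m) length(grid_specs(m, outcomes)),
                integer(1))
  expect_equal(unname(per), rep(258L, 3))
  expect_equal(sum(per), 774L)
  expect_error(model_spec("p2s2", "friends", 0, "p2s2"), "differ")
  expect_error(grid_specs("nope", outcomes), "unknown moderator")
})

test_that("grid fitting collects per-model failures without aborting", {
  cfg <- small_cohort_config(seed = 41)
  gen <- generate_cohort(cfg)
  co <- attach_network_moderators(gen$cohort, gen$nominations)
  ex <- build_exposure_table(co, gen$nominations, c("p2s2", "susceptibility"))
  g <- run_model_grid("eigenvector", co, ex, c("p2s2", "susceptibility"))
  expect_s3_class(g, "model_grid")
  expect_equal(nrow(g$results), 12)
  expect_true(all(g$results$n[!g$results$unfit] > 0))
  expect_true(all(g$results$p_interaction[!g$results$unfit] >= 0))
})
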