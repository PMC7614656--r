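make_incomplete_trial <- function(n = 2000, mechanism = "MCAR", seed = 51) {
  p <- case_params("I", "simple")
  d <- simulate_trial(n, p$treatment, p$control, "simple", seed = seed)
  apply_missingness(d, mechanism_preset(mechanism), seed = seed + 1L)
}

test_that("Rubin pooling matches hand arithmetic", {
  pooled <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(pooled$estimate, 2)
  expect_equal(pooled$within, 1)
  expect_equal(pooled$between, 2)
  expect_equal(pooled$total, 1 + (1 + 1 / 2) * 2)
  expect_equal(pooled$df, (2 - 1) * (1 + 1 / ((1 + 1 / 2) * 2))^2)
  expect_true(pooled$ci[1] < pooled$estimate & pooled$estimate < pooled$ci[2])

  # identical estimates: no between-imputation variance, Wald interval
  same <- pool_rubin(rep(0.4, 5L), rep(0.09, 5L))
  expect_equal(same$between, 0)
  expect_equal(same$total, 0.09)
  expect_identical(same$df, Inf)
  expect_equal(same$ci, 0.4 + c(-1, 1) * qnorm(0.975) * 0.3)

  expect_error(pool_rubin(1, 1), "M >= 2")
  expect_error(pool_rubin(c(1, 2), c(1, -1)), "positive")
  # total variance never below the within component
  set.seed(52)
  for (i in 1:20) {
    est <- rnorm(10)
    v <- rexp(10) + 0.1
    p <- pool_rubin(est, v)
    expect_gte(p$total, p$within)
  }
})

test_that("internal logistic fit agrees with glm", {
  set.seed(53)
  n <- 500
  d <- data.frame(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.3))
  d$y <- rbinom(n, 1, plogis(-0.3 + 0.8 * d$a - 0.5 * d$b))
  fit <- compositemi:::logit_fit(cbind(1, d$a, d$b), d$y)
  ref <- glm(y ~ a + b, binomial, data = d,
             control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$vcov), unname(vcov(ref)), tolerance = 1e-6)
  expect_false(fit$separated)
})

test_that("augmentation resolves separation and vanishes in the limit", {
  set.seed(54)
  n <- 300
  d <- data.frame(a = rbinom(n, 1, 0.5))
  d$y <- rbinom(n, 1, plogis(0.2 + 0.5 * d$a))
  tiny <- augment_fit(d, "y", "a", weight = 1e-6)
  ref <- glm(y ~ a, binomial, data = d,
             control = glm.control(epsilon = 1e-12))
  expect_equal(unname(tiny$coefficients), unname(coef(ref)),
               tolerance = 1e-4)

  # perfectly separated: outcome equals predictor
  sep <- data.frame(a = rep(0:1, each = 20L))
  sep$y <- sep$a
  fit <- augment_fit(sep, "y", "a")
  expect_true(all(is.finite(fit$coefficients)))
  pr <- compositemi:::predict_prob(fit, cbind(1, 0:1))
  expect_true(all(pr > 0 & pr < 1))

  # a grid of separated configurations stays strictly inside (0, 1)
  for (k in c(5L, 25L, 100L)) {
    sep <- data.frame(a = rep(0:1, each = k))
    sep$y <- sep$a
    fit <- augment_fit(sep, "y", "a")
    pr <- compositemi:::predict_prob(fit, cbind(1, 0:1))
    expect_true(all(pr > 0 & pr < 1))
  }

  # without augmentation the univariate imputer refuses separated fits
  sep2 <- data.frame(x = rep(0:1, each = 20L),
                     y = c(rep(0L, 20L), rep(NA_integer_, 10L),
                           rep(1L, 10L)))
  sep2$y[sep2$x == 1 & !is.na(sep2$y)] <- 1L
  expect_error(impute_logistic_univariate(sep2, "y", "x"),
               "perfect prediction")
  expect_silent(impute_logistic_univariate(sep2, "y", "x", augment = TRUE))
})

test_that("univariate logistic imputation is proper and calibrated", {
  d0 <- data.frame(x = rep(0:1, 50L), y = rep(0:1, each = 50L))
  expect_identical(impute_logistic_univariate(d0, "y", "x"), d0)

  # outcome independent of predictor: imputed rate tracks the observed rate
  set.seed(55)
  n <- 2e4
  d <- data.frame(x = rbinom(n, 1, 0.5), y = rbinom(n, 1, 0.35))
  d$y[seq_len(n / 2)] <- NA_integer_
  obs_rate <- mean(d$y, na.rm = TRUE)
  done <- impute_logistic_univariate(d, "y", "x")
  imp_rate <- mean(done$y[seq_len(n / 2)])
  expect_lt(abs(imp_rate - obs_rate), 4 * sqrt(0.35 * 0.65 / (n / 2)))

  # distinct draws across repeated imputations (properness)
  reps <- replicate(8L, {
    set.seed(sample.int(1e6, 1))
    mean(impute_logistic_univariate(d, "y", "x")$y[seq_len(n / 2)])
  })
  expect_gt(var(reps), 0)
})

test_that("composite-level MI treats the right rows as missing", {
  m <- make_incomplete_trial(800)
  def <- composite_simple()
  der <- derive_endpoint(m, def)

  set.seed(56)
  cra_copies <- impute_composite(m, def, "mi_cra", M = 3)
  deriv_copies <- impute_composite(m, def, "mi_deriv", M = 3)
  complete_comp <- !is.na(m$z2) & !is.na(m$z3)
  for (d in cra_copies) {
    expect_false(anyNA(d$y))
    # observed (complete-component) rows keep their true composite
    expect_equal(d$y[complete_comp], der$y_deriv[complete_comp])
  }
  for (d in deriv_copies) {
    expect_false(anyNA(d$y))
    # every derivable row keeps its derived value
    keep <- der$r_y_deriv == 1L
    expect_equal(d$y[keep], der$y_deriv[keep])
  }
  # mi_cra imputes strictly more rows than mi_deriv
  expect_gt(sum(!complete_comp), sum(der$r_y_deriv == 0L))

  # fully observed data: all copies identical to the input
  p <- case_params("I", "simple")
  full <- simulate_trial(300, p$treatment, p$control, "simple", seed = 57)
  copies <- impute_composite(full, def, "mi_cra", M = 2, seed = 58)
  expect_identical(copies[[1L]]$y, full$y)
  expect_identical(copies[[2L]]$y, full$y)
})

test_that("chained-equations MI is passive, proper and reproducible", {
  m <- make_incomplete_trial(1200, "MAR1")
  def <- composite_simple()
  completed <- impute_components_mice(m, def, "mic_x", M = 3, burnin = 5,
                                      seed = 59)
  for (d in completed) {
    expect_false(anyNA(d$z2))
    expect_false(anyNA(d$z3))
    # observed values never overwritten
    keep2 <- !is.na(m$z2)
    expect_identical(d$z2[keep2], m$z2[keep2])
    # composite passivity: y recomputed from components, exactly
    expect_identical(d$y, evaluate_composite(def, d))
  }
  # properness: imputed columns differ across imputations
  miss2 <- which(is.na(m$z2))
  expect_false(identical(completed[[1L]]$z2[miss2],
                         completed[[2L]]$z2[miss2]))
  # seed reproducibility
  again <- impute_components_mice(m, def, "mic_x", M = 3, burnin = 5,
                                  seed = 59)
  expect_identical(completed, again)
})

test_that("stratified fitting equals the explicit interaction model", {
  # MIC-x fits per arm; the equivalent single model carries x interactions.
  set.seed(60)
  n <- 4000
  d <- data.frame(x = rbinom(n, 1, 0.5), z1 = rbinom(n, 1, 0.5),
                  z3 = rbinom(n, 1, 0.4))
  d$z2 <- rbinom(n, 1, plogis(-0.4 + 0.9 * d$z1 + 0.5 * d$z3 - 0.7 * d$x +
                                0.8 * d$z1 * d$x))
  probs_strat <- numeric(n)
  for (arm in 0:1) {
    idx <- d$x == arm
    fit <- compositemi:::logit_fit(cbind(1, d$z1, d$z3)[idx, ], d$z2[idx])
    probs_strat[idx] <- compositemi:::predict_prob(
      fit, cbind(1, d$z1, d$z3)[idx, ])
  }
  X <- cbind(1, d$z1, d$z3, d$x, d$z1 * d$x, d$z3 * d$x)
  fit_int <- compositemi:::logit_fit(X, d$z2)
  probs_int <- compositemi:::predict_prob(fit_int, X)
  expect_equal(probs_strat, probs_int, tolerance = 1e-10)
})

test_that("degenerate chained-equation configurations raise typed errors", {
  d <- data.frame(x = rep(0:1, each = 10L), z1 = rep(0:1, 10L),
                  z2 = NA_integer_, z3 = rep(0:1, 10L))
  expect_error(
    impute_chained(d, list(z2 = list(predictors = "z3", strata = "x")),
                   M = 2),
    "no observed values")
  # a stratum whose rows are all missing cannot support a conditional model
  d$z2 <- ifelse(d$x == 1L, rep(0:1, 5L), NA_integer_)
  expect_error(
    impute_chained(d, list(z2 = list(predictors = "z3", strata = "x")),
                   M = 2),
    "degenerate stratum")
  expect_error(
    impute_chained(d, list(z2 = list(predictors = "z2", strata = "x")),
                   M = 2),
    "own predictor")
})
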