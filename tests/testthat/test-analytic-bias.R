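test_that("joint constructor enforces probability invariants", {
  expect_s3_class(two_component_joint(0.25, 0.25, 0.25, 0.25),
                  "two_component_joint")
  expect_error(two_component_joint(-0.1, 0.5, 0.3, 0.3), "p00")
  expect_error(two_component_joint(0.2, 0.2, 0.2, 0.2), "sum to 1")
  j <- independent_joint(0.7)
  expect_equal(unclass(j),
               c(p00 = 0.09, p01 = 0.21, p10 = 0.21, p11 = 0.49))
})

test_that("derived-endpoint missingness probabilities match the closed form", {
  j <- two_component_joint(0.1, 0.2, 0.3, 0.4)
  expect_equal(unname(derived_missingness_probs(j, 1)), c(0, 1))
  u <- two_component_joint(0.25, 0.25, 0.25, 0.25)
  expect_equal(unname(derived_missingness_probs(u, 0)), c(0.5, 0.5))
  expect_equal(unname(derived_missingness_probs(j, 0.3)), c(0.21, 0.79))
  pr <- derived_missingness_probs(j, 0.3)
  expect_equal(sum(pr), 1)
})

test_that("outcome distribution by derivability matches enumeration", {
  j <- two_component_joint(0.1, 0.2, 0.3, 0.4)
  oracle <- enum_two_component(j, 0.3)
  got <- outcome_dist_by_derivability(j, 0.3)
  expect_equal(unname(got[1L]), oracle$py1_nonderiv, tolerance = 1e-12)
  expect_equal(unname(got[2L]), oracle$py1_deriv, tolerance = 1e-12)

  # no events among the non-derivable when p01 = 0
  j0 <- two_component_joint(0.3, 0, 0.3, 0.4)
  expect_equal(unname(outcome_dist_by_derivability(j0, 0.5)[1L]), 0)

  # full-observation limit recovers the marginal event probability
  expect_equal(unname(outcome_dist_by_derivability(j, 1 - 1e-12)[2L]),
               0.9, tolerance = 1e-9)
  # conditioning event of probability zero is a distinguished error
  expect_error(outcome_dist_by_derivability(j, 1), "undefined")
})

test_that("full-data odds ratio matches direct arithmetic and symmetry", {
  trt <- independent_joint(0.2)
  ctrl <- independent_joint(0.7)
  expect_equal(odds_ratio_full(trt, ctrl),
               (0.36 / 0.64) / (0.91 / 0.09), tolerance = 1e-12)
  expect_equal(odds_ratio_full(trt, trt), 1)
  expect_equal(odds_ratio_full(ctrl, trt), 1 / odds_ratio_full(trt, ctrl),
               tolerance = 1e-12)
  degenerate <- two_component_joint(0, 0.2, 0.3, 0.5)
  expect_error(odds_ratio_full(degenerate, ctrl), "degenerate")
})

test_that("derived-endpoint odds ratio agrees with the enumeration oracle", {
  trt <- independent_joint(0.2)
  ctrl <- independent_joint(0.7)
  expect_equal(odds_ratio_derived(trt, ctrl, 1),
               odds_ratio_full(trt, ctrl), tolerance = 1e-12)
  expect_equal(odds_ratio_derived(trt, trt, 0.4), 1, tolerance = 1e-12)
  for (alpha in c(0.1, 0.3, 0.8)) {
    expect_equal(odds_ratio_derived(trt, ctrl, alpha),
                 enum_or_deriv(trt, ctrl, alpha), tolerance = 1e-12)
  }
})

test_that("all closed forms match exhaustive enumeration on random joints", {
  set.seed(421)
  for (i in 1:200) {
    j <- random_joint()
    alpha <- stats::runif(1, 0.05, 0.95)
    oracle <- enum_two_component(j, alpha)
    expect_equal(unname(derived_missingness_probs(j, alpha)[1L]),
                 oracle$p_miss, tolerance = 1e-12)
    got <- outcome_dist_by_derivability(j, alpha)
    expect_equal(unname(got[1L]), oracle$py1_nonderiv, tolerance = 1e-12)
    expect_equal(unname(got[2L]), oracle$py1_deriv, tolerance = 1e-12)
    expect_equal(cra_outcome_dist(j, alpha), oracle$py1_complete,
                 tolerance = 1e-12)
  }
})

test_that("bias decomposition is internally consistent and bounded", {
  set.seed(99)
  for (i in 1:1000) {
    trt <- random_joint()
    ctrl <- random_joint()
    alpha <- stats::runif(1, 0.02, 0.98)
    b <- bias_ratio(trt, ctrl, alpha)
    expect_equal(b$ratio, b$or_deriv / b$or_full, tolerance = 1e-10)
    # analytic sigma/tau form of the ratio
    expect_equal(b$ratio,
                 (1 - (1 - alpha) * b$sigma) / (1 - (1 - alpha) * b$tau),
                 tolerance = 1e-10)
    expect_true(b$ratio >= alpha - 1e-12 && b$ratio <= 1 / alpha + 1e-12)
    expect_true(b$sigma >= 0 && b$sigma <= 1 && b$tau >= 0 && b$tau <= 1)
  }
})

test_that("no treatment effect on components means no derived-endpoint bias", {
  j <- random_joint()
  expect_equal(bias_ratio(j, j, 0.25)$ratio, 1, tolerance = 1e-12)
})

test_that("the worked two-component example reproduces the printed figures", {
  # independent components at 0.7 and 0.2; 70% of z2 missing
  frac07 <- event_fraction(independent_joint(0.7))
  frac02 <- event_fraction(independent_joint(0.2))
  expect_equal(round(frac07, 2), 0.23)
  expect_equal(round(frac02, 2), 0.44)
  b <- bias_ratio(independent_joint(0.7), independent_joint(0.2), 0.3)
  expect_equal(round(100 * (b$ratio - 1)), 22)
})

test_that("derived endpoint is MNAR under MCAR component missingness", {
  # strict inequality of the outcome distribution across derivability strata
  for (p in c(0.7, 0.2)) {
    d <- outcome_dist_by_derivability(independent_joint(p), 0.3)
    expect_true(abs(d[["non_derivable"]] - d[["derivable"]]) > 1e-6)
  }
})

test_that("complete-record outcome distribution is invariant to the MCAR rate", {
  j <- two_component_joint(0.15, 0.25, 0.35, 0.25)
  expect_identical(cra_outcome_dist(j, 0.1), cra_outcome_dist(j, 0.9))
  expect_equal(cra_outcome_dist(j, 0.5), 0.85)
  all_null <- two_component_joint(1, 0, 0, 0)
  expect_equal(cra_outcome_dist(all_null, 0.5), 0)
  expect_error(cra_outcome_dist(j, 0), "strictly positive")
})

test_that("bias surface tabulates the decomposition over alpha", {
  surf <- bias_surface(independent_joint(0.7), independent_joint(0.2),
                       c(0.3, 0.6, 0.9))
  expect_equal(nrow(surf), 3L)
  expect_named(surf, c("alpha", "sigma", "tau", "or_full", "or_deriv",
                       "ratio"))
  expect_equal(surf$ratio[surf$alpha == 0.3],
               bias_ratio(independent_joint(0.7), independent_joint(0.2),
                          0.3)$ratio)
  # less missingness, less bias
  expect_true(all(diff(surf$ratio) < 0))
})
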