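daily_row <- function(days, x = 0L) {
  stopifnot(length(days) == 30L)
  d <- data.frame(x = x)
  d[compositemi:::day_cols()] <- as.list(as.integer(days))
  d
}

test_that("block completeness rules follow the two approaches", {
  # block 1 days: (0, 0, 1, NA, 0) -- one missing day, an observed event
  days <- c(0, 0, 1, NA, 0, rep(0, 25))
  b1 <- make_blocks(daily_row(days), block_spec(approach = 1))
  b2 <- make_blocks(daily_row(days), block_spec(approach = 2))
  expect_true(is.na(b1$b1))
  expect_equal(b2$b1, 1L)

  # three missing days push approach 2 to missing as well
  days3 <- c(0, 0, NA, NA, NA, rep(0, 25))
  expect_true(is.na(make_blocks(daily_row(days3), block_spec(2))$b1))
  expect_equal(make_blocks(daily_row(days3), block_spec(2))$b2, 0L)

  # two missing days, no observed event: approach 2 derives a 0
  days2 <- c(0, 0, 0, NA, NA, rep(1, 25))
  expect_equal(make_blocks(daily_row(days2), block_spec(2))$b1, 0L)

  # fully observed: approaches agree
  full <- daily_row(rep(c(0, 1), 15))
  expect_identical(make_blocks(full, block_spec(1)),
                   make_blocks(full, block_spec(2)))
  expect_equal(unlist(make_blocks(full, block_spec(1))[paste0("b", 1:6)],
                      use.names = FALSE),
               rep(1L, 6L))
})

test_that("the synthetic cohort generator hits its calibration targets", {
  # no missingness requested: fully observed cohort
  clean <- synthesize_topps_like(n = 200, profile = list(complete = 1,
                                                         all_missing = 0),
                                 seed = 71)
  expect_false(anyNA(clean[compositemi:::day_cols()]))

  big <- synthesize_topps_like(n = 2e4, seed = 72)
  days <- as.matrix(big[compositemi:::day_cols()])
  # arm event rates (any event in 30 days) near the configured targets;
  # use complete rows to avoid conditioning on the missingness pattern
  complete <- rowSums(is.na(days)) == 0L
  for (arm in 0:1) {
    target <- if (arm == 1L) 0.50 else 0.43
    idx <- complete & big$x == arm
    phat <- mean(apply(days[idx, ], 1L, max))
    expect_lt(abs(phat - target), 4 * sqrt(target * (1 - target) / sum(idx)))
  }
  # fraction of participants with all six blocks complete under approach 1
  blocks <- make_blocks(big, block_spec(1))
  frac_complete <- mean(stats::complete.cases(blocks[paste0("b", 1:6)]))
  expect_lt(abs(frac_complete - 0.77), 4 * sqrt(0.77 * 0.23 / nrow(big)))

  expect_identical(synthesize_topps_like(n = 100, seed = 73),
                   synthesize_topps_like(n = 100, seed = 73))
  expect_error(synthesize_topps_like(profile = list(complete = 0.9,
                                                    all_missing = 0.2)),
               "at most 1")
})

test_that("fully complete blocks make all handling methods agree", {
  daily <- synthesize_topps_like(n = 400,
                                 profile = list(complete = 1,
                                                all_missing = 0),
                                 seed = 74)
  blocks <- make_blocks(daily, block_spec(1))
  ref <- analyze_blocks(blocks, "cra", M = 2, burnin = 1, seed = 75)
  for (m in c("deriv", "mi_cra", "mi_deriv", "mic_main", "mic_trt_all",
              "mic_trt_adjacent")) {
    res <- analyze_blocks(blocks, m, M = 2, burnin = 1, seed = 75)
    expect_equal(res$estimate, ref$estimate, tolerance = 1e-10)
    expect_equal(res$n_analyzed, ref$n_analyzed)
  }
})

test_that("the derived-endpoint inclusion rule matches its definition", {
  # constructed participants: fully complete rows in both arms; one with an
  # incomplete block but an observed bleed elsewhere (derivable y = 1); one
  # with an incomplete block and no observed bleed (non-derivable)
  rows <- rbind(
    daily_row(rep(0, 30), x = 0L),
    daily_row(rep(1, 30), x = 0L),
    daily_row(rep(0, 30), x = 1L),
    daily_row(rep(1, 30), x = 1L),
    daily_row(c(rep(NA, 5), rep(1, 5), rep(0, 20)), x = 1L),
    daily_row(c(rep(NA, 5), rep(0, 25)), x = 1L))
  blocks <- make_blocks(rows, block_spec(1))
  cra <- analyze_blocks(blocks, "cra")
  der <- analyze_blocks(blocks, "deriv")
  expect_equal(cra$n_analyzed, 4L)
  expect_equal(der$n_analyzed, 5L)
})

test_that("analysis sets nest across approaches and methods", {
  daily <- synthesize_topps_like(n = 600, seed = 76)
  sets <- list()
  for (a in 1:2) {
    blocks <- make_blocks(daily, block_spec(a))
    bl <- blocks[paste0("b", 1:6)]
    cra_set <- which(stats::complete.cases(bl))
    der <- derive_endpoint(blocks, composite_simple(paste0("b", 1:6)))
    deriv_set <- which(der$r_y_deriv == 1L)
    expect_true(all(cra_set %in% deriv_set))
    sets[[a]] <- list(cra = cra_set, deriv = deriv_set)
  }
  # the weaker completeness rule of approach 2 only adds participants
  expect_true(all(sets[[1]]$cra %in% sets[[2]]$cra))
  expect_true(all(sets[[1]]$deriv %in% sets[[2]]$deriv))
})

test_that("adjacent-block conditioning uses neighbours, two at the ends", {
  models <- compositemi:::block_chain_models("mic_trt_adjacent")
  expect_equal(models$b1$predictors, c("b2", "b3"))
  expect_equal(models$b3$predictors, c("b2", "b4"))
  expect_equal(models$b6$predictors, c("b5", "b4"))
  expect_equal(models$b4$strata, "x")
  # full conditioning uses the other five blocks
  all_m <- compositemi:::block_chain_models("mic_trt_all")
  expect_equal(sort(all_m$b2$predictors), paste0("b", c(1, 3:6)))
})

test_that("block-level imputation pools a finite risk difference", {
  daily <- synthesize_topps_like(n = 500, seed = 77)
  blocks <- make_blocks(daily, block_spec(1))
  res <- analyze_blocks(blocks, "mic_trt_adjacent", M = 4, burnin = 5,
                        seed = 78)
  expect_true(is.finite(res$estimate))
  expect_true(res$se > 0)
  expect_equal(res$n_analyzed, 500L)
  expect_equal(res$conf_level, 0.90)
})
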