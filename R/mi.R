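# Internal logistic fitting machinery used by all imputation routines.
# Predictors are plain numeric columns (binary components / treatment), so
# design matrices are built directly rather than through model.matrix; this
# keeps the chained-equations inner loop cheap.

design_matrix <- function(data, predictors) {
  X <- cbind(`(Intercept)` = rep(1, nrow(data)))
  if (length(predictors)) {
    X <- cbind(X, as.matrix(data[predictors]))
  }
  X
}

# Maximum-likelihood logistic fit with prior weights. The workhorse is a
# lean Newton/IRLS iteration (the chained-equations inner loop calls this
# thousands of times); rank-deficient designs are reduced to a full-rank
# column subset (aliased coefficients dropped) before iterating.
logit_fit <- function(X, y, w = NULL, augment = FALSE, weight = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  if (length(y) == 0L) stop("empty fitting set", call. = FALSE)
  if (augment) {
    aug <- augment_rows(X, w, weight)
    X <- rbind(X, aug$X)
    y <- c(y, aug$y)
    w <- c(w, aug$w)
  }
  keep <- seq_len(ncol(X))
  fit <- irls_logit(X, y, w)
  if (is.null(fit)) { # singular information: drop aliased columns and retry
    qrX <- qr(X)
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    fit <- irls_logit(X[, keep, drop = FALSE], y, w)
    if (is.null(fit)) {
      stop("logistic fit failed: design collinear beyond repair",
           call. = FALSE)
    }
  }
  separated <- !fit$converged || any(!is.finite(fit$coefficients)) ||
    max(abs(fit$coefficients)) > 12
  structure(list(coefficients = fit$coefficients, vcov = fit$vcov,
                 keep = keep, ncol_full = ncol(X),
                 converged = fit$converged, separated = separated,
                 augmented = augment, n_fit = length(y)),
            class = "cm_logit")
}

irls_logit <- function(X, y, w, max_iter = 30L, tol = 1e-10) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  R <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wt <- w * mu * (1 - mu)
    info <- crossprod(X, X * wt)
    R <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    score <- crossprod(X, w * (y - mu))
    delta <- backsolve(R, backsolve(R, score, transpose = TRUE))
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
    if (max(abs(beta)) > 50) break # diverging: separation
  }
  names(beta) <- colnames(X)
  list(coefficients = beta, vcov = chol2inv(R), converged = converged)
}

# Pseudo-observations that rule out separation: every distinct covariate
# pattern in the fitting set is paired with both outcomes at a small weight.
# Total added weight defaults to 1% of the fitting weight.
augment_rows <- function(X, w, weight = NULL) {
  pat <- if (all(X == 0 | X == 1)) {
    # binary designs: exact integer pattern encoding beats unique.matrix
    code <- drop(X %*% 2^(seq_len(ncol(X)) - 1L))
    X[!duplicated(code), , drop = FALSE]
  } else {
    unique(X)
  }
  if (is.null(weight)) weight <- 0.01 * sum(w) / (2 * nrow(pat))
  if (!is.numeric(weight) || weight <= 0) {
    stop("augmentation weight must be positive", call. = FALSE)
  }
  list(X = rbind(pat, pat),
       y = rep(c(0, 1), each = nrow(pat)),
       w = rep(weight, 2L * nrow(pat)))
}

predict_prob <- function(fit, Xnew) {
  stats::plogis(drop(Xnew[, fit$keep, drop = FALSE] %*% fit$coefficients))
}

# One draw from the asymptotic normal approximation at the MLE; the source of
# parameter uncertainty that makes the imputation proper.
draw_coefs <- function(fit) {
  if (is.null(fit$vcov)) {
    stop("cannot draw imputation parameters: singular information matrix",
         call. = FALSE)
  }
  drop(MASS::mvrnorm(1L, fit$coefficients, fit$vcov))
}

predict_prob_at <- function(fit, Xnew, beta) {
  stats::plogis(drop(Xnew[, fit$keep, drop = FALSE] %*% beta))
}

#' Weighted pseudo-observation augmentation for logistic regression
#'
#' Fits a logistic regression of `outcome` on main effects of `predictors`,
#' augmenting the fitting set so that the maximum-likelihood estimate is
#' always finite: for every distinct covariate pattern present in the data, a
#' pair of pseudo-observations with outcomes 0 and 1 is added at a small
#' weight (by default the total added weight is 1% of the fitting set). As
#' the weight tends to zero on non-separated data the coefficients converge
#' to the unaugmented MLE; on separated data the fit remains finite with all
#' predicted probabilities strictly inside \eqn{(0, 1)}.
#'
#' @param data Data frame containing `outcome` and `predictors`, with the
#'   outcome observed on every row used for fitting.
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of predictor column names (main
#'   effects).
#' @param weight Pseudo-observation weight; `NULL` uses the 1% default.
#' @return A fitted-model object with elements `coefficients` and `vcov`.
#' @export
augment_fit <- function(data, outcome, predictors, weight = NULL) {
  rows <- !is.na(data[[outcome]])
  X <- design_matrix(data[rows, , drop = FALSE], predictors)
  logit_fit(X, data[[outcome]][rows], augment = TRUE, weight = weight)
}

#' @export
coef.cm_logit <- function(object, ...) object$coefficients

#' Proper univariate logistic imputation
#'
#' Fits a logistic regression of `outcome` on `predictors` using the rows
#' where the outcome is observed, draws one coefficient vector from the
#' asymptotic normal approximation at the MLE, and imputes the missing
#' outcome rows by Bernoulli draws at the drawn coefficients. Propagating the
#' parameter draw is what makes repeated calls produce between-imputation
#' variability (proper imputation).
#'
#' @inheritParams augment_fit
#' @param augment If `TRUE`, fit with pseudo-observation augmentation
#'   (guarding against perfect prediction); if `FALSE`, separation raises an
#'   error.
#' @return `data` with the missing entries of `outcome` imputed.
#' @export
impute_logistic_univariate <- function(data, outcome, predictors,
                                       augment = FALSE, weight = NULL) {
  y <- data[[outcome]]
  target <- which(is.na(y))
  if (!length(target)) return(data)
  for (p in predictors) {
    if (anyNA(data[[p]])) {
      stop("predictor '", p, "' contains missing values", call. = FALSE)
    }
  }
  fit_rows <- which(!is.na(y))
  if (!length(fit_rows)) {
    stop("no observed '", outcome, "' values to fit the imputation model on",
         call. = FALSE)
  }
  X <- design_matrix(data, predictors)
  fit <- logit_fit(X[fit_rows, , drop = FALSE], y[fit_rows],
                   augment = augment, weight = weight)
  if (fit$separated && !augment) {
    stop("perfect prediction while imputing '", outcome,
         "'; refit with augment = TRUE", call. = FALSE)
  }
  beta <- draw_coefs(fit)
  pr <- predict_prob_at(fit, X[target, , drop = FALSE], beta)
  data[[outcome]][target] <- stats::rbinom(length(target), 1L, pr)
  data
}

#' Multiple imputation of the composite endpoint itself
#'
#' Univariate logistic MI of the composite `y` given treatment `x`, in one of
#' two modes differing in which rows are treated as missing:
#' \describe{
#'   \item{`mi_cra`}{`y` is treated as missing whenever *any* component is
#'     missing, regardless of derivability; the imputation model `y ~ x` is
#'     fitted on complete-component rows. Mirrors a complete-record analysis.}
#'   \item{`mi_deriv`}{`y` is first derived from observed components where
#'     possible; only non-derivable rows are imputed, with `y ~ x` fitted on
#'     the derivable rows. Inherits the derived endpoint's bias.}
#' }
#'
#' @param data Trial data frame with complete `x` and the component columns.
#' @param def A [composite_definition()].
#' @param mode `"mi_cra"` or `"mi_deriv"`.
#' @param M Number of imputations (at least 2).
#' @param seed Optional integer seed.
#' @param augment Passed to [impute_logistic_univariate()].
#' @return A list of `M` completed data frames, each with a complete `y`.
#' @export
impute_composite <- function(data, def, mode = c("mi_cra", "mi_deriv"),
                             M = 25, seed = NULL, augment = FALSE) {
  mode <- match.arg(mode)
  stopifnot(M >= 2)
  if (anyNA(data$x)) stop("treatment column must be complete", call. = FALSE)
  comps <- composite_components(def)
  y_all <- evaluate_composite(def, data)
  if (mode == "mi_cra") {
    complete_comp <- Reduce(`&`, lapply(comps, function(nm) !is.na(data[[nm]])))
    data$y <- ifelse(complete_comp, y_all, NA_integer_)
  } else {
    data$y <- y_all # three-valued: derivable rows filled, others NA
  }
  lapply(seq_len(M), function(m) {
    if (!is.null(seed)) set.seed(as.integer(seed) + 7919L * m)
    impute_logistic_univariate(data, "y", "x", augment = augment)
  })
}

# Normalize a chained-equations model specification.
check_chain_models <- function(data, models) {
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    stop("'models' must be a named list keyed by target column", call. = FALSE)
  }
  for (tgt in names(models)) {
    m <- models[[tgt]]
    if (is.null(data[[tgt]])) {
      stop("target column '", tgt, "' not found in data", call. = FALSE)
    }
    if (tgt %in% m$predictors) {
      stop("target '", tgt, "' cannot be its own predictor", call. = FALSE)
    }
    for (v in c(m$predictors, m$strata)) {
      if (is.null(data[[v]])) {
        stop("model for '", tgt, "' references missing column '", v, "'",
             call. = FALSE)
      }
    }
    for (v in m$strata) {
      if (anyNA(data[[v]])) {
        stop("stratification variable '", v, "' must be fully observed",
             call. = FALSE)
      }
    }
  }
  models
}

# Precompute, per target, the stratum structure of the chained equations:
# which rows each conditional model is fitted on and which rows it imputes.
# Row membership depends only on fully observed columns, so it is fixed
# across cycles and imputations.
chain_plan <- function(data, models) {
  lapply(names(models), function(t) {
    spec <- models[[t]]
    obs <- !is.na(data[[t]])
    strata_id <- if (length(spec$strata)) {
      interaction(data[spec$strata], drop = FALSE, lex.order = TRUE)
    } else {
      factor(rep(1L, nrow(data)))
    }
    strata <- lapply(levels(strata_id), function(lev) {
      in_s <- strata_id == lev
      tgt <- which(in_s & !obs)
      if (!length(tgt)) return(NULL)
      fit_idx <- which(in_s & obs)
      if (!length(fit_idx)) {
        stop("degenerate stratum '", lev, "' for target '", t,
             "': no observed rows to fit the conditional model on",
             call. = FALSE)
      }
      list(fit = fit_idx, tgt = tgt, level = lev)
    })
    list(target = t, predictors = spec$predictors, obs = obs,
         strata = Filter(Negate(is.null), strata))
  })
}

strat_X <- function(cols, idx) {
  X <- matrix(1, length(idx), length(cols) + 1L)
  for (j in seq_along(cols)) X[, j + 1L] <- cols[[j]][idx]
  X
}

# Fit the conditional model for one target (possibly stratified), draw
# parameters, and impute the target rows in place. `d` is a list of column
# vectors (mutated copy of the data).
impute_one_target <- function(d, plan, augment, weight) {
  y <- d[[plan$target]]
  cols <- d[plan$predictors]
  for (s in plan$strata) {
    fit <- logit_fit(strat_X(cols, s$fit), y[s$fit],
                     augment = augment, weight = weight)
    if (fit$separated && !augment) {
      stop("perfect prediction in stratum '", s$level, "' while imputing '",
           plan$target, "'; use augment = TRUE", call. = FALSE)
    }
    beta <- draw_coefs(fit)
    pr <- predict_prob_at(fit, strat_X(cols, s$tgt), beta)
    y[s$tgt] <- stats::rbinom(length(s$tgt), 1L, pr)
  }
  d[[plan$target]] <- y
  d
}

#' Chained-equations multiple imputation of binary columns
#'
#' Generic MICE engine for binary targets with logistic conditional models.
#' Each imputation chain starts from a random fill of the missing entries
#' (draws from each column's observed values), then cycles through the
#' targets in the given order for `burnin` iterations: the conditional model
#' for a target is fitted on the rows where that target was originally
#' observed (using current completed values of its predictors), a
#' coefficient vector is drawn from the normal approximation at the MLE, and
#' the originally missing rows are imputed by Bernoulli draws. The state
#' after the final cycle is the completed dataset.
#'
#' @param data Data frame with the target columns partially observed.
#' @param models Named list keyed by target column; each element is a list
#'   with character elements `predictors` (main effects) and `strata`
#'   (fully observed columns within whose level combinations the model is
#'   fitted separately — equivalent to interacting every predictor and the
#'   intercept with the strata).
#' @param M Number of imputations (at least 2).
#' @param burnin Number of cycles per imputation (at least 1).
#' @param seed Optional integer seed.
#' @param augment Use pseudo-observation augmentation in every conditional
#'   fit (recommended; without it perfect prediction raises an error).
#' @param weight Augmentation weight, see [augment_fit()].
#' @return A list of `M` completed data frames.
#' @export
impute_chained <- function(data, models, M = 25, burnin = 20, seed = NULL,
                           augment = TRUE, weight = NULL) {
  stopifnot(M >= 2, burnin >= 1)
  check_chain_models(data, models)
  targets <- names(models)
  for (t in targets) {
    if (all(is.na(data[[t]]))) {
      stop("target '", t, "' has no observed values", call. = FALSE)
    }
  }
  plans <- chain_plan(data, models)
  base <- as.list(data) # mutate plain column vectors in the hot loop
  lapply(seq_len(M), function(m) {
    if (!is.null(seed)) set.seed(as.integer(seed) + 104729L * m)
    d <- base
    for (p in plans) { # initial fill from the observed marginal
      nm <- sum(!p$obs)
      if (nm) {
        d[[p$target]][!p$obs] <- sample(d[[p$target]][p$obs], nm,
                                        replace = TRUE)
      }
    }
    for (cycle in seq_len(burnin)) {
      for (p in plans) {
        d <- impute_one_target(d, p, augment, weight)
      }
    }
    out <- data
    for (p in plans) out[[p$target]] <- d[[p$target]]
    out
  })
}

mic_models <- function(strategy, targets = c("z2", "z3"),
                       fully_observed = "z1", treatment = "x") {
  other <- function(t) setdiff(targets, t)
  specs <- switch(strategy,
    mic_main = lapply(targets, function(t) {
      list(predictors = c(treatment, fully_observed, other(t)),
           strata = character())
    }),
    mic_x = lapply(targets, function(t) {
      list(predictors = c(fully_observed, other(t)), strata = treatment)
    }),
    mic_x_z1 = lapply(targets, function(t) {
      list(predictors = other(t), strata = c(treatment, fully_observed))
    }),
    stop("unknown component-level strategy '", strategy, "'", call. = FALSE))
  names(specs) <- targets
  specs
}

#' Component-level multiple imputation with passive composite imputation
#'
#' Chained-equations MI of the incomplete components `z2` and `z3` with one
#' of three conditional-model structures, after which the composite `y` is
#' passively computed from the (observed and imputed) components in every
#' completed dataset:
#' \describe{
#'   \item{`mic_main`}{each component's conditional model has `x`, `z1` and
#'     the other incomplete component as main effects;}
#'   \item{`mic_x`}{`z1` and the other component as main effects, fitted
#'     separately within treatment arms (equivalently, all two-way
#'     interactions with `x`);}
#'   \item{`mic_x_z1`}{the other component as main effect, fitted separately
#'     within the four `(x, z1)` strata (the saturated specification, never
#'     mis-specified for this data structure).}
#' }
#'
#' @param data Trial data frame with complete `x`, `z1` and partially
#'   observed `z2`, `z3`.
#' @param def A [composite_definition()] used for the passive step.
#' @param strategy `"mic_main"`, `"mic_x"` or `"mic_x_z1"`.
#' @param M,burnin,seed,augment,weight Passed to [impute_chained()].
#' @return A list of `M` completed data frames, each with complete
#'   components and passively computed `y`.
#' @export
impute_components_mice <- function(data, def,
                                   strategy = c("mic_main", "mic_x",
                                                "mic_x_z1"),
                                   M = 25, burnin = 20, seed = NULL,
                                   augment = TRUE, weight = NULL) {
  strategy <- match.arg(strategy)
  for (col in c("x", "z1")) {
    if (anyNA(data[[col]])) {
      stop("column '", col, "' must be fully observed", call. = FALSE)
    }
  }
  models <- mic_models(strategy)
  completed <- impute_chained(data, models, M = M, burnin = burnin,
                              seed = seed, augment = augment, weight = weight)
  lapply(completed, function(d) {
    d$y <- evaluate_composite(def, d)
    d
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled point estimate is the mean of the per-imputation estimates; the
#' total variance combines the mean within-imputation variance \eqn{\bar W}
#' and the between-imputation variance \eqn{B} as
#' \eqn{T = \bar W + (1 + 1/M) B}, with large-sample degrees of freedom
#' \eqn{(M-1)\left(1 + \bar W / ((1+1/M)B)\right)^2} (infinite when
#' \eqn{B = 0}) and a t-based confidence interval.
#'
#' @param estimates Numeric vector of per-imputation point estimates
#'   (length `M >= 2`).
#' @param variances Numeric vector of per-imputation squared standard
#'   errors, all positive.
#' @param conf_level Confidence level for the pooled interval.
#' @return An object of class `pooled_estimate`: list with `estimate`,
#'   `within`, `between`, `total`, `se`, `df`, `ci`, `conf_level`, `m`.
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  M <- length(estimates)
  if (M < 2L || length(variances) != M) {
    stop("pooling requires M >= 2 estimates with matching variances",
         call. = FALSE)
  }
  if (any(!is.finite(estimates)) || any(!is.finite(variances)) ||
      any(variances <= 0)) {
    stop("estimates must be finite and variances strictly positive",
         call. = FALSE)
  }
  point <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  total <- W + (1 + 1 / M) * B
  df <- if (B == 0) Inf else (M - 1) * (1 + W / ((1 + 1 / M) * B))^2
  se <- sqrt(total)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  out <- list(estimate = point, within = W, between = B, total = total,
              se = se, df = df,
              ci = c(point - tcrit * se, point + tcrit * se),
              conf_level = conf_level, m = M)
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate (M = %d): %.4f (SE %.4f)\n",
              x$m, x$estimate, x$se))
  cat(sprintf("  within %.5f, between %.5f, total %.5f, df %.1f\n",
              x$within, x$between, x$total, x$df))
  cat(sprintf("  %g%% CI [%.4f, %.4f]\n", 100 * x$conf_level,
              x$ci[1], x$ci[2]))
  invisible(x)
}
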