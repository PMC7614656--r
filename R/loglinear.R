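#' Saturated log-linear parameters for three binary components
#'
#' Coefficients of a saturated log-linear model for the cell counts of the
#' eight combinations of three binary components \eqn{(z_1, z_2, z_3)}:
#' \deqn{\log \mu_c = \mu_0 + LP_c,\qquad
#'  LP_c = \lambda_1 z_1 + \lambda_2 z_2 + \lambda_3 z_3 + \lambda_{12} z_1 z_2
#'   + \lambda_{23} z_2 z_3 + \lambda_{13} z_1 z_3 + \lambda_{123} z_1 z_2 z_3.}
#' The two-way coefficients are the pairwise log odds ratios between two
#' components when the third is 0; \eqn{\lambda_{123}} is the three-way
#' interaction (how a pairwise association changes with the third component).
#' The intercept \eqn{\mu_0} only normalizes counts and is not needed for
#' probabilities.
#'
#' @param lambda1,lambda2,lambda3 Main-effect coefficients.
#' @param lambda12,lambda13,lambda23 Two-way interaction coefficients.
#' @param lambda123 Three-way interaction coefficient.
#' @return An object of class `loglinear_params` (named numeric vector).
#' @export
loglinear_params <- function(lambda1 = 0, lambda2 = 0, lambda3 = 0,
                             lambda12 = 0, lambda13 = 0, lambda23 = 0,
                             lambda123 = 0) {
  lam <- c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
           lambda12 = lambda12, lambda13 = lambda13, lambda23 = lambda23,
           lambda123 = lambda123)
  if (!is.numeric(lam) || any(!is.finite(lam))) {
    stop("all log-linear coefficients must be finite numerics", call. = FALSE)
  }
  structure(lam, class = "loglinear_params")
}

check_params <- function(params, arg = "params") {
  if (!inherits(params, "loglinear_params")) {
    stop("'", arg, "' must be a loglinear_params object", call. = FALSE)
  }
  params
}

# The canonical ordering of the 8 component combinations: c = 1 is (0,0,0),
# z1 = 1 iff c > 4, z2 = 1 iff c in {3,4,7,8}, z3 = 1 iff c in {2,4,6,8}.
combination_map <- function() {
  data.frame(
    c = 1:8,
    z1 = rep(0:1, each = 4L),
    z2 = rep(rep(0:1, each = 2L), 2L),
    z3 = rep(0:1, 4L)
  )
}

#' Linear predictor of the log-linear model for a component combination
#'
#' @param params A [loglinear_params()] object.
#' @param z1,z2,z3 Component values in \{0, 1\}; vectorized.
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(params, z1, z2, z3) {
  check_params(params)
  zs <- cbind(z1, z2, z3)
  if (!all(zs %in% c(0, 1))) {
    stop("component values must be 0 or 1", call. = FALSE)
  }
  params[["lambda1"]] * z1 + params[["lambda2"]] * z2 +
    params[["lambda3"]] * z3 +
    params[["lambda12"]] * z1 * z2 + params[["lambda23"]] * z2 * z3 +
    params[["lambda13"]] * z1 * z3 + params[["lambda123"]] * z1 * z2 * z3
}

#' Combination table implied by log-linear parameters
#'
#' Enumerates the eight combinations of \eqn{(z_1, z_2, z_3)} with the simple
#' (any component) and complex (\eqn{z_1} and at least one of \eqn{z_2, z_3})
#' composite values, the linear predictor and the normalized cell
#' probability \eqn{p_c = \exp(LP_c)/\sum_c \exp(LP_c)} (computed with
#' max-subtraction so finite coefficients never overflow).
#'
#' @param params A [loglinear_params()] object.
#' @return A data frame with columns `c`, `z1`, `z2`, `z3`, `y_simple`,
#'   `y_complex`, `lp`, `p`.
#' @export
combination_table <- function(params) {
  check_params(params)
  tab <- combination_map()
  tab$y_simple <- as.integer(tab$z1 | tab$z2 | tab$z3)
  tab$y_complex <- as.integer(tab$z1 & (tab$z2 | tab$z3))
  tab$lp <- linear_predictor(params, tab$z1, tab$z2, tab$z3)
  elp <- exp(tab$lp - max(tab$lp))
  tab$p <- elp / sum(elp)
  tab
}

#' Cell probabilities of the eight component combinations
#'
#' @param params A [loglinear_params()] object.
#' @return Numeric vector of length 8 summing to one.
#' @export
combination_probs <- function(params) {
  combination_table(params)$p
}

match_definition <- function(definition) {
  match.arg(definition, c("simple", "complex"))
}

#' Composite event probability implied by log-linear parameters
#'
#' The simple composite (1 iff any component is 1) has event probability
#' \eqn{\sum_{c=2}^{8} p_c}; the complex composite (1 iff \eqn{z_1 = 1} and
#' \eqn{z_2 = 1} or \eqn{z_3 = 1}) has \eqn{\sum_{c=6}^{8} p_c}.
#'
#' @param params A [loglinear_params()] object.
#' @param definition `"simple"` or `"complex"`.
#' @return A probability.
#' @export
composite_event_prob <- function(params, definition = c("simple", "complex")) {
  definition <- match_definition(definition)
  tab <- combination_table(params)
  y <- if (definition == "simple") tab$y_simple else tab$y_complex
  sum(tab$p[y == 1])
}

#' Calibrate exchangeable main effects to a target composite event rate
#'
#' With the interaction coefficients held fixed, finds the common main-effect
#' value \eqn{m = \lambda_1 = \lambda_2 = \lambda_3} such that the composite
#' event probability equals `target` (to `1e-10`), by bracketed root finding
#' on \eqn{m \in [-20, 20]}. The event probability is strictly increasing in
#' the common main effect, so the root is unique.
#'
#' @param target Target composite event probability, in \eqn{(0, 1)}.
#' @param lambda12,lambda13,lambda23,lambda123 Fixed interaction
#'   coefficients.
#' @param definition `"simple"` or `"complex"`.
#' @return A [loglinear_params()] object achieving the target rate.
#' @export
#' @examples
#' p <- calibrate_lambdas(plogis(0.3), definition = "simple")
#' composite_event_prob(p, "simple") # 0.574...
calibrate_lambdas <- function(target, lambda12 = 0, lambda13 = 0,
                              lambda23 = 0, lambda123 = 0,
                              definition = c("simple", "complex")) {
  definition <- match_definition(definition)
  if (!is.numeric(target) || length(target) != 1L || is.na(target) ||
      target <= 0 || target >= 1) {
    stop("'target' must be a probability strictly between 0 and 1",
         call. = FALSE)
  }
  make <- function(m) {
    loglinear_params(m, m, m, lambda12, lambda13, lambda23, lambda123)
  }
  f <- function(m) composite_event_prob(make(m), definition) - target
  lo <- f(-20); hi <- f(20)
  if (lo > 0 || hi < 0) {
    stop(sprintf(paste0("calibration failure: target %.4g outside achievable",
                        " range [%.4g, %.4g] for main effects in [-20, 20]"),
                 target, lo + target, hi + target), call. = FALSE)
  }
  root <- stats::uniroot(f, c(-20, 20), tol = 1e-12)$root
  make(root)
}

#' Per-arm log-linear parameters for the three interaction cases
#'
#' Builds the pair of arm-specific parameter sets used throughout the
#' simulation study. Arm event rates are fixed at
#' \eqn{\mathrm{expit}(\beta_0)} (control) and
#' \eqn{\mathrm{expit}(\beta_0 + \beta_x)} (treatment) by calibrating each
#' arm's common main effect, so the marginal logistic regression of the
#' composite on treatment has intercept `beta0` and slope `beta_x` exactly.
#' The cases differ in the three-way interaction:
#' \describe{
#'   \item{I}{\eqn{\lambda_{123} = 0} in both arms;}
#'   \item{II}{\eqn{\lambda_{123} = 0} (treatment), \eqn{\ne 0} (control);}
#'   \item{III}{\eqn{\lambda_{123} \ne 0} in both arms, different values.}
#' }
#' Two-way interactions default to 0.2 (treatment) and 1.0 (control): the
#' pairwise association between components differs by arm, which is what
#' makes the choice of conditional imputation model consequential.
#'
#' @param case `"I"`, `"II"` or `"III"`.
#' @param definition `"simple"` or `"complex"`.
#' @param beta0,beta_x Intercept and slope of the marginal logistic model of
#'   the composite on treatment (defaults 0.3 and 1.35, giving arm event
#'   rates 0.57 and 0.84).
#' @param two_way Length-2 numeric `c(treatment, control)` pairwise
#'   interaction values.
#' @param lambda123 Length-2 numeric `c(treatment, control)` three-way
#'   interaction values; defaults depend on `case` (I: 0/0; II: 0/0.5;
#'   III: 0.3/0.6).
#' @return A list with [loglinear_params()] elements `treatment` and
#'   `control`, plus attributes recording the case and targets.
#' @export
case_params <- function(case = c("I", "II", "III"),
                        definition = c("simple", "complex"),
                        beta0 = 0.3, beta_x = 1.35,
                        two_way = c(treatment = 0.2, control = 1.0),
                        lambda123 = NULL) {
  case <- match.arg(case)
  definition <- match_definition(definition)
  if (is.null(lambda123)) {
    lambda123 <- switch(case,
      I = c(treatment = 0, control = 0),
      II = c(treatment = 0, control = 0.5),
      III = c(treatment = 0.3, control = 0.6))
  }
  stopifnot(length(two_way) == 2L, length(lambda123) == 2L)
  arm <- function(target, tw, l123) {
    calibrate_lambdas(target, lambda12 = tw, lambda13 = tw, lambda23 = tw,
                      lambda123 = l123, definition = definition)
  }
  out <- list(
    treatment = arm(stats::plogis(beta0 + beta_x), two_way[[1]], lambda123[[1]]),
    control = arm(stats::plogis(beta0), two_way[[2]], lambda123[[2]])
  )
  attr(out, "case") <- case
  attr(out, "definition") <- definition
  attr(out, "beta0") <- beta0
  attr(out, "beta_x") <- beta_x
  out
}

#' Simulate a randomized trial with three correlated binary components
#'
#' Participants are assigned to treatment by independent Bernoulli(`p_x`)
#' draws (simple randomization, so arm sizes are random). Within each arm a
#' combination \eqn{c \in \{1..8\}} is drawn from that arm's log-linear cell
#' probabilities; components are read off the combination table and the
#' composite `y` is evaluated under `definition`.
#'
#' @param n Number of participants.
#' @param params_treatment,params_control Arm-specific [loglinear_params()].
#' @param definition `"simple"` or `"complex"`.
#' @param p_x Randomization probability of treatment (default 0.5).
#' @param seed Optional integer seed (sets the RNG state).
#' @return A data frame with columns `x`, `z1`, `z2`, `z3`, `y`.
#' @export
simulate_trial <- function(n, params_treatment, params_control,
                           definition = c("simple", "complex"),
                           p_x = 0.5, seed = NULL) {
  definition <- match_definition(definition)
  check_params(params_treatment, "params_treatment")
  check_params(params_control, "params_control")
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, p_x >= 0, p_x <= 1)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rbinom(n, 1L, p_x)
  cc <- integer(n)
  for (arm in 0:1) {
    idx <- which(x == arm)
    if (!length(idx)) next
    p <- combination_probs(if (arm == 1L) params_treatment else params_control)
    cc[idx] <- sample.int(8L, length(idx), replace = TRUE, prob = p)
  }
  tab <- combination_map()
  out <- data.frame(
    x = x,
    z1 = tab$z1[cc],
    z2 = tab$z2[cc],
    z3 = tab$z3[cc]
  )
  out$y <- if (definition == "simple") {
    as.integer(out$z1 | out$z2 | out$z3)
  } else {
    as.integer(out$z1 & (out$z2 | out$z3))
  }
  out
}
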