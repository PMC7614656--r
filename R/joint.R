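#' Joint distribution of two binary components
#'
#' Container for the four cell probabilities \eqn{p_{jk} = P(z_1 = j, z_2 = k)}
#' of two binary endpoint components. The simple composite built from the two
#' components is \eqn{y = 1} iff \eqn{z_1 = 1} or \eqn{z_2 = 1}, so
#' \eqn{P(y = 1) = p_{01} + p_{10} + p_{11}}.
#'
#' @param p00,p01,p10,p11 Cell probabilities; must be non-negative and sum to
#'   one (tolerance `1e-12`).
#' @return An object of class `two_component_joint` (a named numeric vector).
#' @seealso [independent_joint()] for the product-Bernoulli special case.
#' @export
#' @examples
#' two_component_joint(0.09, 0.21, 0.21, 0.49)
two_component_joint <- function(p00, p01, p10, p11) {
  p <- c(p00 = p00, p01 = p01, p10 = p10, p11 = p11)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]])) {
      stop("joint cell '", nm, "' must be a single numeric value", call. = FALSE)
    }
    if (p[[nm]] < 0) {
      stop("joint cell '", nm, "' is negative (", p[[nm]], ")", call. = FALSE)
    }
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("joint cell probabilities must sum to 1 (got ", sum(p), ")",
         call. = FALSE)
  }
  structure(p, class = "two_component_joint")
}

#' Joint distribution of two independent Bernoulli components
#'
#' @param prob1,prob2 Marginal success probabilities of \eqn{z_1} and
#'   \eqn{z_2}. `prob2` defaults to `prob1`.
#' @return A [two_component_joint()] with product cell probabilities.
#' @export
#' @examples
#' independent_joint(0.7) # the two-component worked example, control arm
independent_joint <- function(prob1, prob2 = prob1) {
  stopifnot(is.numeric(prob1), is.numeric(prob2),
            prob1 >= 0, prob1 <= 1, prob2 >= 0, prob2 <= 1)
  two_component_joint((1 - prob1) * (1 - prob2), (1 - prob1) * prob2,
                      prob1 * (1 - prob2), prob1 * prob2)
}

check_joint <- function(joint, arg = "joint") {
  if (!inherits(joint, "two_component_joint")) {
    stop("'", arg, "' must be a two_component_joint object", call. = FALSE)
  }
  joint
}

check_alpha <- function(alpha, open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("'alpha' must be a single probability in [0, 1]", call. = FALSE)
  }
  if (open_lower && alpha == 0) {
    stop("'alpha' must be strictly positive here", call. = FALSE)
  }
  if (open_upper && alpha == 1) {
    stop("'alpha' must be strictly below 1 here", call. = FALSE)
  }
  alpha
}

#' Missingness distribution of the derived composite endpoint
#'
#' With \eqn{z_1} fully observed and \eqn{z_2} missing completely at random
#' with observation probability `alpha`, the simple composite can be derived
#' whenever \eqn{z_2} is observed or \eqn{z_1 = 1}. This returns the
#' probabilities that the derived endpoint is missing and non-missing:
#' \deqn{P(r_{deriv} = 0) = (1-\alpha)(p_{00}+p_{01}), \quad
#'       P(r_{deriv} = 1) = \alpha + (1-\alpha)(p_{10}+p_{11}).}
#'
#' @param joint A [two_component_joint()].
#' @param alpha Probability that \eqn{z_2} is observed (MCAR).
#' @return Named numeric vector `c(missing = , derivable = )`, summing to one.
#' @export
derived_missingness_probs <- function(joint, alpha) {
  check_joint(joint)
  check_alpha(alpha)
  miss <- (1 - alpha) * (joint[["p00"]] + joint[["p01"]])
  c(missing = miss, derivable = 1 - miss)
}

#' Composite outcome distribution by derivability status
#'
#' Returns \eqn{P(y = 1 \mid r_{deriv} = 0)} and
#' \eqn{P(y = 1 \mid r_{deriv} = 1)} under MCAR missingness of \eqn{z_2}.
#' Inequality of the two demonstrates that the derived endpoint is missing
#' not at random even though the component is MCAR: the subset with a
#' non-derivable endpoint has outcome distribution
#' \eqn{p_{01}/(p_{00}+p_{01})}, which differs in general from the derivable
#' subset's \eqn{(\alpha p_{01}+p_{10}+p_{11})/(\alpha+(1-\alpha)(p_{10}+p_{11}))}.
#'
#' @inheritParams derived_missingness_probs
#' @return Named numeric vector `c(non_derivable = , derivable = )`.
#' @export
outcome_dist_by_derivability <- function(joint, alpha) {
  check_joint(joint)
  check_alpha(alpha)
  if (derived_missingness_probs(joint, alpha)[["missing"]] <= 0) {
    stop("P(y = 1 | non-derivable) is undefined: the non-derivable set has ",
         "probability 0 (alpha = ", alpha, ")", call. = FALSE)
  }
  p <- unclass(joint)
  nonderiv <- p[["p01"]] / (p[["p00"]] + p[["p01"]])
  deriv <- (alpha * p[["p01"]] + p[["p10"]] + p[["p11"]]) /
    (alpha + (1 - alpha) * (p[["p10"]] + p[["p11"]]))
  c(non_derivable = nonderiv, derivable = deriv)
}

event_odds_cells <- function(joint, arg) {
  p <- unclass(check_joint(joint, arg))
  ev <- p[["p01"]] + p[["p10"]] + p[["p11"]]
  if (p[["p00"]] <= 0 || ev <= 0) {
    stop("degenerate odds in '", arg, "': both P(y = 1) and P(y = 0) must be ",
         "strictly positive", call. = FALSE)
  }
  p
}

#' Full-data odds ratio for the treatment effect on a two-component composite
#'
#' \eqn{OR_{full} = \frac{(s_{01}+s_{10}+s_{11})\,t_{00}}{(t_{01}+t_{10}+t_{11})\,s_{00}}}
#' where \eqn{s_{jk}} and \eqn{t_{jk}} are the per-arm joint cell
#' probabilities of the two components.
#'
#' @param trt,ctrl Per-arm [two_component_joint()] distributions.
#' @return A positive scalar odds ratio.
#' @export
odds_ratio_full <- function(trt, ctrl) {
  s <- event_odds_cells(trt, "trt")
  t <- event_odds_cells(ctrl, "ctrl")
  ((s[["p01"]] + s[["p10"]] + s[["p11"]]) * t[["p00"]]) /
    ((t[["p01"]] + t[["p10"]] + t[["p11"]]) * s[["p00"]])
}

#' Odds ratio based on the derived composite endpoint
#'
#' Among participants whose endpoint is derivable when \eqn{z_2} is MCAR with
#' observation probability `alpha`:
#' \deqn{OR_{deriv} = \frac{(\alpha s_{01}+s_{10}+s_{11})\,t_{00}}
#'                         {(\alpha t_{01}+t_{10}+t_{11})\,s_{00}}.}
#' Equals [odds_ratio_full()] at `alpha = 1`.
#'
#' @inheritParams odds_ratio_full
#' @param alpha Probability that \eqn{z_2} is observed, in \eqn{(0, 1]}.
#' @return A positive scalar odds ratio.
#' @export
odds_ratio_derived <- function(trt, ctrl, alpha) {
  check_alpha(alpha, open_lower = TRUE)
  s <- event_odds_cells(trt, "trt")
  t <- event_odds_cells(ctrl, "ctrl")
  ((alpha * s[["p01"]] + s[["p10"]] + s[["p11"]]) * t[["p00"]]) /
    ((alpha * t[["p01"]] + t[["p10"]] + t[["p11"]]) * s[["p00"]])
}

#' Within-arm fraction of composite events attributable to the missing
#' component alone
#'
#' The quantity \eqn{p_{01} / (p_{01} + p_{10} + p_{11})}: among participants
#' with a composite event, the fraction whose event is carried only by the
#' partially observed component \eqn{z_2} (so the event is invisible when
#' \eqn{z_2} is missing and \eqn{z_1 = 0}). The bias of the derived-endpoint
#' odds ratio is driven by the contrast of this fraction between arms.
#'
#' @param joint A [two_component_joint()].
#' @return A probability.
#' @export
#' @examples
#' event_fraction(independent_joint(0.7)) # 0.23 to 2 dp
#' event_fraction(independent_joint(0.2)) # 0.44 to 2 dp
event_fraction <- function(joint) {
  p <- unclass(check_joint(joint))
  ev <- p[["p01"]] + p[["p10"]] + p[["p11"]]
  if (ev <= 0) {
    stop("event_fraction undefined: arm has zero event probability",
         call. = FALSE)
  }
  p[["p01"]] / ev
}

#' Bias decomposition of the derived-endpoint odds ratio
#'
#' Computes the ratio \eqn{OR_{deriv}/OR_{full}} together with its
#' decomposition
#' \deqn{\frac{OR_{deriv}}{OR_{full}} = \frac{1-(1-\alpha)\sigma}{1-(1-\alpha)\tau},}
#' where \eqn{\sigma} and \eqn{\tau} are the [event_fraction()]s of the `trt`
#' and `ctrl` joints. The ratio is bounded between \eqn{\alpha} and
#' \eqn{1/\alpha}: one MCAR component can distort the odds ratio by at most a
#' factor \eqn{\alpha}. The derived endpoint overstates the odds ratio when
#' \eqn{\sigma < \tau}, understates it when \eqn{\sigma > \tau}, and is
#' unbiased when \eqn{\sigma = \tau} (for instance when treatment does not
#' affect any component).
#'
#' `sigma` is always the fraction of the arm passed as `trt` (the numerator
#' arm of the odds ratio) and `tau` that of `ctrl`; swapping the arms inverts
#' the ratio.
#'
#' @inheritParams odds_ratio_derived
#' @return An object of class `bias_decomposition`: a list with elements
#'   `or_full`, `or_deriv`, `ratio`, `sigma`, `tau`, `alpha`.
#' @export
#' @examples
#' # independent components at 0.7 vs 0.2 with 70% of z2 missing:
#' bias_ratio(independent_joint(0.7), independent_joint(0.2), alpha = 0.3)
bias_ratio <- function(trt, ctrl, alpha) {
  check_alpha(alpha, open_lower = TRUE)
  or_full <- odds_ratio_full(trt, ctrl)
  or_deriv <- odds_ratio_derived(trt, ctrl, alpha)
  sigma <- event_fraction(trt)
  tau <- event_fraction(ctrl)
  out <- list(or_full = or_full, or_deriv = or_deriv,
              ratio = or_deriv / or_full,
              sigma = sigma, tau = tau, alpha = alpha)
  class(out) <- "bias_decomposition"
  out
}

#' @export
print.bias_decomposition <- function(x, ...) {
  cat("Derived-endpoint bias decomposition\n")
  cat(sprintf("  OR_full  = %.4f\n  OR_deriv = %.4f\n", x$or_full, x$or_deriv))
  cat(sprintf("  ratio    = %.4f  (= [1-(1-a)sigma]/[1-(1-a)tau])\n", x$ratio))
  cat(sprintf("  sigma = %.4f, tau = %.4f, alpha = %.2f\n",
              x$sigma, x$tau, x$alpha))
  invisible(x)
}

#' Complete-record outcome distribution under MCAR
#'
#' The distribution of the composite among complete records,
#' \eqn{P(y = 1 \mid r_{z_2} = 1)}. Under MCAR this equals the full-data
#' event probability \eqn{p_{01}+p_{10}+p_{11}} for every `alpha`, which is
#' why a complete-record analysis is unbiased when the component is MCAR.
#'
#' @inheritParams derived_missingness_probs
#' @param alpha Observation probability of \eqn{z_2}; must be positive for
#'   the conditioning event to have positive probability.
#' @return A probability, constant in `alpha`.
#' @export
cra_outcome_dist <- function(joint, alpha) {
  check_joint(joint)
  check_alpha(alpha, open_lower = TRUE)
  p <- unclass(joint)
  p[["p01"]] + p[["p10"]] + p[["p11"]]
}

#' Bias surface of the derived-endpoint odds ratio over observation rates
#'
#' Tabulates [bias_ratio()] over a grid of MCAR observation probabilities.
#'
#' @inheritParams odds_ratio_full
#' @param alphas Numeric vector of observation probabilities in \eqn{(0, 1]}.
#' @return A data frame with columns `alpha`, `sigma`, `tau`, `or_full`,
#'   `or_deriv`, `ratio`.
#' @export
bias_surface <- function(trt, ctrl, alphas) {
  stopifnot(is.numeric(alphas), length(alphas) >= 1L)
  rows <- lapply(alphas, function(a) {
    b <- bias_ratio(trt, ctrl, a)
    data.frame(alpha = a, sigma = b$sigma, tau = b$tau,
               or_full = b$or_full, or_deriv = b$or_deriv, ratio = b$ratio)
  })
  do.call(rbind, rows)
}
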