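#' Logistic response-model coefficients for one component
#'
#' The probability that a partially observed component \eqn{z_l}
#' (\eqn{l = 2, 3}) is observed follows
#' \deqn{\mathrm{logit}\, P(r_l = 1 \mid x, z_1)
#'   = \alpha_0 + \alpha_x x + \alpha_{z_1} z_1 + \alpha_{x z_1} x z_1,}
#' depending only on the fully observed treatment and component, so the
#' component missingness is MCAR when only \eqn{\alpha_0} is non-zero and
#' MAR otherwise.
#'
#' @param alpha0,alpha_x,alpha_z1,alpha_xz1 Finite coefficients.
#' @return An object of class `missingness_params`.
#' @seealso [mechanism_preset()] for the three named mechanisms.
#' @export
missingness_params <- function(alpha0 = 0, alpha_x = 0, alpha_z1 = 0,
                               alpha_xz1 = 0) {
  a <- c(alpha0 = alpha0, alpha_x = alpha_x, alpha_z1 = alpha_z1,
         alpha_xz1 = alpha_xz1)
  if (!is.numeric(a) || any(!is.finite(a))) {
    stop("all response-model coefficients must be finite", call. = FALSE)
  }
  structure(a, class = "missingness_params")
}

#' Named missingness mechanism presets
#'
#' * `MCAR`: \eqn{\alpha_0 = 0.7}, all else 0 — each component observed with
#'   probability \eqn{\mathrm{expit}(0.7) \approx 0.668} regardless of data;
#' * `MAR1`: \eqn{\alpha_0 = 1.05, \alpha_x = -0.75, \alpha_{z_1} = 0.25};
#' * `MAR2`: as MAR1 plus \eqn{\alpha_{x z_1} = 0.25}.
#'
#' All three give per-component observation probabilities around 0.7.
#'
#' @param mechanism `"MCAR"`, `"MAR1"` or `"MAR2"`.
#' @return A [missingness_params()] object.
#' @export
mechanism_preset <- function(mechanism = c("MCAR", "MAR1", "MAR2")) {
  mechanism <- match.arg(mechanism)
  switch(mechanism,
    MCAR = missingness_params(0.7, 0, 0, 0),
    MAR1 = missingness_params(1.05, -0.75, 0.25, 0),
    MAR2 = missingness_params(1.05, -0.75, 0.25, 0.25))
}

#' Probability that a component is observed
#'
#' @param params A [missingness_params()] object.
#' @param x,z1 Treatment and fully observed component values in \{0, 1\};
#'   vectorized.
#' @return Probabilities in \eqn{(0, 1)}.
#' @export
response_prob <- function(params, x, z1) {
  if (!inherits(params, "missingness_params")) {
    stop("'params' must be a missingness_params object", call. = FALSE)
  }
  if (!all(c(x, z1) %in% c(0, 1))) {
    stop("'x' and 'z1' must be 0 or 1", call. = FALSE)
  }
  stats::plogis(params[["alpha0"]] + params[["alpha_x"]] * x +
                  params[["alpha_z1"]] * z1 + params[["alpha_xz1"]] * x * z1)
}

#' Mask components z2 and z3 according to logistic response models
#'
#' Draws independent response indicators \eqn{r_l \sim
#' \mathrm{Bernoulli}(\pi_l(x, z_1))} per participant for \eqn{l = 2, 3} and
#' sets the component to `NA` where \eqn{r_l = 0}. `x` and `z1` are never
#' masked. When `seed` is supplied, the two components use fixed offsets of
#' it, so toggling one component's mechanism leaves the other's mask
#' unchanged.
#'
#' @param data A trial data frame with complete columns `x`, `z1`, `z2`, `z3`.
#' @param params_z2 [missingness_params()] for `z2`.
#' @param params_z3 [missingness_params()] for `z3`; defaults to `params_z2`.
#' @param seed Optional integer seed.
#' @return `data` with `NA`s introduced in `z2` and `z3`.
#' @export
apply_missingness <- function(data, params_z2, params_z3 = params_z2,
                              seed = NULL) {
  for (col in c("x", "z1", "z2", "z3")) {
    if (is.null(data[[col]])) {
      stop("'data' must contain column '", col, "'", call. = FALSE)
    }
    if (anyNA(data[[col]])) {
      stop("column '", col, "' already contains missing values; ",
           "apply_missingness expects fully observed input", call. = FALSE)
    }
  }
  n <- nrow(data)
  mask_one <- function(params, offset) {
    if (!is.null(seed)) set.seed(as.integer(seed) + offset)
    pr <- response_prob(params, data$x, data$z1)
    stats::rbinom(n, 1L, pr) == 1L
  }
  r2 <- mask_one(params_z2, 1L)
  r3 <- mask_one(params_z3, 2L)
  data$z2[!r2] <- NA_integer_
  data$z3[!r3] <- NA_integer_
  data
}
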