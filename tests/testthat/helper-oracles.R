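# Brute-force oracles used across the test files. These enumerate the small
# discrete sample spaces directly and stay independent of the closed forms
# they check.

# Enumerate the 8 outcomes (z1, z2, r2) for one arm under MCAR observation of
# z2 with probability alpha, and return the quantities of interest as plain
# sums over the outcome table.
enum_two_component <- function(joint, alpha) {
  p <- unclass(joint)
  grid <- expand.grid(z1 = 0:1, z2 = 0:1, r2 = 0:1)
  grid$prob <- apply(grid, 1L, function(g) {
    cell <- p[[paste0("p", g[["z1"]], g[["z2"]])]]
    cell * ifelse(g[["r2"]] == 1, alpha, 1 - alpha)
  })
  grid$y <- as.integer(grid$z1 | grid$z2)
  grid$deriv <- as.integer(grid$r2 == 1 | grid$z1 == 1)
  list(
    p_miss = sum(grid$prob[grid$deriv == 0]),
    p_deriv = sum(grid$prob[grid$deriv == 1]),
    py1_nonderiv = sum(grid$prob[grid$deriv == 0 & grid$y == 1]) /
      sum(grid$prob[grid$deriv == 0]),
    py1_deriv = sum(grid$prob[grid$deriv == 1 & grid$y == 1]) /
      sum(grid$prob[grid$deriv == 1]),
    py1_complete = sum(grid$prob[grid$r2 == 1 & grid$y == 1]) /
      sum(grid$prob[grid$r2 == 1])
  )
}

# Odds ratio among participants with a derivable endpoint, by enumeration
# over (x, z1, z2, r2).
enum_or_deriv <- function(trt, ctrl, alpha) {
  pt <- enum_two_component(trt, alpha)$py1_deriv
  pc <- enum_two_component(ctrl, alpha)$py1_deriv
  (pt / (1 - pt)) / (pc / (1 - pc))
}

enum_or_full <- function(trt, ctrl) {
  pt <- 1 - unclass(trt)[["p00"]]
  pc <- 1 - unclass(ctrl)[["p00"]]
  (pt / (1 - pt)) / (pc / (1 - pc))
}

# A random strictly positive two-component joint.
random_joint <- function() {
  g <- stats::rgamma(4L, shape = 1) + 1e-3
  g <- g / sum(g)
  g <- g / sum(g) # renormalize once more against rounding
  two_component_joint(g[1], g[2], g[3], g[4])
}

# All 3^k tri-state assignments over k components.
tristate_grid <- function(k) {
  do.call(expand.grid, rep(list(c(0L, 1L, NA_integer_)), k))
}
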