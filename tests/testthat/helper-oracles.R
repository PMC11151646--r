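# Independent oracles. These deliberately avoid the package's search
# code: R^2 comes from lm() on the probit-transformed points and the
# theta search is plain exhaustive enumeration.

oracle_r2 <- function(x, g) {
  if (length(unique(x)) < 2L) return(0)
  fit <- stats::lm(stats::qnorm(g) ~ x)
  y <- stats::qnorm(g)
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

# Exhaustive hydrotime grid: R^2 for every candidate theta_H.
brute_force_ht <- function(points, thetas) {
  vapply(thetas, function(th) {
    oracle_r2(points$water_potential_MPa - th / points$tg_h, points$g)
  }, numeric(1))
}

# Exhaustive hydrothermal grid at fixed Tb.
brute_force_htt <- function(points, thetas, Tb) {
  vapply(thetas, function(th) {
    x <- points$water_potential_MPa -
      th / ((points$temperature_C - Tb) * points$tg_h)
    oracle_r2(x, points$g)
  }, numeric(1))
}
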