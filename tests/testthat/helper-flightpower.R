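# Shared fixtures and small numeric helpers.

study_morph <- function() pipistrelle_morphology()
std_cond <- function() flight_conditions()

# Published fitted power curves (regression constants for curve evaluation,
# never refit): raw and weight-/lift-specific, mechanical and metabolic.
mech_curve <- function() power_curve(9.21e-5, 0.176, 0.0297)
mech_curve_lift <- function() power_curve(9.03e-4, 2.22, 0.391)
met_curve <- function() power_curve(3.73e-4, 2.52, 0.490)
met_curve_weight <- function() power_curve(4.11e-3, 28.6, 5.90)

# Random positive cubic-plus-inverse coefficient triples on scales spanning
# mechanical (mW) to weight-specific (W/N) curves, constrained so that both
# characteristic speeds fall inside a physical 1-30 m/s bracket.
random_curve_triples <- function(n, seed = 42) {
  withr::with_seed(seed, {
    k1 <- 10^runif(n, -5, -2)
    u_mp <- runif(n, 2, 12)
    k2 <- 3 * k1 * u_mp^4
    p_am <- k1 * u_mp^3 + k2 / u_mp
    k3 <- runif(n, 0.05, 2) * p_am
    tibble::tibble(k1 = k1, k2 = k2, k3 = k3)
  })
}

# Bilinear interpolation on a regular grid (test-side sampling helper).
bilinear_at <- function(M, x, y, xv, yv) {
  ix <- findInterval(xv, x)
  iy <- findInterval(yv, y)
  fx <- (xv - x[ix]) / (x[2] - x[1])
  fy <- (yv - y[iy]) / (y[2] - y[1])
  M[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    M[cbind(ix + 1, iy)] * fx * (1 - fy) +
    M[cbind(ix, iy + 1)] * (1 - fx) * fy +
    M[cbind(ix + 1, iy + 1)] * fx * fy
}

# A small uniform wake series built directly from field functions.
manual_wake <- function(vfun, wfun, ufun = function(Y, Z) 0 * Y,
                        halfwidth = 0.2, n = 41, freestream = 6,
                        nt = 4, wingbeat_freq = 10) {
  y <- seq(-halfwidth, halfwidth, length.out = n)
  Y <- matrix(y, n, n)
  Z <- matrix(y, n, n, byrow = TRUE)
  dt <- 1 / (wingbeat_freq * nt)
  arr <- function(M) array(rep(M, nt), c(n, n, nt))
  wake_series(y, y, (seq_len(nt) - 1) * dt,
              u = arr(ufun(Y, Z)), v = arr(vfun(Y, Z)), w = arr(wfun(Y, Z)),
              freestream = matrix(freestream, n, n),
              wingbeat_freq = wingbeat_freq)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
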