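# Shared fixtures: the reference baseline and seeded random viable
# parameter draws used by the identity/property tests.

baseline_sp <- function() seasonal_params()
baseline_dp <- function() demography_params()

# Draw random parameter sets (and a resident strategy) around the baseline;
# keep only draws whose resident population is viable at its equilibrium.
draw_viable_params <- function(n, seed = 20260101) {
  set.seed(seed)
  draws <- list()
  tries <- 0
  while (length(draws) < n && tries < 50 * n) {
    tries <- tries + 1
    sp <- seasonal_params(r = runif(1, 0.5, 1.5), sigma_R = runif(1, 0.05, 0.5),
                          R0 = runif(1, 2, 5), s = runif(1, -2, -0.5),
                          sigma_S = runif(1, 0.2, 0.8), S0 = runif(1, 0.85, 1))
    dp <- demography_params(s_A = runif(1, 0.45, 0.9), k = runif(1, 0.3, 0.7),
                            q_c = runif(1, 0.5, 2), v = runif(1, 0.3, 0.8))
    mu <- runif(1, sp$s, sp$r)
    eq <- ecological_equilibrium(mu, sp, dp)
    if (eq$extinct) next
    draws[[length(draws) + 1L]] <- list(sp = sp, dp = dp, mu = mu, eq = eq)
  }
  stopifnot(length(draws) == n)
  draws
}

# Brute-force Riemann-midpoint integral oracle.
riemann <- function(f, a, b, panels = 1e5) {
  x <- seq(a, b, length.out = panels + 1)
  mid <- (x[-1] + x[-length(x)]) / 2
  sum(f(mid)) * (b - a) / panels
}
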