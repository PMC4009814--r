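sp <- baseline_sp()
dp <- baseline_dp()

test_that("settlement accumulates monotonically from zero to the season total", {
  mu <- -0.2
  a <- mu - dp$v / 2
  b <- mu + dp$v / 2
  expect_equal(cumulative_survivors(a, 1, mu, sp, dp), 0)
  expect_equal(cumulative_survivors(a - 1, 1, mu, sp, dp), 0)
  expect_equal(cumulative_survivors(b + 2, 1, mu, sp, dp),
               total_survivors(1, mu, sp, dp))
  expect_equal(cumulative_survivors(0.1, 0, mu, sp, dp), 0)

  x <- seq(a - 0.2, b + 0.2, length.out = 101)
  ns <- cumulative_survivors(x, 1, mu, sp, dp)
  expect_true(all(diff(ns) >= 0))
})

test_that("total survivors respect the survival bounds", {
  # perfect-survival limit: window far after the spring transition
  expect_equal(total_survivors(1, sp$s + 100, sp, dp), 1, tolerance = 1e-10)
  # window centred on the half-saturation point with a narrow window
  dpn <- demography_params(v = 1e-3)
  expect_equal(total_survivors(1, sp$s, sp, dpn), 0.5 * sp$S0,
               tolerance = 1e-6)
  expect_equal(total_survivors(0, 0, sp, dp), 0)
  # N_S < n and N_S <= S0 * n
  for (mu in c(-1.5, -0.2, 0.8)) {
    NS <- total_survivors(2, mu, sp, dp)
    expect_lt(NS, 2)
    expect_lte(NS, sp$S0 * 2)
  }
})

test_that("territory quality declines from 1 and clamps at the window edges", {
  mu <- -0.2
  expect_equal(territory_quality(0.1, 0, mu, sp, dp), 1)
  # before the window the first arriver finds the best territory
  expect_equal(territory_quality(mu - dp$v, 1, mu, sp, dp), 1)
  # beyond the window quality freezes at its end-of-window value
  b <- mu + dp$v / 2
  expect_equal(territory_quality(b + 3, 1, mu, sp, dp),
               territory_quality(b, 1, mu, sp, dp))
  # linear hit of zero at n_S = 1/q_c, and clamped at 0 beyond
  n_big <- 1 / total_survivors(1, mu, sp, dp) / dp$q_c
  expect_equal(territory_quality(b, n_big, mu, sp, dp), 0, tolerance = 1e-12)
  expect_equal(territory_quality(b, 2 * n_big, mu, sp, dp), 0)
  # non-increasing along the season, always in [0, 1]
  x <- seq(mu - dp$v, mu + dp$v, length.out = 101)
  Q <- territory_quality(x, 3, mu, sp, dp)
  expect_true(all(diff(Q) <= 0))
  expect_true(all(Q >= 0 & Q <= 1))
})

test_that("recruitment matches limits and the competition-free reduction", {
  expect_equal(recruits(0, -0.2, sp, dp), 0)
  # no competition, saturated survival and reproduction: B -> R0 * S0 * n
  sp_flat <- seasonal_params(r = 1e3, s = -1e3)
  dp_free <- demography_params(q_c = 0)
  expect_equal(recruits(2, 0, sp_flat, dp_free), sp_flat$R0 * sp_flat$S0 * 2,
               tolerance = 1e-9)
  # B <= R0 * N_S always
  for (n in c(0.3, 1, 5)) {
    expect_lte(recruits(n, -0.2, sp, dp),
               sp$R0 * total_survivors(n, -0.2, sp, dp) + 1e-12)
  }
})

test_that("within-season integrals agree with a brute-force Riemann oracle", {
  mu <- -0.23
  n <- 3  # high density so the quality kink is exercised
  a <- mu - dp$v / 2
  b <- mu + dp$v / 2
  B_oracle <- n / dp$v * riemann(function(x) {
    prebreeding_survival(x, sp) * reproductive_success(x, sp) *
      territory_quality(x, n, mu, sp, dp)
  }, a, b)
  expect_equal(recruits(n, mu, sp, dp), B_oracle, tolerance = 1e-8)

  NS_oracle <- n / dp$v * riemann(function(x) prebreeding_survival(x, sp), a, b)
  expect_equal(total_survivors(n, mu, sp, dp), NS_oracle, tolerance = 1e-8)
})

test_that("the annual map fixes its equilibrium and absorbs extinction", {
  expect_equal(annual_update(0, -0.2, sp, dp), 0)
  eq <- ecological_equilibrium(-0.23, sp, dp)
  expect_true(eq$converged)
  expect_false(eq$extinct)
  expect_gt(eq$n_star, 0)
  expect_equal(annual_update(eq$n_star, -0.23, sp, dp), eq$n_star,
               tolerance = 1e-8)
})

test_that("fraction of young follows the recruit share of returning migrants", {
  # no recruits: R0 -> 0 means f -> 0 (take a food peak far in the past)
  sp_no_food <- seasonal_params(r = -1e3)
  eqf <- fraction_young(1, -0.2, sp_no_food, dp)
  expect_lt(eqf, 1e-6)
  # equal contributions with k = 0.5 give f = 1/3: verified via the identity
  # f = kB / (NS + kB) computed from the component operations
  NS <- total_survivors(0.4, -0.2, sp, dp)
  B <- recruits(0.4, -0.2, sp, dp)
  expect_equal(fraction_young(0.4, -0.2, sp, dp),
               dp$k * B / (NS + dp$k * B), tolerance = 1e-10)
  # extinct population: undefined
  expect_true(is.na(fraction_young(1, -0.2, seasonal_params(r = -1e3, s = 1e3), dp)))
})

test_that("equilibrium is independent of the starting density", {
  e1 <- ecological_equilibrium(-0.23, sp, dp, n0 = 0.01)
  e2 <- ecological_equilibrium(-0.23, sp, dp, n0 = 10)
  expect_equal(e1$n_star, e2$n_star, tolerance = 1e-8)
  expect_equal(e1$f_star, e2$f_star, tolerance = 1e-8)
})

test_that("a population that cannot invade the empty habitat is extinct", {
  dp_weak <- demography_params(s_A = 0.2)
  # oracle: per-capita growth at vanishing density, by quadrature
  mu <- -0.3
  growth0 <- stats::integrate(function(x) {
    prebreeding_survival(x, sp) *
      (dp_weak$s_A + dp_weak$k * dp_weak$s_A * reproductive_success(x, sp))
  }, mu - dp_weak$v / 2, mu + dp_weak$v / 2, rel.tol = 1e-10)$value / dp_weak$v
  expect_lt(growth0, 1)
  eq <- ecological_equilibrium(mu, sp, dp_weak)
  expect_true(eq$extinct)
  expect_equal(eq$n_star, 0)
  expect_true(is.na(eq$f_star))
  expect_equal(empty_environment_growth(mu, sp, dp_weak), growth0,
               tolerance = 1e-10)
})

test_that("reduced-coefficient iteration agrees with direct quadrature stepping", {
  # moderate and kink-active densities, stepped both ways
  for (mu in c(-0.6, -0.23, 0.2)) {
    eq <- ecological_equilibrium(mu, sp, dp)
    if (eq$extinct) next
    expect_equal(annual_update(eq$n_star, mu, sp, dp), eq$n_star,
                 tolerance = 1e-8)
  }
  # strong competition regime where quality hits zero inside the window
  sp_rich <- seasonal_params(R0 = 6)
  dp_rich <- demography_params(s_A = 0.9)
  eq <- ecological_equilibrium(-0.9, sp_rich, dp_rich)
  expect_false(eq$extinct)
  nS_end <- total_survivors(eq$n_star, -0.9, sp_rich, dp_rich)
  expect_gt(dp_rich$q_c * nS_end, 1)  # kink is genuinely active
  expect_equal(annual_update(eq$n_star, -0.9, sp_rich, dp_rich), eq$n_star,
               tolerance = 1e-8)
})
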