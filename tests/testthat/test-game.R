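# closed-form vaccination game

test_that("payoffs are the stated linear forms", {
  expect_equal(payoff_vaccinated(0), 0)
  expect_equal(payoff_vaccinated(1), -1)
  expect_equal(payoff_vaccinated(0.5), -0.5)
  expect_equal(payoff_unvaccinated(10, 10, 0), 0)
  expect_equal(payoff_unvaccinated(10, 10, 0.01), -1)
  expect_equal(payoff_unvaccinated(10, 10, 0.02),
               2 * payoff_unvaccinated(10, 10, 0.01))
})

test_that("expected payoff interpolates the pure strategies and is flat at indifference", {
  expect_equal(expected_payoff(1, 0.3, 10, 0.05), -0.3)
  expect_equal(expected_payoff(0, 0.3, 10, 0.05), -0.5)
  # beta_U * I == r: every P gives the same payoff
  Ps <- seq(0, 1, by = 0.1)
  expect_equal(expected_payoff(Ps, 0.2, 10, 0.02), rep(-0.2, length(Ps)))
})

test_that("payoff gain vanishes on the indifference line and for identical strategies", {
  expect_equal(payoff_gain(10, 0.05, 0.1, 0.4, 0.4), 0)
  expect_equal(payoff_gain(10, 0.03, 0.3, 0.9, 0.1), 0)
  expect_gt(payoff_gain(10, 0.05, 0.1, 0.8, 0.2), 0)
  expect_lt(payoff_gain(10, 0.001, 0.1, 0.8, 0.2), 0)
})

test_that("coverage mixes the two subpopulations", {
  expect_equal(coverage(1, 0.3, 0.9), 0.3)
  expect_equal(coverage(0, 0.3, 0.9), 0.9)
  expect_equal(coverage(0.5, 0.2, 0.8), 0.5)
})

test_that("theta_crit reproduces the herd-immunity thresholds", {
  expect_equal(theta_crit(10), 0.9)
  expect_equal(theta_crit(20), 0.95)
  expect_equal(theta_crit(0.5), 0)
  expect_equal(round(theta_crit(c(5, 10, 15, 20)) * 100) / 100 >= 0, rep(TRUE, 4))
})

test_that("force of infection hits zero exactly at the critical coverage", {
  expect_equal(force_of_infection_U(10, 0), 0.9)
  expect_equal(force_of_infection_U(10, theta_crit(10)), 0, tolerance = 1e-12)
  expect_equal(force_of_infection_U(1, 0), 0)
  expect_equal(force_of_infection_U(2, 0.9), 0)  # clamped disease-free branch
  expect_error(force_of_infection_U(10, 1), "theta")
})

test_that("ESS existence follows R0 (1 - r) > 1", {
  expect_true(ess_exists(10, 0.1))
  expect_false(ess_exists(2, 0.6))
  expect_false(ess_exists(100, 1))
  expect_false(ess_exists(100, 1.5))
})

test_that("p_star matches the reference values and signals the no-ESS case", {
  expect_equal(round(p_star(10, 0.1), 2), 0.89)
  expect_equal(round(p_star(5, 0.1), 2), 0.78)
  expect_equal(p_star(10, 0), theta_crit(10))
  expect_warning(out <- p_star(2, 0.9), "no mixed ESS")
  expect_true(is.na(out))
  expect_error(p_star(2, 0.9, strict = TRUE), "no mixed ESS")
})

test_that("p_star sits below theta_crit, decreases in r, increases in R0", {
  for (R0 in c(2, 5, 10, 20)) {
    for (r in c(0.05, 0.1, 0.2)) {
      if (!ess_exists(R0, r)) next
      expect_lt(p_star(R0, r), theta_crit(R0))
    }
    rs <- c(0.01, 0.05, 0.1, 0.2, 0.3)
    rs <- rs[ess_exists(R0, rs)]
    expect_true(all(diff(p_star(R0, rs)) < 0))
  }
  expect_true(all(diff(p_star(c(2, 5, 10, 20), 0.1)) > 0))
})

test_that("force of infection at P* returns the relative risk (defining fixed point)", {
  for (R0 in c(1.5, 5, 10, 20)) for (r in c(0.01, 0.1, 0.3)) {
    if (!ess_exists(R0, r)) next
    expect_equal(force_of_infection_U(R0, p_star(R0, r)), r, tolerance = 1e-12)
  }
})

test_that("switch point is r_v / (r_i beta_U) and governs the payoff slope", {
  expect_equal(switch_point(1, 10, 10), 0.01)
  expect_equal(switch_point(0, 10, 10), 0)
  expect_error(switch_point(1, 0, 10), "positive")
  ip <- switch_point(1, 10, 10)
  # dE/dP = beta_U I - r: positive above I', negative below
  slope <- function(I) expected_payoff(1, 0.1, 10, I) - expected_payoff(0, 0.1, 10, I)
  expect_gt(slope(ip * 2), 0)
  expect_lt(slope(ip / 2), 0)
})

test_that("endemic equilibrium switches branch at theta_crit and stays nonnegative", {
  eq <- endemic_equilibrium(10, 0.01, 0.5)
  expect_equal(eq$S_hat, 0.1)
  expect_equal(eq$I_hat, 0.01 / 1.01 * (0.9 - 0.5))
  expect_gte(eq$I_hat, 0)
  eq2 <- endemic_equilibrium(10, 0.01, 0.95)
  expect_equal(eq2$branch, "disease_free")
  expect_equal(eq2$I_hat, 0)
  eq3 <- endemic_equilibrium(10, 0.01, theta_crit(10))
  expect_equal(eq3$I_hat, 0)
  for (P in seq(0, 0.89, by = 0.1))
    expect_gte(endemic_equilibrium(10, 0.05, P)$I_hat, 0)
})

test_that("regimes classify by coverage against P* and theta_crit", {
  expect_equal(classify_regime(10, 0.1, 1), "eradicated")
  expect_equal(classify_regime(10, 0.1, 0.89), "steady_endemic")
  expect_equal(classify_regime(10, 0.1, 0.5), "unsteady")
  # no-ESS: only the eradication boundary remains
  expect_equal(classify_regime(2, 0.9, 0.6), "eradicated")
  expect_equal(classify_regime(2, 0.9, 0.3), "unsteady")
})

test_that("reference table rounds half-up to the printed digits", {
  tab <- game_table1()
  expect_equal(tab$theta_crit, c(0.80, 0.90, 0.93, 0.95))
  expect_equal(tab$p_star, c(0.78, 0.89, 0.93, 0.94))
})
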