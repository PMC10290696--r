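# individual-based Monte Carlo simulator
# unit tests run small systems / short horizons; the full-scale ensembles
# live in the acceptance suite

small <- function(..., t_end = 30) ibmc_params(N = 200, L = 110, t_end = t_end, ...)

test_that("parameter validation rejects impossible settings", {
  expect_error(ibmc_params(N = 1), "at least 2")
  expect_error(ibmc_params(p_infect = 1.5), "probability")
  expect_error(ibmc_params(p_vacc = -0.1), "probability")
  expect_error(ibmc_params(t_incubation = c(-1, 2)), "mean > 0")
  expect_error(ibmc_params(t_end = 0), "positive")
  p <- ibmc_params()
  expect_equal(p$rho, p$N / p$L^2)
  expect_equal(p$rho, 1000 / 246^2)  # density derived from N and L
})

test_that("initial population: uniform placement, one index case, vaccination draws", {
  p <- small(p_vacc = 0)
  pop <- init_population(p, seed = 3)
  expect_true(all(pop$x >= 0 & pop$x < p$L & pop$y >= 0 & pop$y < p$L))
  cc <- ibmc_class_counts(pop)
  expect_equal(sum(cc[1:5]), p$N)
  expect_equal(unname(cc["incubating"]), 1)     # index case incubates at t = 0
  expect_equal(unname(cc["vaccinated"]), 0)     # p_vacc = 0: nobody opts in
  popall <- init_population(small(p_vacc = 1), seed = 3)
  expect_equal(sum(popall$vaccinated), 199)     # everyone except the index case
})

test_that("vaccinated counts fall in the binomial 99% band", {
  # oracle: qbinom for n = N - 1 Bernoulli(p_vacc) draws
  p <- ibmc_params(N = 1000, p_vacc = 0.4, t_end = 10)
  band <- stats::qbinom(c(0.005, 0.995), size = 999, prob = 0.4)
  for (s in 1:5) {
    pop <- init_population(p, seed = s)
    expect_gte(sum(pop$vaccinated), band[1])
    expect_lte(sum(pop$vaccinated), band[2])
  }
})

test_that("duration sampler: degenerate sd, truncation floor, analytic mean", {
  expect_equal(ibmc_sample_durations(10, 14, 0, seed = 1), rep(14, 10))
  expect_true(all(ibmc_sample_durations(2e4, 1, 3, seed = 2) > 0.1))
  draws <- ibmc_sample_durations(1e5, 7.74, 4.39, seed = 5)
  # independent closed form for the mean of a lower-truncated normal
  a <- (0.1 - 7.74) / 4.39
  m <- 7.74 + 4.39 * dnorm(a) / (1 - pnorm(a))
  expect_equal(mean(draws), m, tolerance = 0.01)
  # R-level sampler has the same distribution
  set.seed(9)
  draws_r <- sample_duration(1e5, 7.74, 4.39)
  expect_equal(mean(draws_r), m, tolerance = 0.01)
  expect_true(all(sample_duration(1e4, 180, 30) > 0))
  expect_equal(truncnorm_mean(7.74, 4.39), m)
})

test_that("a fixed seed gives a bit-identical trajectory", {
  p <- small(p_vacc = 0.3)
  t1 <- ibmc_run(p, seed = 11)
  t2 <- ibmc_run(p, seed = 11)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "peak_infectious"), attr(t2, "peak_infectious"))
  t3 <- ibmc_run(p, seed = 12)
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("advancing in chunks reproduces a single advance (RNG state round-trip)", {
  p <- small()
  pop_a <- init_population(p, seed = 21)
  pop_a <- ibmc_step(pop_a, p, n_steps = 2000)
  pop_b <- init_population(p, seed = 21)
  pop_b <- ibmc_step(ibmc_step(pop_b, p, n_steps = 700), p, n_steps = 1300)
  expect_equal(pop_a$x, pop_b$x)
  expect_equal(pop_a$state, pop_b$state)
  expect_identical(ibmc_class_counts(pop_a), ibmc_class_counts(pop_b))
})

test_that("class counts are conserved and deaths are monotone along a run", {
  p <- small(p_vacc = 0.2, p_fatal = 0.2)
  tr <- ibmc_run(p, seed = 31)
  sums <- rowSums(tr[, c("healthy", "incubating", "infectious", "immune", "dead")])
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  expect_true(all(diff(tr$dead) >= 0))
})

test_that("without transmission the epidemic never grows past the index case", {
  p <- small(p_infect = 0, t_end = 60)
  tr <- ibmc_run(p, seed = 41)
  expect_equal(attr(tr, "ever_infected"), 1)
  expect_lte(max(tr$infectious), 1 / p$N)
  expect_lte(attr(tr, "peak_infectious"), 1 / p$N)
})

test_that("universal immediate vaccination confines the epidemic to the index case", {
  # near-zero onset delay and a window outlasting the horizon: protection
  # effectively covers [0, t_end] for everyone but the index case
  p <- small(p_vacc = 1, t_vacc = c(0.0001, 0), t_vacc_immune = c(1000, 0))
  tr <- ibmc_run(p, seed = 51)
  expect_lte(attr(tr, "peak_infectious"), 1 / p$N)
  expect_lte(attr(tr, "ever_infected"), 2)
})

test_that("movement: step length delta_R, periodic wrap, diffusive MSD", {
  p <- ibmc_params(N = 500, L = 246, p_infect = 0, t_end = 1)
  pop0 <- init_population(p, seed = 61)
  pop1 <- ibmc_step(pop0, p, n_steps = 1)
  mi <- function(d, L) (d + L / 2) %% L - L / 2  # minimum-image displacement
  dx <- mi(pop1$x - pop0$x, p$L); dy <- mi(pop1$y - pop0$y, p$L)
  expect_equal(sqrt(dx^2 + dy^2), rep(p$delta_R, p$N), tolerance = 1e-9)
  expect_true(all(pop1$x >= 0 & pop1$x < p$L))
  # MSD after k steps ~ k * delta_R^2 (unbiased 2D walk, D = dR^2 / (4 tau))
  k <- 400
  popk <- ibmc_step(pop1, p, n_steps = k - 1)
  dxk <- mi(popk$x - pop0$x, p$L); dyk <- mi(popk$y - pop0$y, p$L)
  msd <- mean(dxk^2 + dyk^2)
  expect_equal(msd, k * p$delta_R^2, tolerance = 0.15)
})

test_that("ensembles: identical seeds collapse the spread, stats bound the members", {
  p <- small(p_vacc = 0.2)
  ens_same <- ibmc_ensemble(p, n_reps = 3, seeds = c(5, 5, 5))
  expect_equal(max(ens_same$sd, na.rm = TRUE), 0)
  ens <- ibmc_ensemble(p, n_reps = 4, base_seed = 70)
  expect_gte(mean(ens$peak_infectious), min(ens$peak_infectious))
  expect_lte(mean(ens$peak_infectious), max(ens$peak_infectious))
  expect_error(ibmc_ensemble(p, n_reps = 3, seeds = 1:2), "n_reps")
  expect_error(ibmc_ensemble(p, n_reps = 1), "n_reps >= 2")
})

test_that("both infection clocks run and per-contact-entry infects no faster", {
  p1 <- small(p_infect = 0.5)
  p2 <- small(p_infect = 0.5, infection_mode = "per_contact_entry")
  e1 <- mean(sapply(1:3, function(s) attr(ibmc_run(p1, seed = s), "ever_infected")))
  e2 <- mean(sapply(1:3, function(s) attr(ibmc_run(p2, seed = s), "ever_infected")))
  expect_gte(e1, e2)  # fewer Bernoulli trials per contact episode
})
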