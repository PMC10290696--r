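#' Individual-based Monte Carlo epidemic simulator
#'
#' `N` structureless agents perform an unbiased random walk (step `delta_R`
#' per Monte Carlo step `tau`, diffusion coefficient `D = delta_R^2/(4 tau)`)
#' on a periodic square of side `L`.  A susceptible agent within the
#' infectious distance `r_infect` of an infectious agent is infected with
#' probability `p_infect` per infectious neighbour per step.  Disease course:
#' incubation (sick but not infectious) of `t_incubation`, an infectious
#' period `t_infect` ending in death (probability `p_fatal`, decided at
#' infection, death time uniform within the infectious period) or in waning
#' immunity lasting `t_infect_immune`.  At t = 0 one agent is the index case
#' and every other agent independently vaccinates with probability `p_vacc`,
#' gaining a delayed immunity window `[t_vacc, t_vacc + t_vacc_immune)`.
#' All "mean +/- sd" durations are truncated-normal draws (floor 0.1 day).
#'
#' @name ibmc
NULL

ibmc_check_prob <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop("`", nm, "` must be a probability in [0, 1]")
  x
}

ibmc_check_dur <- function(x, nm) {
  x <- as.numeric(x)
  if (length(x) == 1) x <- c(x, 0)
  if (length(x) != 2 || any(is.na(x)) || x[1] <= 0 || x[2] < 0)
    stop("`", nm, "` must be c(mean, sd) with mean > 0, sd >= 0")
  x
}

#' IBMC scenario parameters
#'
#' Defaults reproduce the reference parameterisation: 1000 agents on a
#' 246 m periodic square (density `rho = N/L^2 = 0.165` per m^2, mimicking a
#' congested urban area), 1 m unmasked infectious distance, infection and
#' fatality probabilities of
#' 1.8% and 0.8%, incubation 7.74 +/- 4.39 days, infectious period and
#' vaccine delay both 14 +/- 7 days, and six-month (180 +/- 30 day) waning
#' immunity from either infection or vaccination.
#'
#' @param N number of individuals (>= 2).
#' @param L system side length, m.
#' @param r_infect infectious distance, m.
#' @param p_infect per-step, per-infectious-neighbour infection probability.
#' @param p_fatal probability an infection is fatal.
#' @param p_vacc probability an individual vaccinates at t = 0.
#' @param t_incubation,t_infect,t_vacc,t_infect_immune,t_vacc_immune
#'   `c(mean, sd)` durations in days (a single number means sd = 0).
#' @param tau Monte Carlo time step, days.
#' @param delta_R Monte Carlo step size, m.
#' @param t_end simulation horizon, days.
#' @param infection_mode `"per_step"` applies the infection Bernoulli trial
#'   every step a pair is in range; `"per_contact_entry"` only when the pair
#'   newly comes into range.
#' @param revaccinate_on_waning renew vaccine-immunity windows when they
#'   expire (booster behaviour); off by default.
#' @return object of class `ibmc_params`.
#' @export
ibmc_params <- function(N = 1000, L = 246, r_infect = 1, p_infect = 0.018,
                        p_fatal = 0.008, p_vacc = 0,
                        t_incubation = c(7.74, 4.39),
                        t_infect = c(14, 7),
                        t_vacc = c(14, 7),
                        t_infect_immune = c(180, 30),
                        t_vacc_immune = c(180, 30),
                        tau = 0.001, delta_R = 1.0, t_end = 1500,
                        infection_mode = c("per_step", "per_contact_entry"),
                        revaccinate_on_waning = FALSE) {
  if (!is.numeric(N) || N < 2) stop("`N` must be at least 2 (no epidemic is possible otherwise)")
  stopifnot(L > 0, r_infect > 0, tau > 0, delta_R > 0)
  if (t_end <= 0) stop("`t_end` must be positive")
  infection_mode <- match.arg(infection_mode)
  p <- list(
    N = as.integer(N), L = L, rho = N / L^2, r_infect = r_infect,
    p_infect = ibmc_check_prob(p_infect, "p_infect"),
    p_fatal = ibmc_check_prob(p_fatal, "p_fatal"),
    p_vacc = ibmc_check_prob(p_vacc, "p_vacc"),
    t_incubation = ibmc_check_dur(t_incubation, "t_incubation"),
    t_infect = ibmc_check_dur(t_infect, "t_infect"),
    t_vacc = ibmc_check_dur(t_vacc, "t_vacc"),
    t_infect_immune = ibmc_check_dur(t_infect_immune, "t_infect_immune"),
    t_vacc_immune = ibmc_check_dur(t_vacc_immune, "t_vacc_immune"),
    tau = tau, delta_R = delta_R, t_end = t_end,
    infection_mode = infection_mode,
    revaccinate_on_waning = isTRUE(revaccinate_on_waning)
  )
  class(p) <- "ibmc_params"
  p
}

#' @export
print.ibmc_params <- function(x, ...) {
  cat(sprintf("IBMC parameters: N = %d on a %.0f m periodic square (rho = %.3f /m^2)\n",
              x$N, x$L, x$rho))
  cat(sprintf("  r_infect = %g m, p_infect = %g, p_fatal = %g, p_vacc = %g\n",
              x$r_infect, x$p_infect, x$p_fatal, x$p_vacc))
  cat(sprintf("  tau = %g d, delta_R = %g m (D = %.3g m^2/d), t_end = %g d, mode = %s\n",
              x$tau, x$delta_R, x$delta_R^2 / (4 * x$tau), x$t_end,
              x$infection_mode))
  invisible(x)
}

#' Sample positive durations around a mean +/- sd
#'
#' Truncated-normal sampler used for all IBMC "mean +/- sd" durations:
#' normal draws conditioned to exceed a small positive floor (0.1 day by
#' default), via inverse-CDF sampling with R's RNG.  `sd = 0` returns the
#' mean exactly.
#'
#' @param n number of draws.
#' @param mean,sd distribution parameters (days); `mean > 0`, `sd >= 0`.
#' @param floor lower truncation bound.
#' @return vector of `n` durations, all `> floor` (or `== mean` when
#'   `sd = 0`).
#' @export
sample_duration <- function(n, mean, sd, floor = 0.1) {
  stopifnot(n >= 0, mean > 0, sd >= 0)
  if (sd == 0) return(rep(mean, n))
  alpha <- (floor - mean) / sd
  lo <- stats::pnorm(alpha)
  u <- stats::runif(n, min = lo, max = 1)
  mean + sd * stats::qnorm(u)
}

#' Analytic mean of the truncated-normal duration distribution
#'
#' @inheritParams sample_duration
#' @return expected value of [sample_duration()] draws.
#' @export
truncnorm_mean <- function(mean, sd, floor = 0.1) {
  if (sd == 0) return(mean)
  alpha <- (floor - mean) / sd
  mean + sd * stats::dnorm(alpha) / (1 - stats::pnorm(alpha))
}

ibmc_params_for_cpp <- function(params) {
  stopifnot(inherits(params, "ibmc_params"))
  params
}

#' Initialise an agent population
#'
#' Places `N` agents uniformly on the periodic square, selects one uniformly
#' at random as the index case (entering incubation at t = 0) and vaccinates
#' every other agent independently with probability `p_vacc`.
#'
#' @param params [ibmc_params()].
#' @param seed integer seed for the simulator's private RNG stream.
#' @return object of class `ibmc_population`: a list of per-agent vectors
#'   (`x`, `y`, `state`, `vaccinated`, ...) plus clock and RNG state.  The
#'   `state` codes are 0 healthy, 1 incubating, 2 infectious, 3 immune
#'   (infection-derived), 4 dead; agents in an active vaccine window are
#'   reported in the immune class by [ibmc_class_counts()].
#' @export
init_population <- function(params, seed = 1) {
  params <- ibmc_params_for_cpp(params)
  pop <- ibmc_cpp_init(params, as.numeric(seed))
  attr(pop, "seed") <- seed
  class(pop) <- "ibmc_population"
  pop
}

#' Advance a population by Monte Carlo steps
#'
#' Each step: (1) every non-dead agent moves one step of length `delta_R` in
#' a uniformly random direction with periodic wrapping; (2) a synchronous
#' infection sweep over post-move positions; (3) scheduled transitions fire
#' in agent-index order.
#'
#' @param pop [init_population()] result.
#' @param params the same [ibmc_params()] the population was built with.
#' @param n_steps number of MC steps (`tau` days each) to advance.
#' @return the advanced population.
#' @export
ibmc_step <- function(pop, params, n_steps = 1) {
  stopifnot(inherits(pop, "ibmc_population"), n_steps >= 1)
  out <- ibmc_cpp_advance(pop, ibmc_params_for_cpp(params),
                          as.numeric(n_steps))
  attr(out, "seed") <- attr(pop, "seed")
  class(out) <- "ibmc_population"
  out
}

#' Class counts of a population
#'
#' @param pop [init_population()] result.
#' @return named integer vector over the five exclusive classes (healthy,
#'   incubating, infectious, immune, dead -- summing to `N`) plus the
#'   overlapping `vaccinated` bookkeeping count.
#' @export
ibmc_class_counts <- function(pop) {
  st <- pop$state
  t <- pop$t
  in_window <- pop$state == 0 & t >= pop$vacc_start & t < pop$vacc_end
  c(healthy = sum(st == 0 & !in_window),
    incubating = sum(st == 1),
    infectious = sum(st == 2),
    immune = sum(st == 3) + sum(in_window),
    dead = sum(st == 4),
    vaccinated = sum(pop$vaccinated == 1))
}

#' Run one IBMC simulation
#'
#' @param params [ibmc_params()].
#' @param seed integer seed; a fixed seed gives a bit-identical trajectory.
#' @param record_stride reporting stride in days (the dynamics always run at
#'   step `tau`).
#' @return object of class `ibmc_trajectory`: data frame with `time` and the
#'   population fractions of the five exclusive classes plus the vaccinated
#'   bookkeeping fraction and cumulative `dead`; attributes
#'   `peak_infectious` (fraction, tracked every MC step), `ever_infected`,
#'   `extinction_time` (first time with no incubating/infectious agents, NA
#'   if the epidemic outlives the horizon), `n_dead`, `seed`, `params`.
#' @export
ibmc_run <- function(params, seed = 1, record_stride = 1) {
  params <- ibmc_params_for_cpp(params)
  stopifnot(record_stride >= params$tau)
  res <- ibmc_cpp_run(params, as.numeric(seed), record_stride)
  counts <- res$counts
  df <- data.frame(time = res$time, counts / params$N)
  names(df) <- c("time", colnames(counts))
  attr(df, "peak_infectious") <- res$peak_infectious / params$N
  attr(df, "ever_infected") <- res$ever_infected
  attr(df, "extinction_time") <- if (res$extinction_time < 0) NA_real_
                                 else res$extinction_time
  attr(df, "n_dead") <- res$n_dead
  attr(df, "seed") <- seed
  attr(df, "params") <- params
  class(df) <- c("ibmc_trajectory", class(df))
  df
}

#' @export
print.ibmc_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  ext <- attr(x, "extinction_time")
  cat(sprintf("IBMC trajectory: N = %d, p_vacc = %g, %d daily records\n",
              p$N, p$p_vacc, nrow(x)))
  cat(sprintf("  peak infectious fraction %.3f; ever infected %d; deaths %d; %s\n",
              attr(x, "peak_infectious"), attr(x, "ever_infected"),
              attr(x, "n_dead"),
              if (is.na(ext)) "epidemic outlived the horizon"
              else sprintf("extinct at day %.0f", ext)))
  invisible(x)
}

#' Ensemble of independent IBMC simulations
#'
#' @param params [ibmc_params()].
#' @param n_reps number of replicates (>= 2).
#' @param seeds integer seeds, one per replicate (defaults to
#'   `base_seed + 0:(n_reps-1)`).
#' @param base_seed used to build default seeds.
#' @param record_stride reporting stride in days.
#' @return list with `time`, per-class `mean` and `sd` fraction matrices,
#'   `peak_infectious` and `final_immune` per replicate, `seeds`, and the
#'   individual `runs`.
#' @export
ibmc_ensemble <- function(params, n_reps = 10, seeds = NULL,
                          base_seed = 1, record_stride = 1) {
  stopifnot(n_reps >= 2)
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_reps) - 1L
  if (length(seeds) != n_reps)
    stop("`seeds` must have exactly `n_reps` entries")
  runs <- lapply(seeds, function(s) ibmc_run(params, seed = s,
                                             record_stride = record_stride))
  classes <- c("healthy", "incubating", "infectious", "immune", "dead",
               "vaccinated")
  nt <- min(vapply(runs, nrow, integer(1)))
  time <- runs[[1]]$time[seq_len(nt)]
  arr <- array(NA_real_, dim = c(nt, length(classes), n_reps))
  for (k in seq_len(n_reps))
    arr[, , k] <- as.matrix(runs[[k]][seq_len(nt), classes])
  mean_mat <- apply(arr, c(1, 2), mean)
  sd_mat <- apply(arr, c(1, 2), stats::sd)
  colnames(mean_mat) <- colnames(sd_mat) <- classes
  list(
    time = time,
    mean = mean_mat,
    sd = sd_mat,
    peak_infectious = vapply(runs, function(r) attr(r, "peak_infectious"),
                             numeric(1)),
    final_immune = vapply(runs, function(r) r$immune[nrow(r)], numeric(1)),
    extinction_time = vapply(runs, function(r) {
      e <- attr(r, "extinction_time"); if (is.na(e)) NA_real_ else e
    }, numeric(1)),
    seeds = seeds,
    runs = runs
  )
}

#' Sweep the vaccination probability
#'
#' Runs an [ibmc_ensemble()] for each `p_vacc` on a grid and summarises the
#' distribution of peak infectious fractions -- the decreasing branch at
#' high coverage is the herd-immunity signature.
#'
#' @param params base [ibmc_params()] (its `p_vacc` is overridden).
#' @param p_vacc_grid vaccination probabilities to scan.
#' @param n_reps replicates per grid point.
#' @param base_seed seed offset; replicate seeds are derived per grid point.
#' @param record_stride reporting stride in days.
#' @return data frame with one row per grid point: `p_vacc`, `peak_mean`,
#'   `peak_sd`, `peak_min`, `peak_max`, `all_below_5pct`.
#' @export
ibmc_sweep <- function(params, p_vacc_grid = seq(0, 0.8, by = 0.1),
                       n_reps = 10, base_seed = 1, record_stride = 1) {
  rows <- lapply(seq_along(p_vacc_grid), function(i) {
    pv <- p_vacc_grid[i]
    p <- params
    p$p_vacc <- ibmc_check_prob(pv, "p_vacc")
    ens <- ibmc_ensemble(p, n_reps = n_reps,
                         base_seed = base_seed + 1000L * (i - 1L),
                         record_stride = record_stride)
    pk <- ens$peak_infectious
    data.frame(p_vacc = pv, peak_mean = mean(pk), peak_sd = stats::sd(pk),
               peak_min = min(pk), peak_max = max(pk),
               all_below_5pct = all(pk < 0.05))
  })
  do.call(rbind, rows)
}

#' Draw durations from the simulator's internal sampler
#'
#' Exposes the C++ truncated-normal sampler (rejection form, same
#' distribution as [sample_duration()]) for verification.
#'
#' @inheritParams sample_duration
#' @param seed RNG seed of the private stream.
#' @export
ibmc_sample_durations <- function(n, mean, sd, seed = 1, floor = 0.1) {
  stopifnot(n >= 1, mean > 0, sd >= 0)
  ibmc_cpp_sample_durations(as.numeric(n), mean, sd, as.numeric(seed), floor)
}

#' Plot an agent snapshot
#'
#' Positions coloured by class: green healthy, orange incubating, red
#' infectious, blue immune, grey dead; vaccinated agents (cyan ring) are an
#' overlay, not a sixth exclusive class.
#'
#' @param x [init_population()] result.
#' @param L system size (for axes); taken from the data range if missing.
#' @param ... passed to [graphics::plot()].
#' @export
plot_population <- function(x, L = NULL, ...) {
  stopifnot(inherits(x, "ibmc_population"))
  if (is.null(L)) L <- max(x$x, x$y)
  cols <- c("forestgreen", "orange", "red", "blue", "grey40")[x$state + 1L]
  graphics::plot(x$x, x$y, col = cols, pch = 16, cex = 0.5,
                 xlim = c(0, L), ylim = c(0, L), asp = 1,
                 xlab = "x (m)", ylab = "y (m)", ...)
  vac <- x$vaccinated == 1
  if (any(vac)) graphics::points(x$x[vac], x$y[vac], col = "cyan3",
                                 pch = 1, cex = 0.7)
  invisible(x)
}

#' Plot class fractions over time
#'
#' @param x [ibmc_run()] trajectory.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_trajectory <- function(x, ...) {
  stopifnot(inherits(x, "ibmc_trajectory"))
  classes <- c("healthy", "incubating", "infectious", "immune", "dead",
               "vaccinated")
  cols <- c("forestgreen", "orange", "red", "blue", "grey40", "cyan3")
  graphics::matplot(x$time, as.matrix(x[classes]), type = "l", lty = 1,
                    col = cols, xlab = "time (days)",
                    ylab = "population fraction", ...)
  graphics::legend("topright", legend = classes, col = cols, lty = 1,
                   cex = 0.8, bty = "n")
  invisible(x)
}
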