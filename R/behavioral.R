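#' Behavioural SIR model with Fermi-rule strategy imitation
#'
#' The population is split by epidemiological state and by vaccination
#' strategy into five compartments: susceptible vaccinators and delayers
#' (`S_V`, `S_U`), infected vaccinators and delayers (`I_V`, `I_U`), and the
#' recovered pool `R`.  Transmission within a strategy group runs at `beta_V`
#' or `beta_U` (`beta_V < beta_U`: vaccinators are harder to infect) and
#' across groups at the cross rate `beta_c = c (beta_V + beta_U) / 2`.
#' Individuals imitate more successful strategies at a rate given by the
#' Fermi rule [fermi()] applied to the game payoffs (`pi_V = -r_v`,
#' `pi_U = -r_i beta_U I`), with coupling constant `zeta` setting how fast
#' behaviour responds to epidemiological information:
#'
#'   dS_U/dt = -S_U (beta_U I_U + beta_c I_V) + zeta Phi_S
#'   dS_V/dt = -S_V (beta_c I_U + beta_V I_V) - zeta Phi_S
#'   dI_U/dt =  S_U (beta_U I_U + beta_c I_V) - gamma I_U + zeta Phi_I
#'   dI_V/dt =  S_V (beta_c I_U + beta_V I_V) - gamma I_V - zeta Phi_I
#'   dR/dt   =  gamma (I_U + I_V)
#'
#' The recovery equation is written in the mass-conserving form; the
#' `use_printed_recovery` switch reproduces the non-conserving variant
#' `dR/dt = gamma (I_U - I_V)` for comparison (R is decoupled, so S and I
#' trajectories are unaffected).
#'
#' @name behavioral-sir
NULL

#' Parameters of the behavioural SIR model
#'
#' Defaults are the normative-scenario constants: `r_v = 1`, `r_i = 10`,
#' `zeta = 1`, `gamma = 1.25`, `beta_V = 1`, `beta_U = 10`, `k = 0.5`,
#' `c = 0.1`, `I0 = 0.01`.  The initial vaccinator share `V0` defaults to
#' the mixed-ESS probability `p_star(R0, r_v/r_i)` of the matching scenario
#' (`R0 = 10`); both infected and susceptible mass are split between the
#' strategies in proportion `V0 : 1 - V0`.
#'
#' @param r_v perceived vaccine risk.
#' @param r_i perceived infection risk.
#' @param zeta coupling constant between epidemic state and imitation
#'   dynamics (0 freezes strategies).
#' @param gamma recovery rate (per unit time).
#' @param beta_V,beta_U within-strategy infection rates (`beta_V <= beta_U`).
#' @param k Fermi irrationality (noise) parameter, > 0.
#' @param c cross-infection parameter in `(0, 1)`; the cross rate is
#'   `beta_c = c (beta_V + beta_U)/2`.
#' @param I0 initial infected fraction.
#' @param V0 initial vaccinator share; `NULL` uses `p_star(R0, r_v/r_i)`
#'   (0 when no ESS exists).
#' @param R0 scenario basic reproduction number used only for the `V0`
#'   default.
#' @param use_printed_recovery use the non-conserving recovery equation.
#' @return object of class `behavioral_params`.
#' @export
behavioral_params <- function(r_v = 1, r_i = 10, zeta = 1, gamma = 1.25,
                              beta_V = 1, beta_U = 10, k = 0.5, c = 0.1,
                              I0 = 0.01, V0 = NULL, R0 = 10,
                              use_printed_recovery = FALSE) {
  stopifnot(r_v >= 0, r_i >= 0, zeta >= 0, gamma > 0,
            beta_V >= 0, beta_U >= 0, k > 0, c >= 0, c <= 1,
            I0 >= 0, I0 <= 1, R0 > 0)
  if (is.null(V0)) {
    r <- if (r_i > 0) r_v / r_i else Inf
    V0 <- if (is.finite(r) && ess_exists(R0, r)) p_star(R0, r) else 0
  }
  stopifnot(V0 >= 0, V0 <= 1)
  p <- list(r_v = r_v, r_i = r_i, zeta = zeta, gamma = gamma,
            beta_V = beta_V, beta_U = beta_U, k = k, c = c,
            beta_c = c * (beta_V + beta_U) / 2,
            I0 = I0, V0 = V0, R0 = R0,
            use_printed_recovery = isTRUE(use_printed_recovery))
  class(p) <- "behavioral_params"
  p
}

#' Fermi (logistic) strategy-switching probability
#'
#' Probability that an individual with payoff `pi_i` imitates a partner with
#' payoff `pi_j`: `1 / (1 + exp(-(pi_j - pi_i)/k))`.  Satisfies
#' `fermi(a, b, k) + fermi(b, a, k) == 1`.
#'
#' @param pi_i focal payoff.
#' @param pi_j partner payoff.
#' @param k irrationality parameter, > 0.
#' @export
#' @examples
#' fermi(0, 1, 0.5)   # strongly tempted to imitate the better payoff
fermi <- function(pi_i, pi_j, k) {
  if (any(k <= 0)) stop("`k` must be positive")
  1 / (1 + exp(-(pi_j - pi_i) / k))
}

#' Instantaneous strategy payoffs
#'
#' @param state named vector or list with `S_V`, `S_U`, `I_V`, `I_U`, `R`.
#' @param params [behavioral_params()].
#' @return `c(pi_V, pi_U)` with `pi_V = -r_v` and
#'   `pi_U = -r_i beta_U (I_V + I_U)`.
#' @export
strategy_payoffs <- function(state, params) {
  I <- state[["I_V"]] + state[["I_U"]]
  c(pi_V = -params$r_v, pi_U = -params$r_i * params$beta_U * I)
}

#' Net strategy-conversion fluxes
#'
#' `Phi_S` and `Phi_I` are the net rates at which susceptible and infected
#' mass flows from the vaccinator to the delayer strategy (positive values
#' mean V -> U conversion).
#'
#' @inheritParams strategy_payoffs
#' @return `c(Phi_S, Phi_I)`.
#' @export
strategy_fluxes <- function(state, params) {
  S_V <- state[["S_V"]]; S_U <- state[["S_U"]]
  I_V <- state[["I_V"]]; I_U <- state[["I_U"]]
  pis <- strategy_payoffs(state, params)
  t_vu <- fermi(pis[["pi_V"]], pis[["pi_U"]], params$k)  # V imitates U
  t_uv <- fermi(pis[["pi_U"]], pis[["pi_V"]], params$k)  # U imitates V
  c(
    Phi_S = S_V * (S_U + I_U) * t_vu - S_U * (S_V + I_V) * t_uv,
    Phi_I = I_V * (S_U + I_U) * t_vu - I_U * (S_V + I_V) * t_uv
  )
}

#' Right-hand side of the behavioural SIR model
#'
#' @inheritParams strategy_payoffs
#' @return named derivative vector over `(S_V, S_U, I_V, I_U, R)`; sums to
#'   zero under the conserving recovery equation.
#' @export
behavioral_rhs <- function(state, params) {
  S_V <- state[["S_V"]]; S_U <- state[["S_U"]]
  I_V <- state[["I_V"]]; I_U <- state[["I_U"]]
  ph <- strategy_fluxes(state, params)
  lam_U <- params$beta_U * I_U + params$beta_c * I_V
  lam_V <- params$beta_c * I_U + params$beta_V * I_V
  dR <- if (params$use_printed_recovery) params$gamma * (I_U - I_V)
        else params$gamma * (I_U + I_V)
  c(
    S_V = -S_V * lam_V - params$zeta * ph[["Phi_S"]],
    S_U = -S_U * lam_U + params$zeta * ph[["Phi_S"]],
    I_V = S_V * lam_V - params$gamma * I_V - params$zeta * ph[["Phi_I"]],
    I_U = S_U * lam_U - params$gamma * I_U + params$zeta * ph[["Phi_I"]],
    R = dR
  )
}

#' Integrate the behavioural SIR model
#'
#' @param params [behavioral_params()].
#' @param horizon integration horizon (time units of the model rates).
#' @param dt reporting grid spacing.
#' @param rtol,atol integrator tolerances (lsoda).
#' @param prominence,min_separation peak-detection settings passed to
#'   [find_peaks()].
#' @return object of class `behavioral_trajectory`: a data frame with the
#'   five compartments plus derived series `I = I_V + I_U`, `S = S_V + S_U`
#'   and the vaccinator ratio `V = (S_V + I_V)/(S + I)`; attributes `I_max`
#'   (quadratically refined peak of `I`), `peaks` (data frame of detected
#'   peaks of `I`), `mass_error` and `params`.
#' @export
run_behavioral <- function(params, horizon = 100, dt = 0.01,
                           rtol = 1e-10, atol = 1e-12,
                           prominence = 1e-4, min_separation = 5) {
  stopifnot(inherits(params, "behavioral_params"), horizon > 0, dt > 0)
  S0 <- 1 - params$I0
  y0 <- c(S_V = params$V0 * S0, S_U = (1 - params$V0) * S0,
          I_V = params$V0 * params$I0, I_U = (1 - params$V0) * params$I0,
          R = 0)
  deriv <- function(t, y, parms) {
    d <- behavioral_rhs(y, params)
    if (any(!is.finite(d))) stop("behavioural SIR integration blew up (non-finite derivative)")
    list(d)
  }
  out <- deSolve::ode(y = y0, times = seq(0, horizon, by = dt), func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (any(!is.finite(out))) stop("behavioural SIR integration blew up (non-finite state)")
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  df$I <- df$I_V + df$I_U
  df$S <- df$S_V + df$S_U
  denom <- df$S + df$I
  df$V <- ifelse(denom > 0, (df$S_V + df$I_V) / denom, NA_real_)
  pk <- find_peaks(df$time, df$I, prominence = prominence,
                   min_separation = min_separation)
  attr(df, "I_max") <- refined_max(df$time, df$I)
  attr(df, "peaks") <- pk
  attr(df, "mass_error") <- if (params$use_printed_recovery) NA_real_ else
    max(abs(df$S_V + df$S_U + df$I_V + df$I_U + df$R - 1))
  attr(df, "params") <- params
  class(df) <- c("behavioral_trajectory", class(df))
  df
}

# max of a smooth sampled series, refined by a local quadratic fit so the
# value is insensitive to the reporting grid
refined_max <- function(t, x) {
  i <- which.max(x)
  n <- length(x)
  if (i <= 1 || i >= n) return(x[i])
  # Lagrange quadratic through the three points around the max
  t0 <- t[i - 1]; t1 <- t[i]; t2 <- t[i + 1]
  y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
  d1 <- (y1 - y0) / (t1 - t0)
  d2 <- (y2 - y1) / (t2 - t1)
  a <- (d2 - d1) / (t2 - t0)        # half of second derivative
  if (a >= 0) return(y1)            # not locally concave; keep grid value
  tv <- ((t0 + t1) - d1 / a) / 2    # vertex: derivative of the parabola = 0
  yv <- y0 + d1 * (tv - t0) + a * (tv - t0) * (tv - t1)
  max(y1, yv)
}

#' Detect peaks of a sampled series
#'
#' Local maxima filtered by topographic prominence and a minimum separation
#' (taller peaks win ties).
#'
#' @param t time grid.
#' @param x series values.
#' @param prominence minimum prominence (drop to the highest saddle).
#' @param min_separation minimum spacing between reported peaks, in `t`
#'   units.
#' @return data frame with columns `time`, `height`, `prominence`.
#' @export
find_peaks <- function(t, x, prominence = 1e-4, min_separation = 5) {
  n <- length(x)
  if (n < 3) return(data.frame(time = numeric(), height = numeric(),
                               prominence = numeric()))
  # slope signs with plateaus carried forward, so flat-topped maxima count
  s <- sign(diff(x))
  for (i in which(s == 0)) if (i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) == -2) + 1L
  if (!length(idx)) return(data.frame(time = numeric(), height = numeric(),
                                      prominence = numeric()))
  prom <- vapply(idx, function(i) {
    h <- x[i]
    l <- i; while (l > 1 && x[l] <= h) l <- l - 1
    r <- i; while (r < n && x[r] <= h) r <- r + 1
    h - max(min(x[l:i]), min(x[i:r]))
  }, numeric(1))
  keep <- idx[prom >= prominence]
  promk <- prom[prom >= prominence]
  if (length(keep) > 1) {
    ord <- order(-x[keep])
    sel <- integer()
    for (j in ord) {
      if (!length(sel) || all(abs(t[keep[j]] - t[keep[sel]]) >= min_separation))
        sel <- c(sel, j)
    }
    sel <- sort(sel)
    keep <- keep[sel]; promk <- promk[sel]
  }
  data.frame(time = t[keep], height = x[keep], prominence = promk)
}

#' Check the strategy-share rate identity along a trajectory
#'
#' The pure strategy part of the vaccinator-share dynamics can be written
#' either through the fluxes (`-Phi_S - Phi_I`) or through the mean-field
#' two-strategy form `(1 - R)^2 V U [fermi(pi_U, pi_V) - fermi(pi_V, pi_U)]`;
#' the two are algebraically identical given the compartment definitions.
#' The realised rate of change of the vaccinator mass `S_V + I_V` differs
#' from the pure strategy part by the epidemic term `-gamma I_V` (recovery
#' removes infected vaccinators from the strategy-labelled pool).
#'
#' @param traj a [run_behavioral()] trajectory.
#' @param params the trajectory's parameters (defaults to the stored ones).
#' @param tol tolerance on the algebraic flux identity.
#' @return list with `max_identity_gap` (flux form vs mean-field form),
#'   `identity_ok`, `max_epidemic_gap` (finite-difference d(S_V+I_V)/dt vs
#'   the pure strategy rate) and the pointwise table.
#' @export
check_vdot_consistency <- function(traj, params = attr(traj, "params"),
                                   tol = 1e-10) {
  stopifnot(is.data.frame(traj))
  n <- nrow(traj)
  flux_form <- numeric(n); mf_form <- numeric(n)
  for (i in seq_len(n)) {
    st <- c(S_V = traj$S_V[i], S_U = traj$S_U[i],
            I_V = traj$I_V[i], I_U = traj$I_U[i], R = traj$R[i])
    ph <- strategy_fluxes(st, params)
    flux_form[i] <- -ph[["Phi_S"]] - ph[["Phi_I"]]
    pis <- strategy_payoffs(st, params)
    Vm <- st[["S_V"]] + st[["I_V"]]; Um <- st[["S_U"]] + st[["I_U"]]
    tot <- Vm + Um
    V <- if (tot > 0) Vm / tot else 0
    U <- 1 - V
    mf_form[i] <- (1 - st[["R"]])^2 * V * U *
      (fermi(pis[["pi_U"]], pis[["pi_V"]], params$k) -
         fermi(pis[["pi_V"]], pis[["pi_U"]], params$k))
  }
  mass_V <- traj$S_V + traj$I_V
  dmass <- c(NA, diff(mass_V) / diff(traj$time))
  strategy_rate <- params$zeta * flux_form
  gap <- abs(dmass[-1] - strategy_rate[-1])
  list(
    max_identity_gap = max(abs(flux_form - mf_form)),
    identity_ok = max(abs(flux_form - mf_form)) <= tol,
    max_epidemic_gap = max(gap),
    table = data.frame(time = traj$time, flux_form = flux_form,
                       mean_field_form = mf_form,
                       d_mass_V = dmass,
                       epidemic_term = -params$gamma * traj$I_V)
  )
}

#' Oscillation structure across the behaviour-epidemiology coupling
#'
#' Integrates the model along a grid of coupling constants `zeta` and reports
#' the number of detected infection peaks and the maximum peak height: faster
#' behavioural response splits the epidemic into more, comparably tall waves.
#'
#' @param params base [behavioral_params()].
#' @param zeta_grid coupling constants to scan.
#' @param horizon integration horizon.
#' @param ... further arguments for [run_behavioral()].
#' @return data frame with columns `zeta`, `n_peaks`, `I_max`.
#' @export
sweep_zeta <- function(params, zeta_grid = c(0.5, 1, 2, 4), horizon = 300,
                       ...) {
  stopifnot(length(zeta_grid) >= 1)
  rows <- lapply(zeta_grid, function(z) {
    p <- params; p$zeta <- z
    tr <- run_behavioral(p, horizon = horizon, ...)
    data.frame(zeta = z, n_peaks = nrow(attr(tr, "peaks")),
               I_max = attr(tr, "I_max"))
  })
  do.call(rbind, rows)
}

#' Peak infection across perceived risk and transmissibility
#'
#' Scans the perceived infection risk `r_i` and the unvaccinated-group
#' infection rate `beta_U`.  By default the initial vaccinator share tracks
#' the scenario's ESS (`V0 = p_star(R0, r_v/r_i)`, 0 where no ESS exists),
#' mirroring how each risk scenario would be initialised on its own; set
#' `track_V0 = FALSE` to hold `V0` at the base value.
#'
#' @param params base [behavioral_params()].
#' @param ri_grid perceived infection risks to scan.
#' @param betaU_grid unvaccinated infection rates to scan.
#' @param horizon integration horizon.
#' @param track_V0 recompute `V0` per grid cell from the ESS.
#' @param ... further arguments for [run_behavioral()].
#' @return data frame with columns `r_i`, `beta_U`, `V0`, `I_max`,
#'   `first_peak` (height of the earliest detected peak, NA if none).
#' @export
sweep_risk <- function(params, ri_grid = c(0, 3, 5, 10), betaU_grid = NULL,
                       horizon = 300, track_V0 = TRUE, ...) {
  if (is.null(betaU_grid)) betaU_grid <- params$beta_U
  stopifnot(length(ri_grid) >= 1, length(betaU_grid) >= 1)
  rows <- list()
  for (bu in betaU_grid) for (ri in ri_grid) {
    p <- behavioral_params(
      r_v = params$r_v, r_i = ri, zeta = params$zeta, gamma = params$gamma,
      beta_V = params$beta_V, beta_U = bu, k = params$k, c = params$c,
      I0 = params$I0, R0 = params$R0,
      V0 = if (track_V0) NULL else params$V0,
      use_printed_recovery = params$use_printed_recovery)
    tr <- run_behavioral(p, horizon = horizon, ...)
    pk <- attr(tr, "peaks")
    rows[[length(rows) + 1L]] <- data.frame(
      r_i = ri, beta_U = bu, V0 = p$V0, I_max = attr(tr, "I_max"),
      first_peak = if (nrow(pk)) pk$height[which.min(pk$time)] else NA_real_)
  }
  do.call(rbind, rows)
}

#' @export
print.behavioral_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat("Behavioural SIR trajectory:", nrow(x), "points over t in [0,",
      max(x$time), "]\n")
  cat(sprintf("  I_max = %.6g; %d infection peak(s); mass error %.2g\n",
              attr(x, "I_max"), nrow(attr(x, "peaks")),
              attr(x, "mass_error")))
  cat(sprintf("  r = %.3g, zeta = %.3g, beta_V = %.3g, beta_U = %.3g, V0 = %.3g\n",
              if (p$r_i > 0) p$r_v / p$r_i else Inf,
              p$zeta, p$beta_V, p$beta_U, p$V0))
  invisible(x)
}
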