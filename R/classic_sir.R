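#' SIR model with vaccination at birth
#'
#' Dimensional form (fractions S, I, R, uptake theta, birth/death rate mu,
#' transmission beta, recovery gamma):
#'
#'   dS/dt = mu (1 - theta) - beta S I - mu S
#'   dI/dt = beta S I - gamma I - mu I
#'   dR/dt = mu theta + gamma I - mu R
#'
#' and the nondimensional form on the time scale delta = gamma t, with
#' `R0 = beta / (gamma + mu)` and `f = mu / gamma`:
#'
#'   dS/ddelta = f (1 - theta) - R0 (1 + f) S I - f S
#'   dI/ddelta = R0 (1 + f) S I - (1 + f) I
#'
#' The redundant R equation is carried explicitly and the S+I+R = 1 identity
#' is used as an integration-error monitor rather than eliminated.
#'
#' @name classic-sir
NULL

#' Parameters for the dimensional SIR-with-vaccination model
#'
#' @param mu average birth (= death) rate, 1/day.
#' @param beta average infection rate, 1/day.
#' @param gamma average recovery rate, 1/day.
#' @param theta vaccine uptake fraction in `[0, 1]`.
#' @return list with the rates plus the derived `R0 = beta/(gamma+mu)` and
#'   `f = mu/gamma`.
#' @export
classic_sir_params <- function(mu, beta, gamma, theta) {
  stopifnot(mu >= 0, beta >= 0, gamma > 0, theta >= 0, theta <= 1)
  list(mu = mu, beta = beta, gamma = gamma, theta = theta,
       R0 = beta / (gamma + mu), f = mu / gamma)
}

#' Right-hand side of the dimensional SIR-with-vaccination ODE
#'
#' @param state numeric vector `c(S, I, R)` of population fractions.
#' @param params list from [classic_sir_params()].
#' @return derivatives `c(dS, dI, dR)` (they sum to zero).
#' @export
classic_sir_rhs <- function(state, params) {
  S <- state[[1]]; I <- state[[2]]; R <- state[[3]]
  with(params, c(
    mu * (1 - theta) - beta * S * I - mu * S,
    beta * S * I - gamma * I - mu * I,
    mu * theta + gamma * I - mu * R
  ))
}

#' Right-hand side of the nondimensional SIR-with-vaccination ODE
#'
#' Time is measured in units of the mean recovery time (`delta = gamma t`).
#'
#' @param state numeric vector `c(S, I, R)`.
#' @param R0 basic reproduction number.
#' @param f demographic ratio `mu / gamma`.
#' @param theta vaccine uptake fraction.
#' @return derivatives with respect to delta, `c(dS, dI, dR)`.
#' @export
classic_sir_rhs_nondim <- function(state, R0, f, theta) {
  S <- state[[1]]; I <- state[[2]]; R <- state[[3]]
  c(
    f * (1 - theta) - R0 * (1 + f) * S * I - f * S,
    R0 * (1 + f) * S * I - (1 + f) * I,
    f * theta + I - f * R
  )
}

#' Integrate the nondimensional SIR-with-vaccination model
#'
#' @inheritParams classic_sir_rhs_nondim
#' @param init initial `c(S, I, R)`; defaults to `c(1 - I0, I0, 0)`.
#' @param I0 initial infected fraction used when `init` is missing.
#' @param horizon integration horizon in recovery-time units.
#' @param dt reporting grid spacing.
#' @param rtol,atol integrator tolerances (lsoda).
#' @return data frame with columns `delta`, `S`, `I`, `R` and attribute
#'   `mass_error` (max |S+I+R-1| along the trajectory).
#' @export
run_classic_sir <- function(R0, f, theta, init = NULL, I0 = 0.01,
                            horizon = 500, dt = 0.1,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(horizon > 0)
  if (is.null(init)) init <- c(S = 1 - I0, I = I0, R = 0)
  names(init) <- c("S", "I", "R")
  deriv <- function(t, y, parms) {
    d <- classic_sir_rhs_nondim(y, R0, f, theta)
    if (any(!is.finite(d))) stop("classic SIR integration blew up (non-finite derivative)")
    list(d)
  }
  out <- deSolve::ode(y = init, times = seq(0, horizon, by = dt), func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (any(!is.finite(out))) stop("classic SIR integration blew up (non-finite state)")
  df <- as.data.frame(out)
  names(df)[1] <- "delta"
  attr(df, "mass_error") <- max(abs(df$S + df$I + df$R - 1))
  df
}

#' Integrate the nondimensional model to a steady state
#'
#' Integrates in chunks until the derivative norm stays below `tol` for 10
#' consecutive checkpoints (or the horizon is exhausted, in which case the
#' result is flagged as non-converged).
#'
#' @inheritParams run_classic_sir
#' @param tol steady-state declaration threshold on `max(abs(derivative))`.
#' @param chunk chunk length between checkpoints, in recovery-time units.
#' @return list with `state` (named `S`, `I`, `R`), `converged`, `delta`
#'   (time reached) and `deriv_norm`.
#' @export
integrate_to_steady <- function(R0, f, theta, init = NULL, I0 = 0.01,
                                horizon = 1e5, tol = 1e-9, chunk = 50,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(horizon > 0)
  if (is.null(init)) init <- c(S = 1 - I0, I = I0, R = 0)
  names(init) <- c("S", "I", "R")
  y <- init
  t_now <- 0
  hits <- 0L
  deriv <- function(t, y, parms) {
    d <- classic_sir_rhs_nondim(y, R0, f, theta)
    if (any(!is.finite(d))) stop("classic SIR integration blew up (non-finite derivative)")
    list(d)
  }
  dn <- max(abs(classic_sir_rhs_nondim(y, R0, f, theta)))
  while (t_now < horizon) {
    out <- deSolve::ode(y = y, times = c(t_now, t_now + chunk), func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    y <- out[nrow(out), c("S", "I", "R")]
    if (any(!is.finite(y))) stop("classic SIR integration blew up")
    t_now <- t_now + chunk
    dn <- max(abs(classic_sir_rhs_nondim(y, R0, f, theta)))
    hits <- if (dn < tol) hits + 1L else 0L
    if (hits >= 10L) break
  }
  list(state = y, converged = hits >= 10L, delta = t_now, deriv_norm = dn)
}
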