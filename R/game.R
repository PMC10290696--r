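#' Closed-form vaccination game
#'
#' Payoff structure of the voluntary-vaccination game: an individual either
#' vaccinates (strategy V, payoff `-r_v`) or delays and free-rides on herd
#' immunity (strategy U, payoff `-r_i * beta_U * I` at infected prevalence
#' `I`).  With the relative perceived risk `r = r_v / r_i` the game admits a
#' mixed evolutionarily stable strategy `P*` whenever `R0 * (1 - r) > 1`, and
#' `P*` always falls short of the herd-immunity coverage
#' `theta_crit = 1 - 1/R0` for `r > 0` -- the free-rider gap that the
#' behavioural dynamics in [run_behavioral()] explore over time.
#'
#' @name vaccination-game
NULL

round2 <- function(x) floor(x * 100 + 0.5) / 100  # round-half-up, 2 dp

#' Payoff of a vaccinated individual
#'
#' @param r_v perceived risk of vaccination (payoff units, >= 0).
#' @return `-r_v`.
#' @export
#' @examples
#' payoff_vaccinated(1)   # Methods default r_v = 1
payoff_vaccinated <- function(r_v) {
  stopifnot(is.numeric(r_v), all(r_v >= 0))
  -r_v
}

#' Payoff of an unvaccinated (delaying) individual
#'
#' The delayer's expected loss scales with the infection rate of the
#' unvaccinated group and the current infected prevalence.
#'
#' @param r_i perceived risk of infection (>= 0).
#' @param beta_U infection rate of the unvaccinated group (>= 0).
#' @param I infected fraction in `[0, 1]`.
#' @return `-r_i * beta_U * I`.
#' @export
payoff_unvaccinated <- function(r_i, beta_U, I) {
  stopifnot(all(r_i >= 0), all(beta_U >= 0), all(I >= 0), all(I <= 1))
  -r_i * beta_U * I
}

#' Average expected payoff of a mixed strategy
#'
#' An individual vaccinating with probability `P` earns
#' `E = -r P - beta_U I (1 - P)` (payoffs rescaled by `r_i`, with
#' `r = r_v / r_i`).
#'
#' @param P vaccination probability in `[0, 1]`.
#' @param r relative perceived risk `r_v / r_i`.
#' @param beta_U infection rate of the unvaccinated group.
#' @param I infected fraction.
#' @export
expected_payoff <- function(P, r, beta_U, I) {
  stopifnot(all(P >= 0), all(P <= 1))
  -r * P - beta_U * I * (1 - P)
}

#' Payoff gain of strategy V over strategy U
#'
#' `Delta E = (beta_U I - r)(V - U)`: positive values attract individuals
#' toward vaccination, negative values toward delaying; the sign flips on the
#' indifference line `beta_U I = r`.
#'
#' @param beta_U infection rate of the unvaccinated group.
#' @param I infected fraction.
#' @param r relative perceived risk.
#' @param V,U strategy shares in `[0, 1]`.
#' @export
payoff_gain <- function(beta_U, I, r, V, U) {
  stopifnot(all(V >= 0), all(V <= 1), all(U >= 0), all(U <= 1))
  (beta_U * I - r) * (V - U)
}

#' Population vaccination coverage
#'
#' A focal share `epsilon` of the population vaccinates with probability `P`,
#' the rest with probability `Q`.
#'
#' @param epsilon focal population share in `[0, 1]`.
#' @param P,Q vaccination probabilities in `[0, 1]`.
#' @return coverage `theta = epsilon P + (1 - epsilon) Q`.
#' @export
coverage <- function(epsilon, P, Q) {
  stopifnot(all(epsilon >= 0), all(epsilon <= 1),
            all(P >= 0), all(P <= 1), all(Q >= 0), all(Q <= 1))
  epsilon * P + (1 - epsilon) * Q
}

#' Critical vaccination coverage (herd-immunity threshold)
#'
#' @param R0 basic reproduction number (> 0).
#' @return `0` when `R0 < 1`, else `1 - 1/R0`.
#' @export
#' @examples
#' theta_crit(c(5, 10, 15, 20))
theta_crit <- function(R0) {
  stopifnot(is.numeric(R0), all(R0 > 0))
  ifelse(R0 < 1, 0, 1 - 1 / R0)
}

#' Endemic force of infection on an unvaccinated individual
#'
#' At the endemic steady state with coverage `theta`, the probability pressure
#' `beta_U I` felt by a delayer reduces to `1 - 1/(R0 (1 - theta))`, clamped
#' at zero in the disease-free regime.
#'
#' @param R0 basic reproduction number.
#' @param theta coverage in `[0, 1)`.
#' @export
force_of_infection_U <- function(R0, theta) {
  stopifnot(all(R0 > 0), all(theta >= 0))
  if (any(theta >= 1)) stop("`theta` must be below 1 (everyone vaccinated leaves no unvaccinated group)")
  pmax(0, 1 - 1 / (R0 * (1 - theta)))
}

#' Does a mixed evolutionarily stable strategy exist?
#'
#' @param R0 basic reproduction number.
#' @param r relative perceived risk (>= 0).
#' @return `TRUE` iff `R0 (1 - r) > 1`.
#' @export
ess_exists <- function(R0, r) {
  stopifnot(all(R0 > 0), all(r >= 0))
  R0 * (1 - r) > 1
}

#' Mixed-ESS vaccination probability P*
#'
#' The self-interested (Nash) vaccination level: the coverage at which a
#' delayer's endemic infection pressure exactly equals the relative vaccine
#' risk, `P* = 1 - 1/(R0 (1 - r))`.  `P*` is only defined when
#' [ess_exists()]; the no-ESS case returns `NA` (with a warning) rather than
#' a silently clamped zero.
#'
#' @inheritParams ess_exists
#' @param strict error (rather than warn + `NA`) when no ESS exists.
#' @export
#' @examples
#' p_star(10, 0.1)                    # 0.889, the 89% headline coverage
#' round(p_star(c(5, 10, 15, 20), 0.1), 2)
p_star <- function(R0, r, strict = FALSE) {
  stopifnot(all(R0 > 0), all(r >= 0))
  ok <- ess_exists(R0, r)
  if (any(!ok)) {
    if (strict) stop("no mixed ESS: R0 * (1 - r) <= 1")
    warning("no mixed ESS for some inputs (R0 * (1 - r) <= 1); returning NA")
  }
  out <- 1 - 1 / (R0 * (1 - r))
  out[!ok] <- NA_real_
  out
}

#' Strategy switch point I'
#'
#' The infected prevalence at which vaccinating and delaying give equal
#' payoff: `I' = r_v / (r_i beta_U)`.  Above `I'` the expected payoff
#' increases with the vaccination probability; below it, delaying pays.
#'
#' @param r_v perceived vaccine risk.
#' @param r_i perceived infection risk (> 0).
#' @param beta_U infection rate of the unvaccinated group (> 0).
#' @export
switch_point <- function(r_v, r_i, beta_U) {
  stopifnot(all(r_v >= 0))
  if (any(r_i <= 0) || any(beta_U <= 0))
    stop("`r_i` and `beta_U` must be positive")
  r_v / (r_i * beta_U)
}

#' Endemic equilibrium of the SIR-with-vaccination model
#'
#' For uptake `P` below the critical coverage the system settles at
#' `S_hat = 1/R0`, `I_hat = f/(1+f) (theta_crit - P)`; at or above it, at the
#' disease-free state `(1 - P, 0)`.
#'
#' @param R0 basic reproduction number.
#' @param f demographic ratio `mu / gamma` (birth rate over recovery rate).
#' @param P vaccine uptake in `[0, 1]`.
#' @return list with `S_hat`, `I_hat` and the branch (`"endemic"` or
#'   `"disease_free"`).
#' @export
endemic_equilibrium <- function(R0, f, P) {
  stopifnot(R0 > 0, f >= 0, P >= 0, P <= 1)
  tc <- theta_crit(R0)
  if (P >= tc) {
    list(S_hat = 1 - P, I_hat = 0, branch = "disease_free")
  } else {
    list(S_hat = 1 / R0, I_hat = f / (1 + f) * (tc - P), branch = "endemic")
  }
}

#' Classify the epidemic regime at a given coverage
#'
#' Below `P*` society sits in the unsteady regime (coverage under even the
#' selfish equilibrium); between `P*` and `theta_crit` in the steady endemic
#' regime; at `theta_crit` or above the disease can be eradicated.  When no
#' ESS exists the unsteady/steady distinction collapses and classification
#' uses `theta_crit` alone.
#'
#' @inheritParams ess_exists
#' @param cov population coverage in `[0, 1]`.
#' @return one of `"unsteady"`, `"steady_endemic"`, `"eradicated"`.
#' @export
classify_regime <- function(R0, r, cov) {
  stopifnot(R0 > 0, r >= 0, cov >= 0, cov <= 1)
  tc <- theta_crit(R0)
  if (cov >= tc) return("eradicated")
  if (!ess_exists(R0, r)) return("unsteady")
  ps <- 1 - 1 / (R0 * (1 - r))
  if (cov >= ps) "steady_endemic" else "unsteady"
}

#' Critical coverage and ESS point across reproduction numbers
#'
#' Reproduces the reference table of `theta_crit` and `P*` (at a given `r`)
#' over a grid of basic reproduction numbers, rounded half-up to 2 decimals.
#'
#' @param R0 vector of basic reproduction numbers.
#' @param r relative perceived risk.
#' @return data frame with columns `R0`, `theta_crit`, `p_star`.
#' @export
#' @examples
#' game_table1()
game_table1 <- function(R0 = c(5, 10, 15, 20), r = 0.1) {
  data.frame(
    R0 = R0,
    theta_crit = round2(theta_crit(R0)),
    p_star = round2(p_star(R0, r))
  )
}

#' Full equilibrium report for one game setting
#'
#' @inheritParams ess_exists
#' @param cov population coverage (defaults to `P*` when it exists, else 0).
#' @param f demographic ratio `mu / gamma` used for the endemic infected
#'   fraction.
#' @return list with `theta_crit`, `p_star` (NA when absent), `ess_exists`,
#'   `regime`, `S_hat`, `I_hat`.
#' @export
equilibrium_report <- function(R0, r, cov = NULL, f = 0.01) {
  tc <- theta_crit(R0)
  ok <- ess_exists(R0, r)
  ps <- if (ok) 1 - 1 / (R0 * (1 - r)) else NA_real_
  if (is.null(cov)) cov <- if (ok) ps else 0
  eq <- endemic_equilibrium(R0, f, cov)
  list(theta_crit = tc, p_star = ps, ess_exists = ok,
       regime = classify_regime(R0, r, cov),
       S_hat = eq$S_hat, I_hat = eq$I_hat)
}
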