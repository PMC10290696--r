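#' Price of anarchy of voluntary vaccination
#'
#' The price of anarchy (PoA) compares the epidemic burden that selfish
#' (Nash-equilibrium) vaccination behaviour produces against the cooperative
#' system optimum: `PoA = I_max^NE / I_max^SO`, the ratio of peak infected
#' fractions of two behavioural-SIR runs that differ only in the group
#' infection rates.  The NE run keeps the free-rider advantage
#' (`beta_U > beta_V`); the SO reference sets `beta_U = beta_V` (everyone as
#' well protected as a vaccinator) with all behavioural machinery still
#' active.  PoA close to 1 means selfishness costs society little; large
#' values quantify the anarchy of free-riding.
#'
#' @name price-of-anarchy
NULL

#' Compute the price of anarchy for one scenario
#'
#' Runs the behavioural SIR model twice -- once with the given (NE)
#' parameters and once with `beta_U` lowered to `beta_V` (SO) -- and returns
#' the ratio of refined peak infected fractions.
#'
#' @param params NE scenario, a [behavioral_params()] object.
#' @param horizon integration horizon for both runs.
#' @param ... further arguments passed to [run_behavioral()].
#' @return object of class `poa_result`: list with `r`, `I_max_NE`,
#'   `I_max_SO`, `poa` (NA with `degenerate_SO = TRUE` if the SO run never
#'   has any infection), and `regime` of the NE scenario at coverage `V0`.
#' @export
#' @examples
#' \donttest{
#' compute_poa(behavioral_params(r_v = 0.8))  # r = 0.08 scenario
#' }
compute_poa <- function(params, horizon = 300, ...) {
  stopifnot(inherits(params, "behavioral_params"))
  ne <- run_behavioral(params, horizon = horizon, ...)
  so_params <- params
  so_params$beta_U <- params$beta_V
  so_params$beta_c <- params$c * (params$beta_V + so_params$beta_U) / 2
  so <- run_behavioral(so_params, horizon = horizon, ...)
  i_ne <- attr(ne, "I_max")
  i_so <- attr(so, "I_max")
  r <- if (params$r_i > 0) params$r_v / params$r_i else Inf
  res <- list(
    r = r,
    I_max_NE = i_ne,
    I_max_SO = i_so,
    poa = if (i_so > 0) i_ne / i_so else NA_real_,
    degenerate_SO = i_so <= 0,
    regime = if (is.finite(r))
      classify_regime(params$R0, r, params$V0) else "unsteady"
  )
  class(res) <- "poa_result"
  res
}

#' @export
print.poa_result <- function(x, ...) {
  cat(sprintf("PoA = %.4f (I_max NE = %.5f, I_max SO = %.5f) at r = %.3g [%s]\n",
              x$poa, x$I_max_NE, x$I_max_SO, x$r, x$regime))
  invisible(x)
}

#' Sweep the price of anarchy over the relative risk
#'
#' The relative risk `r = r_v / r_i` is varied by holding `r_i` fixed and
#' setting `r_v = r * r_i`, keeping the payoff scale comparable to the
#' default scenario.  For each `r` the initial vaccinator share is the
#' scenario ESS `p_star(R0, r)` and [compute_poa()] is evaluated.  The sweep
#' also estimates the convergence point `r_star`: the largest grid value up
#' to which the PoA series (scanned from the smallest `r`) stays within
#' `rel_tol` of its neighbour, i.e. where the curve has levelled into its
#' steady (endemic-transition) value.
#'
#' @param r_grid relative risks to scan (positive, ESS-compatible).
#' @param base_params base scenario; `r_v` is overridden per grid point.
#' @param horizon integration horizon for each run.
#' @param rel_tol plateau-detection tolerance on successive PoA values.
#' @param ... further arguments for [run_behavioral()].
#' @return data frame with columns `r`, `I_max_NE`, `I_max_SO`, `poa`,
#'   `regime`; attributes `r_star` and `r_star_resolution` (the grid step).
#' @export
sweep_poa <- function(r_grid = seq(0.02, 0.30, by = 0.01),
                      base_params = behavioral_params(),
                      horizon = 300, rel_tol = 0.02, ...) {
  stopifnot(length(r_grid) >= 1, all(r_grid > 0))
  r_grid <- sort(r_grid)
  rows <- lapply(r_grid, function(r) {
    p <- behavioral_params(
      r_v = r * base_params$r_i, r_i = base_params$r_i,
      zeta = base_params$zeta, gamma = base_params$gamma,
      beta_V = base_params$beta_V, beta_U = base_params$beta_U,
      k = base_params$k, c = base_params$c, I0 = base_params$I0,
      R0 = base_params$R0, use_printed_recovery = base_params$use_printed_recovery)
    res <- compute_poa(p, horizon = horizon, ...)
    data.frame(r = r, I_max_NE = res$I_max_NE, I_max_SO = res$I_max_SO,
               poa = res$poa, regime = res$regime)
  })
  out <- do.call(rbind, rows)
  r_star <- out$r[1]
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      if (abs(out$poa[i] - out$poa[i - 1]) <= rel_tol * abs(out$poa[i])) {
        r_star <- out$r[i]
      } else break
    }
  }
  attr(out, "r_star") <- r_star
  attr(out, "r_star_resolution") <- if (length(r_grid) > 1)
    stats::median(diff(r_grid)) else NA_real_
  out
}
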