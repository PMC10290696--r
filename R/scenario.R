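#' Scenario configuration and reporting
#'
#' A scenario is a YAML file with a global `seed`, an optional `out_dir`,
#' and one section per analysis (`ibmc`, `game`, `sir`, `behavioral`,
#' `poa`).  Unknown keys are rejected so typos fail loudly.  Every stochastic
#' artifact embeds its seed; re-running a config reproduces it byte for
#' byte.  Time series are written as CSV, summaries as JSON, figures
#' (optional) as PNG.
#'
#' @name scenario
NULL

scenario_schema <- list(
  top = c("seed", "out_dir", "ibmc", "game", "sir", "behavioral", "poa"),
  ibmc = c("N", "L", "r_infect", "p_infect", "p_fatal", "p_vacc",
           "t_incubation", "t_infect", "t_vacc", "t_infect_immune",
           "t_vacc_immune", "tau", "delta_R", "t_end", "infection_mode",
           "revaccinate_on_waning", "n_reps", "record_stride", "sweep_grid",
           "snapshot_png"),
  game = c("R0", "r", "coverage", "f", "table1"),
  sir = c("R0", "f", "theta", "I0", "horizon", "dt"),
  behavioral = c("r_v", "r_i", "zeta", "gamma", "beta_V", "beta_U", "k", "c",
                 "I0", "V0", "R0", "use_printed_recovery", "horizon", "dt",
                 "zeta_grid", "ri_grid", "betaU_grid"),
  poa = c("r_grid", "r_v", "r_i", "zeta", "gamma", "beta_V", "beta_U", "k",
          "c", "I0", "R0", "horizon")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
  x
}

take <- function(cfg, defaults) {
  for (nm in intersect(names(cfg), names(defaults))) defaults[[nm]] <- cfg[[nm]]
  defaults
}

provenance <- function(seed, params) {
  list(seed = seed, package = "vaxgame",
       version = as.character(utils::packageVersion("vaxgame")),
       params = params)
}

write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read and validate a scenario configuration
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # keep short keys like "N" as strings (YAML 1.1 would read them as
  # booleans); boolean values must be spelled true/false
  keep_key <- function(v) {
    if (tolower(v) == "true") TRUE
    else if (tolower(v) == "false") FALSE
    else v
  }
  cfg <- yaml::yaml.load_file(path, handlers = list("bool#yes" = keep_key,
                                                    "bool#no" = keep_key))
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  check_keys(cfg, scenario_schema$top, "config")
  for (sec in intersect(names(cfg), c("ibmc", "game", "sir", "behavioral", "poa")))
    check_keys(cfg[[sec]], scenario_schema[[sec]], sec)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

#' Run a scenario configuration
#'
#' Executes every section present in the config and writes its artifacts
#' (CSV time series, JSON summaries with a provenance block) into `out_dir`.
#'
#' @param config path to a YAML config, or a list from [read_scenario()].
#' @param out_dir output directory; overrides the config's `out_dir`
#'   (default `"."`).
#' @return invisible named list of the objects produced per section.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_scenario(config) else config
  if (is.null(out_dir)) out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  seed <- as.integer(cfg$seed)
  out <- list()

  if (!is.null(cfg$game)) {
    g <- cfg$game
    R0 <- g$R0 %||% c(5, 10, 15, 20)
    r <- g$r %||% 0.1
    tab <- game_table1(R0 = unlist(R0), r = r)
    utils::write.csv(tab, file.path(out_dir, "game_table1.csv"),
                     row.names = FALSE)
    rep1 <- equilibrium_report(R0 = utils::tail(unlist(R0), 1), r = r,
                               cov = g$coverage %||% NULL, f = g$f %||% 0.01)
    write_json_summary(c(rep1, provenance(seed, g)),
                       file.path(out_dir, "game_summary.json"))
    out$game <- tab
  }

  if (!is.null(cfg$sir)) {
    s <- cfg$sir
    tr <- run_classic_sir(R0 = s$R0 %||% 10, f = s$f %||% 0.01,
                          theta = s$theta %||% 0.5, I0 = s$I0 %||% 0.01,
                          horizon = s$horizon %||% 500, dt = s$dt %||% 0.1)
    utils::write.csv(tr, file.path(out_dir, "sir_trajectory.csv"),
                     row.names = FALSE)
    out$sir <- tr
  }

  if (!is.null(cfg$behavioral)) {
    b <- cfg$behavioral
    par_args <- take(b, list(r_v = 1, r_i = 10, zeta = 1, gamma = 1.25,
                             beta_V = 1, beta_U = 10, k = 0.5, c = 0.1,
                             I0 = 0.01, V0 = NULL, R0 = 10,
                             use_printed_recovery = FALSE))
    p <- do.call(behavioral_params, par_args)
    tr <- run_behavioral(p, horizon = b$horizon %||% 100, dt = b$dt %||% 0.01)
    utils::write.csv(as.data.frame(tr),
                     file.path(out_dir, "behavioral_trajectory.csv"),
                     row.names = FALSE)
    summ <- list(I_max = attr(tr, "I_max"),
                 peaks = attr(tr, "peaks"),
                 mass_error = attr(tr, "mass_error"))
    if (!is.null(b$zeta_grid)) {
      sz <- sweep_zeta(p, zeta_grid = unlist(b$zeta_grid),
                       horizon = b$horizon %||% 300)
      utils::write.csv(sz, file.path(out_dir, "behavioral_zeta_sweep.csv"),
                       row.names = FALSE)
      out$zeta_sweep <- sz
    }
    if (!is.null(b$ri_grid)) {
      sr <- sweep_risk(p, ri_grid = unlist(b$ri_grid),
                       betaU_grid = if (is.null(b$betaU_grid)) NULL
                                    else unlist(b$betaU_grid),
                       horizon = b$horizon %||% 300)
      utils::write.csv(sr, file.path(out_dir, "behavioral_risk_sweep.csv"),
                       row.names = FALSE)
      out$risk_sweep <- sr
    }
    write_json_summary(c(summ, provenance(seed, b)),
                       file.path(out_dir, "behavioral_summary.json"))
    out$behavioral <- tr
  }

  if (!is.null(cfg$poa)) {
    po <- cfg$poa
    base <- do.call(behavioral_params,
                    take(po, list(r_v = 1, r_i = 10, zeta = 1, gamma = 1.25,
                                  beta_V = 1, beta_U = 10, k = 0.5, c = 0.1,
                                  I0 = 0.01, R0 = 10)))
    grid <- unlist(po$r_grid %||% seq(0.02, 0.30, by = 0.01))
    sw <- sweep_poa(grid, base_params = base, horizon = po$horizon %||% 300)
    utils::write.csv(sw, file.path(out_dir, "poa_sweep.csv"),
                     row.names = FALSE)
    write_json_summary(c(list(r_star = attr(sw, "r_star"),
                              r_star_resolution = attr(sw, "r_star_resolution")),
                         provenance(seed, po)),
                       file.path(out_dir, "poa_summary.json"))
    out$poa <- sw
  }

  if (!is.null(cfg$ibmc)) {
    ib <- cfg$ibmc
    par_args <- take(ib, formals(ibmc_params)[
      setdiff(names(formals(ibmc_params)), "infection_mode")])
    par_args <- lapply(par_args, function(v) if (is.language(v)) eval(v) else v)
    if (!is.null(ib$infection_mode)) par_args$infection_mode <- ib$infection_mode
    p <- do.call(ibmc_params, par_args)
    if (!is.null(ib$sweep_grid)) {
      sw <- ibmc_sweep(p, p_vacc_grid = unlist(ib$sweep_grid),
                       n_reps = ib$n_reps %||% 10, base_seed = seed,
                       record_stride = ib$record_stride %||% 1)
      utils::write.csv(sw, file.path(out_dir, "ibmc_sweep.csv"),
                       row.names = FALSE)
      out$ibmc_sweep <- sw
    } else {
      n_reps <- ib$n_reps %||% 1
      if (n_reps > 1) {
        ens <- ibmc_ensemble(p, n_reps = n_reps, base_seed = seed,
                             record_stride = ib$record_stride %||% 1)
        long <- do.call(rbind, lapply(seq_along(ens$runs), function(k) {
          r <- ens$runs[[k]]
          cbind(as.data.frame(r), replicate = k)
        }))
        utils::write.csv(long, file.path(out_dir, "ibmc_trajectories.csv"),
                         row.names = FALSE)
        summ <- list(peak_infectious = ens$peak_infectious,
                     final_immune = ens$final_immune,
                     extinction_time = ens$extinction_time,
                     seeds = ens$seeds)
        write_json_summary(c(summ, provenance(seed, unclass(p))),
                           file.path(out_dir, "ibmc_summary.json"))
        out$ibmc <- ens
      } else {
        tr <- ibmc_run(p, seed = seed,
                       record_stride = ib$record_stride %||% 1)
        utils::write.csv(as.data.frame(tr),
                         file.path(out_dir, "ibmc_trajectory.csv"),
                         row.names = FALSE)
        summ <- list(peak_infectious = attr(tr, "peak_infectious"),
                     ever_infected = attr(tr, "ever_infected"),
                     extinction_time = attr(tr, "extinction_time"),
                     deaths = attr(tr, "n_dead"))
        write_json_summary(c(summ, provenance(seed, unclass(p))),
                           file.path(out_dir, "ibmc_summary.json"))
        if (isTRUE(ib$snapshot_png)) {
          grDevices::png(file.path(out_dir, "ibmc_snapshot.png"),
                         width = 700, height = 700)
          plot_population(tr_final_pop(p, seed), L = p$L)
          grDevices::dev.off()
        }
        out$ibmc <- tr
      }
    }
  }

  invisible(out)
}

# final population snapshot for the PNG export
tr_final_pop <- function(params, seed) {
  res <- ibmc_cpp_run(params, as.numeric(seed), params$t_end)
  fin <- res$final
  class(fin) <- "ibmc_population"
  fin
}

`%||%` <- function(a, b) if (is.null(a)) b else a
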