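# Orchestration of the coupled loop: grow -> relax -> probe -> reorient ->
# elongate -> convert, plus ensembles and parameter sweeps.

#' Run one coupled folding + pathfinding simulation
#'
#' Advances dimensionless time `T = G_ctx * t` from 0 to 1.  Between agent
#' updates the bilayer is relaxed by `substeps` explicit increments while
#' the growth multipliers advance at the region rates; at each agent step
#' every growing bundle receives angle noise, reorients toward the maximum
#' tensile principal stress of its element when that stress is tensile and
#' non-degenerate, elongates by the tip + towed growth law, converts the
#' ECM elements its new segment traverses into fiber elements, and settles
#' when it crosses the cortex-white-matter interface.
#'
#' @param config a [simulation_config()]
#' @param seed overrides `config$seed` when given
#' @return object of class `foldax_result`: reference `mesh`, final nodal
#'   displacements `u`, per-element `elem_region` and `elem_mu`, Gauss-point
#'   stresses, agent `trajectories` (one row per agent per step), final
#'   `agents` table, per-step `series` (time, energies, KE/IE ratio, V_f,
#'   GI, counts), the resolved `config`, and `flags`
#' @export
run_simulation <- function(config, seed = NULL) {
  validate_config(config)
  config <- resolve_config(config)
  if (!is.null(seed)) config$seed <- seed
  mesh <- build_bilayer_mesh(config$w, config$h, config$t_c, config$elem_size)
  raw <- cpp_run(config[c("w", "h", "t_c", "elem_size", "perturb", "mu_s",
                          "mu_c_over_mu_s", "mu_f_over_mu_s", "k_over_mu",
                          "G_ctx", "growth_ratio", "growth_kinetics",
                          "agent_steps", "substeps", "cfl", "damping",
                          "n_fibers", "seed", "t_star", "noise_std",
                          "G_axn", "a", "sigma_0", "seed_band",
                          "reorientation_enabled", "clamp_negative_growth",
                          "degenerate_tol")])
  if (raw$aborted)
    warning(sprintf("run aborted at t = %g day (%s%s); partial outputs returned",
                    raw$t, raw$abort_reason,
                    if (raw$abort_reason == "element_inversion")
                      sprintf(", element %d", raw$abort_elem) else ""))
  ns <- raw$steps_done
  series <- as.data.frame(raw$series[seq_len(ns), , drop = FALSE])
  names(series) <- c("t", "T", "kinetic", "internal", "energy_ratio", "V_f",
                     "n_fiber_elems", "n_settled", "n_stalled", "theta_ctx")
  # GI time series from the recorded pial line
  series$GI <- vapply(seq_len(ns), function(k)
    gyrification_index(cbind(raw$pial_x[k, ], raw$pial_y[k, ])), numeric(1))
  series$equivalent_stiffness <- series$V_f * config$mu_f_over_mu_s +
    (1 - series$V_f)

  traj <- as.data.frame(raw$trajectories)
  if (nrow(traj)) {
    names(traj) <- c("id", "step", "x", "y", "theta", "sigma", "status_code")
    traj <- traj[traj$step <= ns, , drop = FALSE]
    traj$status <- factor(c("growing", "settled", "stalled")[traj$status_code + 1],
                          levels = c("growing", "settled", "stalled"))
  } else {
    traj <- data.frame(id = integer(), step = integer(), x = numeric(),
                       y = numeric(), theta = numeric(), sigma = numeric(),
                       status_code = numeric(), status = factor(levels =
                         c("growing", "settled", "stalled")))
  }
  elem_region <- factor(c("ecm", "cortex", "fiber")[raw$elem_region + 1],
                        levels = c("cortex", "ecm", "fiber"))
  agents <- if (config$n_fibers > 0) {
    a <- as.data.frame(raw$agents)
    names(a) <- c("X_ref", "Y_ref", "theta", "length", "status_code")
    a$id <- seq_len(nrow(a))
    a$status <- factor(c("growing", "settled", "stalled")[a$status_code + 1],
                       levels = c("growing", "settled", "stalled"))
    # deformed tip positions from the last recorded trajectory rows
    last <- traj[traj$step == ns, , drop = FALSE]
    a$x_def <- last$x[match(a$id, last$id)]
    a$y_def <- last$y[match(a$id, last$id)]
    a
  } else {
    data.frame(X_ref = numeric(), Y_ref = numeric(), theta = numeric(),
               length = numeric(), status_code = numeric(), id = integer(),
               status = factor(levels = c("growing", "settled", "stalled")),
               x_def = numeric(), y_def = numeric())
  }
  pial <- polyline_deformed(mesh, raw$u, mesh$pial)
  flags <- list(aborted = raw$aborted, abort_reason = raw$abort_reason,
                max_energy_ratio = max(series$energy_ratio[series$T >= 0.1], 0),
                quasi_static_ok = all(series$energy_ratio[series$T >= 0.1] <=
                                        0.05),
                pial_self_intersects = polyline_self_intersects(pial))
  res <- structure(list(mesh = mesh, u = raw$u, v = raw$v,
                        theta_ctx = raw$theta_ctx, theta_sub = raw$theta_sub,
                        t = raw$t, elem_region = elem_region,
                        elem_mu = raw$elem_mu, gp_stress = raw$gp_stress,
                        trajectories = traj, agents = agents,
                        series = series, config = config,
                        seed = config$seed, flags = flags,
                        rho = raw$rho, dt = raw$dt),
                   class = "foldax_result")
  res$metrics <- metrics_report(res)
  res
}

#' @export
print.foldax_result <- function(x, ...) {
  cat(sprintf("foldax result (seed %d): T = %.3f, GI = %.4f\n",
              x$seed, max(x$series$T), x$metrics$GI))
  cat(sprintf("  agents settled %d / stalled %d / growing %d of %d\n",
              sum(x$agents$status == "settled"),
              sum(x$agents$status == "stalled"),
              sum(x$agents$status == "growing"), nrow(x$agents)))
  cat(sprintf("  gyral density %.1f%%, V_f %.3f, max KE/IE %.4f%s\n",
              x$metrics$gyral_density_pct, x$metrics$V_f,
              x$flags$max_energy_ratio,
              if (!x$flags$quasi_static_ok) " [quasi-static criterion violated]"
              else ""))
  invisible(x)
}

# scalar metric row for ensembles/sweeps
metric_row <- function(res) {
  m <- res$metrics
  onset <- res$series$T[which(res$series$GI > 1.02)[1]]
  data.frame(seed = res$seed, onset_T = onset, GI = m$GI,
             gyral_density_pct = m$gyral_density_pct,
             sulcal_density_pct = m$sulcal_density_pct,
             n_reached = m$n_reached, V_f = m$V_f,
             equivalent_stiffness = m$equivalent_stiffness,
             max_energy_ratio = res$flags$max_energy_ratio,
             aborted = res$flags$aborted)
}

#' Run an ensemble of replicate simulations
#'
#' Replicates share the configuration; replicate seeds are derived from the
#' base seed through a counter-based generator, so ensembles are
#' reproducible and replicates independent.  Per-run failures are caught
#' and recorded; the ensemble continues.
#'
#' @param config a [simulation_config()]
#' @param n_replicates number of replicates (default `config$n_replicates`)
#' @param base_seed base seed (default `config$seed`)
#' @return list of class `foldax_ensemble`: `table` (one metric row per
#'   replicate), `summary` (mean and SD of each metric), `running_mean`
#'   of the gyral density (replicate-count convergence diagnostic),
#'   `results` (the individual results), `errors`
#' @export
run_ensemble <- function(config, n_replicates = NULL, base_seed = NULL) {
  if (is.null(n_replicates)) n_replicates <- config$n_replicates
  if (is.null(base_seed)) base_seed <- config$seed
  stopifnot(n_replicates >= 1)
  results <- vector("list", n_replicates)
  errors <- list()
  rows <- list()
  for (r in seq_len(n_replicates)) {
    sd_r <- cpp_mix_seed(base_seed, r)
    res <- tryCatch(run_simulation(config, seed = sd_r),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1]] <- list(replicate = r, message =
                                             conditionMessage(res))
    } else {
      results[[r]] <- res
      rows[[length(rows) + 1]] <- cbind(replicate = r, metric_row(res))
    }
  }
  tab <- do.call(rbind, rows)
  num <- tab[, !(names(tab) %in% c("replicate", "seed", "aborted")),
             drop = FALSE]
  summ <- data.frame(metric = names(num),
                     mean = vapply(num, mean, numeric(1), na.rm = TRUE),
                     sd = vapply(num, sd, numeric(1), na.rm = TRUE),
                     row.names = NULL)
  rmean <- cumsum(ifelse(is.na(tab$gyral_density_pct), 0,
                         tab$gyral_density_pct)) /
    cumsum(!is.na(tab$gyral_density_pct))
  structure(list(table = tab, summary = summ, running_mean = rmean,
                 results = results, errors = errors,
                 base_seed = base_seed),
            class = "foldax_ensemble")
}

#' @export
print.foldax_ensemble <- function(x, ...) {
  cat(sprintf("foldax ensemble: %d replicates (base seed %s)\n",
              nrow(x$table), format(x$base_seed)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Sweep one configuration parameter
#'
#' Runs one ensemble per parameter value and returns a tidy table of
#' per-replicate metrics against the value, with optional Tukey HSD
#' pairwise comparisons of the gyral density.
#'
#' @param config a [simulation_config()]
#' @param parameter name of a configuration field (e.g. `"G_axn"`)
#' @param values vector of values to sweep
#' @param n_replicates replicates per value
#' @param base_seed base seed shared across values (replicate seeds are
#'   derived per value and replicate)
#' @param posthoc logical; attach Tukey HSD comparisons of
#'   `gyral_density_pct` across values
#' @return list of class `foldax_sweep`: `table`, `summary` (ensemble means
#'   per value), `posthoc` (or NULL)
#' @export
run_sweep <- function(config, parameter, values, n_replicates = NULL,
                      base_seed = NULL, posthoc = FALSE) {
  if (!parameter %in% names(config)) stop("unknown configuration field: ",
                                          parameter)
  if (is.null(base_seed)) base_seed <- config$seed
  tabs <- list()
  summaries <- list()
  for (i in seq_along(values)) {
    cfg <- config
    cfg[[parameter]] <- values[[i]]
    ens <- run_ensemble(cfg, n_replicates,
                        base_seed = cpp_mix_seed(base_seed, 1000 + i))
    tabs[[i]] <- cbind(value = values[[i]], ens$table)
    summaries[[i]] <- cbind(value = values[[i]],
                            as.data.frame(as.list(setNames(ens$summary$mean,
                                                           ens$summary$metric))))
  }
  tab <- do.call(rbind, tabs)
  summ <- do.call(rbind, summaries)
  ph <- NULL
  if (posthoc && length(values) > 1 && sum(!is.na(tab$gyral_density_pct)) > 2) {
    dat <- data.frame(g = factor(tab$value), y = tab$gyral_density_pct)
    dat <- dat[is.finite(dat$y), ]
    ph <- TukeyHSD(aov(y ~ g, data = dat))
  }
  structure(list(table = tab, summary = summ, posthoc = ph,
                 parameter = parameter),
            class = "foldax_sweep")
}

#' @export
print.foldax_sweep <- function(x, ...) {
  cat(sprintf("foldax sweep over %s\n", x$parameter))
  print(x$summary, digits = 4)
  invisible(x)
}
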