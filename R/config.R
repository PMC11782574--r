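#' Simulation configuration
#'
#' Collects every model parameter with its default.  Defaults reproduce the
#' baseline study conditions: a 60 x 30 mm white-matter slab under a 1.5 mm
#' cortical plate, cortical tangential growth rate `G_ctx = 0.02` per day
#' (dimensionless time `T = G_ctx * t` spans `[0, 1]`, i.e. 50 days), a
#' cortex-to-ECM growth-rate ratio of 6, stiffness ratios
#' `mu_c/mu_s = mu_f/mu_s = 2`, 100 axon bundles seeded in the bottom 10 mm
#' with initial angles uniform in `pi/2 +/- 10%`, tip growth
#' `G_axn = 0.8` mm/day, stress-induced elongation rate `a = 0.015`
#' mm/(Pa day) with target stress 0, reorientation relaxation `t_star = 300`
#' agent steps and Gaussian angle noise of 0.025 rad per agent step.
#'
#' @param w,h,t_c domain width, white-matter height, cortex thickness (mm)
#' @param elem_size element edge length (mm); must divide `w` and `h + t_c`
#' @param G_ctx cortical growth rate (1/day)
#' @param growth_ratio cortex/ECM growth-rate ratio (`G_ctx / G_sub`)
#' @param growth_kinetics `"linear"` or `"exponential"` multiplier kinetics
#' @param mu_s ECM shear modulus (Pa).  Only stiffness *ratios* control the
#'   folding pattern; the absolute value sets the stress scale that the
#'   stress-induced elongation term `a * sigma` feels.
#' @param mu_c_over_mu_s,mu_f_over_mu_s cortex/ECM and fiber/ECM shear ratios
#' @param k_over_mu bulk-to-shear ratio per material (near-incompressibility)
#' @param G_axn axon tip growth rate (mm/day)
#' @param a stress-induced elongation rate (mm Pa^-1 day^-1)
#' @param sigma_0 target stress above which towed growth acts (Pa)
#' @param t_star reorientation relaxation parameter (agent steps)
#' @param noise_std Gaussian angle noise SD per agent step (rad)
#' @param n_fibers number of axon-bundle agents
#' @param n_replicates default ensemble size
#' @param seed integer run seed
#' @param reorientation_enabled logical; disable for the no-reorientation
#'   comparison runs
#' @param clamp_negative_growth floor the elongation increment at 0 (no tip
#'   retraction under compressive axial stress)
#' @param contact_enabled pial self-contact (not implemented; must be FALSE —
#'   runs whose pial line self-intersects are flagged in the result)
#' @param agent_steps number of agent updates over the run (the cortical
#'   multiplier grows by `1/agent_steps` between updates)
#' @param substeps explicit FE increments per agent step (mass scaling is
#'   chosen automatically so this is stable)
#' @param cfl Courant factor used for automatic mass scaling
#' @param damping mass-proportional damping coefficient (1/day); `NULL` picks
#'   a near-critical value from the scaled wave speed and domain size
#' @param seed_band height of the seeding band above the base (mm)
#' @param degenerate_tol relative tolerance declaring in-plane principal
#'   stresses equal (reorientation is skipped at such points)
#' @param perturb amplitude (mm) of a deterministic smooth mesh imperfection
#'   used for agent-free folding studies; 0 (default) leaves symmetry
#'   breaking to fiber-element conversion
#' @return object of class `foldax_config` (a named list)
#' @export
simulation_config <- function(w = 60, h = 30, t_c = 1.5, elem_size = 0.25,
                              G_ctx = 0.02, growth_ratio = 6,
                              growth_kinetics = "linear",
                              mu_s = 100, mu_c_over_mu_s = 2,
                              mu_f_over_mu_s = 2, k_over_mu = 50,
                              G_axn = 0.8, a = 0.015, sigma_0 = 0,
                              t_star = 300, noise_std = 0.025,
                              n_fibers = 100, n_replicates = 10, seed = 1,
                              reorientation_enabled = TRUE,
                              clamp_negative_growth = TRUE,
                              contact_enabled = FALSE,
                              agent_steps = 500, substeps = 100,
                              cfl = 0.45, damping = NULL,
                              seed_band = 10, degenerate_tol = 1e-6,
                              perturb = 0) {
  cfg <- list(w = w, h = h, t_c = t_c, elem_size = elem_size,
              G_ctx = G_ctx, growth_ratio = growth_ratio,
              growth_kinetics = growth_kinetics,
              mu_s = mu_s, mu_c_over_mu_s = mu_c_over_mu_s,
              mu_f_over_mu_s = mu_f_over_mu_s, k_over_mu = k_over_mu,
              G_axn = G_axn, a = a, sigma_0 = sigma_0,
              t_star = t_star, noise_std = noise_std,
              n_fibers = n_fibers, n_replicates = n_replicates, seed = seed,
              reorientation_enabled = reorientation_enabled,
              clamp_negative_growth = clamp_negative_growth,
              contact_enabled = contact_enabled,
              agent_steps = agent_steps, substeps = substeps,
              cfl = cfl, damping = damping,
              seed_band = seed_band, degenerate_tol = degenerate_tol,
              perturb = perturb)
  validate_config(cfg)
  class(cfg) <- "foldax_config"
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (w <= 0 || h <= 0 || t_c <= 0 || elem_size <= 0)
      stop("geometry dimensions must be positive")
    if (t_c < elem_size) stop("cortex thickness must be >= element size")
    ok_div <- function(a, b) abs(a / b - round(a / b)) < 1e-8
    if (!ok_div(w, elem_size) || !ok_div(h + t_c, elem_size))
      stop("elem_size must divide w and h + t_c")
    if (G_ctx < 0 || growth_ratio <= 0 || mu_s <= 0 || k_over_mu <= 0 ||
        G_axn < 0 || a < 0 || t_star <= 0 || noise_std < 0)
      stop("rates and moduli must be non-negative (moduli positive)")
    if (!growth_kinetics %in% c("linear", "exponential"))
      stop("growth_kinetics must be 'linear' or 'exponential'")
    if (isTRUE(contact_enabled))
      stop("pial self-contact is not implemented; set contact_enabled = FALSE")
    if (agent_steps < 1 || substeps < 1) stop("step counts must be >= 1")
  })
  invisible(cfg)
}

# fill in derived defaults just before a run
resolve_config <- function(cfg) {
  if (is.null(cfg$damping)) {
    t_end <- 1 / cfg$G_ctx
    dt <- t_end / (cfg$agent_steps * cfg$substeps)
    c_d <- cfg$cfl * cfg$elem_size / dt     # dilatational wave speed, mm/day
    mu_max <- cfg$mu_s * max(1, cfg$mu_c_over_mu_s, cfg$mu_f_over_mu_s)
    c_s <- c_d * sqrt(1 / (cfg$k_over_mu + 4 / 3))  # shear wave speed
    omega1 <- pi * c_s / max(cfg$w, cfg$h + cfg$t_c)
    # slightly overcritical for the lowest mode: controls the kinetic-energy
    # burst at the buckling bifurcation without stalling quasi-static tracking
    cfg$damping <- 3 * omega1
  }
  cfg
}

#' @export
print.foldax_config <- function(x, ...) {
  cat("foldax simulation configuration\n")
  cat(sprintf("  domain: %g x %g mm + %g mm cortex, elements %g mm (%d x %d)\n",
              x$w, x$h, x$t_c, x$elem_size,
              round(x$w / x$elem_size), round((x$h + x$t_c) / x$elem_size)))
  cat(sprintf("  growth: G_ctx %g /d, ratio %g, kinetics %s\n",
              x$G_ctx, x$growth_ratio, x$growth_kinetics))
  cat(sprintf("  moduli: mu_s %g Pa, mu_c/mu_s %g, mu_f/mu_s %g, k/mu %g\n",
              x$mu_s, x$mu_c_over_mu_s, x$mu_f_over_mu_s, x$k_over_mu))
  cat(sprintf("  agents: n %d, G_axn %g mm/d, a %g, t* %g, noise %g rad, reorient %s\n",
              x$n_fibers, x$G_axn, x$a, x$t_star, x$noise_std,
              x$reorientation_enabled))
  cat(sprintf("  stepping: %d agent steps x %d substeps, seed %d\n",
              x$agent_steps, x$substeps, x$seed))
  invisible(x)
}
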