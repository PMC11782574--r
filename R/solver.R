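# R-level driver around the compiled explicit kernel: a SolverState object,
# force assembly, stepping, energies and stress probing.  The production
# coupled loop lives in C++ (cpp_run); these wrappers expose the same
# kernels for unit testing and for stand-alone quasi-static studies.

region_codes <- function(region) {
  # internal coding used by the kernel: 0 ecm, 1 cortex, 2 fiber
  unname(c(ecm = 0L, cortex = 1L, fiber = 2L)[as.character(region)])
}

#' Create a solver state for a bilayer mesh
#'
#' @param mesh a [build_bilayer_mesh()] mesh
#' @param config a [simulation_config()]; geometry fields must match the mesh
#' @return list of class `foldax_state`: displacements `u`, velocities `v`
#'   (interleaved x,y per node), growth multipliers, physical time `t`,
#'   per-element shear moduli and region codes, lumped nodal masses and the
#'   last computed energies
#' @export
fe_state <- function(mesh, config) {
  config <- resolve_config(config)
  mu_el <- ifelse(mesh$elem_region == "cortex",
                  config$mu_s * config$mu_c_over_mu_s,
                  ifelse(mesh$elem_region == "fiber",
                         config$mu_s * config$mu_f_over_mu_s, config$mu_s))
  t_end <- 1 / config$G_ctx
  dt <- t_end / (config$agent_steps * config$substeps)
  mu_max <- config$mu_s * max(1, config$mu_c_over_mu_s, config$mu_f_over_mu_s)
  M <- (config$k_over_mu + 4 / 3) * mu_max
  rho <- M * (dt / (config$cfl * config$elem_size))^2
  # lumped mass: each element contributes a quarter of its mass per node
  m <- numeric(nrow(mesh$nodes))
  A <- rho * mesh$elem_size^2 / 4
  for (a in 1:4) {
    tab <- tabulate(mesh$quads[, a], nbins = length(m))
    m <- m + A * tab
  }
  structure(list(u = numeric(2 * nrow(mesh$nodes)),
                 v = numeric(2 * nrow(mesh$nodes)),
                 theta_ctx = 1, theta_sub = 1, t = 0,
                 mu_el = mu_el, region = region_codes(mesh$elem_region),
                 m = m, dt = dt, rho = rho, config = config,
                 energies = c(kinetic = 0, internal = 0)),
            class = "foldax_state")
}

#' Assemble internal nodal forces
#'
#' Total-Lagrangian assembly of \eqn{\int B^T T \, dV} around the
#' neo-Hookean stress with 2x2 Gauss quadrature, in the current
#' configuration (forces conjugate to nodal displacements).
#'
#' @param state a [fe_state()]
#' @param mesh the matching mesh
#' @return list: `f` (interleaved nodal force vector), `internal_energy`,
#'   `gp_stress` (4 rows per element: in-plane `T11, T22, T12` at each
#'   Gauss point)
#' @export
internal_forces <- function(state, mesh) {
  cfg <- state$config
  cpp_internal_forces(mesh$w, mesh$h, mesh$t_c, mesh$elem_size,
                      cfg$perturb, state$u, state$region, state$mu_el,
                      state$theta_ctx, state$theta_sub, cfg$k_over_mu)
}

#' Advance the explicit solver
#'
#' Central-difference update with automatic mass scaling and
#' mass-proportional damping; growth multipliers advance at the configured
#' region rates before each force evaluation.  Aborts with a diagnostic
#' error when the kinetic energy exceeds ten times the internal energy
#' (instability) or an element inverts.
#'
#' @param state a [fe_state()]
#' @param mesh the matching mesh
#' @param n number of explicit increments to take
#' @param grow logical; advance growth multipliers (set `FALSE` to relax a
#'   frozen grown state toward equilibrium)
#' @return updated state
#' @export
step_explicit <- function(state, mesh, n = 1, grow = TRUE) {
  cfg <- state$config
  dt <- state$dt
  G_sub <- cfg$G_ctx / cfg$growth_ratio
  nnx <- mesh$nnx
  nn <- nrow(mesh$nodes)
  i_idx <- (seq_len(nn) - 1L) %% nnx
  j_idx <- (seq_len(nn) - 1L) %/% nnx
  fix_x <- which(i_idx == 0L | i_idx == mesh$nex)
  fix_y <- which(j_idx == 0L)
  damp <- 1 / (1 + cfg$damping * dt)
  for (s in seq_len(n)) {
    if (grow) {
      state$theta_ctx <- advance_growth_multiplier(state$theta_ctx, cfg$G_ctx,
                                                   dt, cfg$growth_kinetics)
      state$theta_sub <- advance_growth_multiplier(state$theta_sub, G_sub,
                                                   dt, cfg$growth_kinetics)
    }
    fr <- internal_forces(state, mesh)
    minv <- rep(1 / state$m, each = 2)
    v <- (state$v - dt * fr$f * minv) * damp
    v[2 * fix_x - 1] <- 0
    v[2 * fix_y] <- 0
    state$v <- v
    state$u <- state$u + dt * v
    state$t <- state$t + dt
    ke <- 0.5 * sum(rep(state$m, each = 2) * v^2)
    state$energies <- c(kinetic = ke, internal = fr$internal_energy)
    if (!is.finite(ke) ||
        (fr$internal_energy > 1e-9 && ke > 10 * fr$internal_energy))
      stop(sprintf("explicit solver instability at t = %g day (KE = %g, IE = %g)",
                   state$t, ke, fr$internal_energy))
  }
  state
}

#' Kinetic-to-internal energy ratio
#'
#' Quasi-static validity monitor: the dynamic relaxation run is accepted as
#' quasi-static only while this ratio stays below 0.05.
#'
#' @param state a [fe_state()] (or any list with an `energies` element)
#' @return `KE / IE`, or 0 by convention while `IE == 0`
#' @export
energy_ratio <- function(state) {
  e <- state$energies
  if (e[["internal"]] <= 0) 0 else e[["kinetic"]] / e[["internal"]]
}

#' Probe the Cauchy stress field at deformed-frame points
#'
#' Locates the element containing each query point in the deformed
#' configuration and returns the in-plane Cauchy stress of the nearest Gauss
#' point together with its principal decomposition.
#'
#' @param state a [fe_state()]
#' @param mesh the matching mesh
#' @param x query point(s): length-2 vector or n x 2 matrix (mm, deformed)
#' @return for a single point, a list with `elem`, `T` (2x2), and
#'   `principal`; for several points, a list of such lists
#' @export
probe_stress <- function(state, mesh, x) {
  pts <- if (is.matrix(x)) x else matrix(x, ncol = 2)
  cfg <- state$config
  hit <- cpp_probe(mesh$w, mesh$h, mesh$t_c, mesh$elem_size, cfg$perturb,
                   state$u, pts)
  fr <- internal_forces(state, mesh)
  out <- vector("list", nrow(pts))
  for (p in seq_len(nrow(pts))) {
    e <- hit$elem[p]
    if (is.na(e)) stop(sprintf("point (%g, %g) is outside the deformed domain",
                               pts[p, 1], pts[p, 2]))
    Xr <- hit$ref[p, ]
    es <- mesh$elem_size
    xi <- 2 * (Xr[1] %% es) / es - 1
    eta <- 2 * (Xr[2] %% es) / es - 1
    q <- nearest_gp(xi, eta)
    s <- fr$gp_stress[(e - 1) * 4 + q, ]
    T2 <- matrix(c(s[1], s[3], s[3], s[2]), 2, 2)
    out[[p]] <- list(elem = e, T = T2,
                     principal = principal_decomposition(T2,
                       tol_rel = cfg$degenerate_tol, mu_ref = cfg$mu_s))
  }
  if (nrow(pts) == 1) out[[1]] else out
}

# gauss points are ordered (-,-), (+,-), (+,+), (-,+)
nearest_gp <- function(xi, eta) {
  if (eta <= 0) { if (xi <= 0) 1L else 2L } else { if (xi <= 0) 4L else 3L }
}
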