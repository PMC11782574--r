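# Discrete axon-bundle agents: stochastic tip growth, stress-induced (towed)
# elongation, reorientation toward the maximum tensile principal stress, and
# conversion of traversed ECM elements into fiber elements.

#' Seed axon-bundle agents
#'
#' Tips are placed uniformly over `x in [0, w]`, `y in [0, seed_band]` mm and
#' initial growth angles drawn uniformly in `pi/2 +/- 10%`, directing
#' bundles from the core toward the cortical plate.  Each agent carries its
#' own counter-based RNG stream derived from the run seed, so runs are
#' reproducible bit-for-bit and agents are mutually independent.
#'
#' @param n number of bundles
#' @param config a [simulation_config()] (uses `w`, `seed_band`, `seed`)
#' @param seed overrides `config$seed` when given
#' @return data.frame of class `foldax_bundles`: `id`, `x`, `y` (tip, mm),
#'   `theta` (rad), `length` (mm), `status` (growing/settled/stalled)
#' @export
seed_bundles <- function(n, config, seed = NULL) {
  stopifnot(n >= 1)
  seed <- if (is.null(seed)) config$seed else seed
  m <- cpp_seed_bundles(seed, n, config$w, config$seed_band, pi / 2,
                        (pi / 2) * 0.10)
  structure(data.frame(id = seq_len(n), x = m[, 1], y = m[, 2],
                       theta = m[, 3], length = 0,
                       status = factor(rep("growing", n),
                                       levels = c("growing", "settled",
                                                  "stalled"))),
            class = c("foldax_bundles", "data.frame"), seed = seed)
}

#' Resolve the sign ambiguity of a principal direction
#'
#' Eigenvectors are defined up to sign; the reorientation attractor is taken
#' as the representative of the maximum-tensile-stress direction lying in
#' the half-plane of the current preferred direction, preventing spurious
#' 180-degree rotations.
#'
#' @param nA current preferred direction (unit 2-vector)
#' @param n_max principal direction (unit 2-vector)
#' @return `n_max` flipped if needed so that `nA . n_max >= 0`
#' @export
orient_sign <- function(nA, n_max) {
  if (sum(nA * n_max) < 0) -n_max else n_max
}

#' Angular velocity of stress-induced reorientation
#'
#' \eqn{\omega = \frac{\pi}{2 t^*} \lVert n^A \times n^T_{max}\rVert}: the
#' reorientation rate is proportional to the sine of the angle between the
#' preferred direction and the maximum tensile principal stress direction,
#' scaled by the relaxation parameter `t_star` (in agent steps).
#'
#' @param nA preferred direction (unit 2-vector, sign-aligned)
#' @param n_max principal stress direction (unit 2-vector, sign-aligned)
#' @param t_star relaxation parameter (> 0, agent steps)
#' @return list: `omega` (rad/step) and `axis` (+1 counter-clockwise /
#'   -1 clockwise, the out-of-plane component of the normalized cross
#'   product; 0 when aligned)
#' @export
rotation_vector <- function(nA, n_max, t_star) {
  stopifnot(t_star > 0)
  cross_z <- nA[1] * n_max[2] - nA[2] * n_max[1]
  omega <- pi / (2 * t_star) * abs(cross_z)
  list(omega = omega, axis = sign(cross_z))
}

#' Rotate the preferred direction toward the principal stress direction
#'
#' Closed-form planar rotation by `dt * omega` about the out-of-plane axis,
#' toward the (sign-aligned) maximum tensile principal stress direction.
#' The rotation never overshoots the attractor within a step.  Under a
#' degenerate principal state (`degenerate = TRUE`) the input is returned
#' unchanged: equal in-plane principal stresses define no attractor.
#'
#' @param nA preferred direction (unit 2-vector)
#' @param n_max maximum tensile principal stress direction (unit 2-vector,
#'   either sign)
#' @param t_star relaxation parameter (agent steps)
#' @param dt time increment in agent steps (default 1)
#' @param degenerate logical degeneracy flag from the principal
#'   decomposition
#' @return updated unit direction
#' @export
reorient <- function(nA, n_max, t_star, dt = 1, degenerate = FALSE) {
  if (degenerate) return(nA)
  n_max <- orient_sign(nA, n_max)
  rv <- rotation_vector(nA, n_max, t_star)
  if (rv$omega == 0) return(nA)
  gap <- atan2(nA[1] * n_max[2] - nA[2] * n_max[1], sum(nA * n_max))
  rot <- min(dt * rv$omega, abs(gap)) * sign(gap)
  cs <- cos(rot); sn <- sin(rot)
  out <- c(cs * nA[1] - sn * nA[2], sn * nA[1] + cs * nA[2])
  out / sqrt(sum(out^2))
}

#' Add Gaussian angle noise
#'
#' Stochastic tip-growth model: once per agent step the growth angle
#' receives centred Gaussian noise, `theta + epsilon`,
#' `epsilon ~ N(0, std^2)`.
#'
#' @param theta angle (rad)
#' @param std noise standard deviation (rad, >= 0)
#' @param eps optional pre-drawn standard-normal variate (from the agent's
#'   stream); drawn from R's RNG when missing
#' @return perturbed angle
#' @export
add_angle_noise <- function(theta, std, eps = NULL) {
  stopifnot(std >= 0)
  if (std == 0) return(theta)
  if (is.null(eps)) eps <- rnorm(length(theta))
  theta + std * eps
}

#' Axial stress felt by a bundle
#'
#' Normal component of the Cauchy stress in the bundle direction,
#' \eqn{\sigma = n^A \cdot T \cdot n^A}.
#'
#' @param T symmetric stress tensor (2x2)
#' @param nA unit direction (2-vector)
#' @return axial stress (Pa)
#' @export
axial_stress <- function(T, nA) {
  drop(crossprod(nA, T %*% nA))
}

#' Elongation increment of one agent step
#'
#' Euler update of the combined tip and towed growth law,
#' \eqn{\Delta L = [a(\sigma - \sigma_0) + G^{axn}]\Delta t}.  With the
#' default clamp the increment is floored at zero: compressive axial stress
#' suppresses growth but never retracts the tip.
#'
#' @param sigma axial stress (Pa)
#' @param config a [simulation_config()] (uses `a`, `sigma_0`, `G_axn`,
#'   `clamp_negative_growth`)
#' @param dt time increment (day)
#' @return length increment (mm)
#' @export
elongation_increment <- function(sigma, config, dt) {
  stopifnot(dt > 0)
  dL <- (config$a * (sigma - config$sigma_0) + config$G_axn) * dt
  if (config$clamp_negative_growth) pmax(dL, 0) else dL
}

#' Advance a bundle tip
#'
#' Moves the tip by `dL` along the preferred direction,
#' `tip + dL * (cos theta, sin theta)`, and accumulates the grown length.
#'
#' @param bundle one-row slice of a [seed_bundles()] frame (or a list with
#'   `x`, `y`, `theta`, `length`)
#' @param dL length increment (mm)
#' @return updated bundle
#' @export
advance_tip <- function(bundle, dL) {
  bundle$x <- bundle$x + dL * cos(bundle$theta)
  bundle$y <- bundle$y + dL * sin(bundle$theta)
  bundle$length <- bundle$length + dL
  bundle
}

#' Elements converted by a tip segment
#'
#' Every ECM element whose footprint the tip segment traverses is relabelled
#' as a fiber element (its shear modulus becomes `mu_f` from the next
#' increment on).  Conversion is irreversible; cortex and existing fiber
#' elements are unchanged.
#'
#' @param mesh a [build_bilayer_mesh()] mesh (reference configuration)
#' @param from,to segment endpoints (length-2, reference/undeformed mm)
#' @param elem_region current per-element region factor
#' @return integer ids of newly converted elements (possibly empty)
#' @export
convert_elements <- function(mesh, from, to, elem_region) {
  cells <- cpp_segment_cells(mesh$w, mesh$h, mesh$t_c, mesh$elem_size,
                             from[1], from[2], to[1], to[2]) + 1L
  cells[elem_region[cells] == "ecm"]
}

#' Termination state of a bundle
#'
#' A bundle settles once its tip crosses the cortex-white-matter interface
#' (equivalently, enters a cortex element); settled and stalled agents
#' receive no further updates.
#'
#' @param bundle a bundle row (needs `y` in the reference frame and `status`)
#' @param mesh the mesh (uses `h`)
#' @return updated status factor level
#' @export
check_termination <- function(bundle, mesh) {
  if (bundle$status == "growing" && bundle$y >= mesh$h) "settled"
  else as.character(bundle$status)
}
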