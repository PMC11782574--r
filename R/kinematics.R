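#' @useDynLib foldax, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aov optimize runif rnorm sd integrate setNames TukeyHSD
#' @importFrom utils read.csv write.csv
NULL

#' Growth tensor of the tangentially expanding cortical plate
#'
#' Builds the 3x3 growth tensor of a cortical material point undergoing
#' in-plane area growth, \eqn{F^g = \sqrt{\vartheta} I +
#' (1-\sqrt{\vartheta}) n_0 \otimes n_0}, where \eqn{n_0} is the referential
#' unit normal of the pial surface.  Growth is purely tangential: the normal
#' direction keeps stretch 1 while the two tangential directions stretch by
#' \eqn{\sqrt{\vartheta}}, so \eqn{\det F^g = \vartheta} (the relative area
#' grown).
#'
#' @param theta_g growth multiplier \eqn{\vartheta \ge 1} (dimensionless)
#' @param n0 referential unit normal, length-2 or length-3 numeric
#' @return 3x3 growth tensor
#' @export
cortical_growth_tensor <- function(theta_g, n0) {
  if (theta_g < 1) stop("growth multiplier must be >= 1")
  n0 <- embed3(n0)
  nn <- sqrt(sum(n0^2))
  if (abs(nn - 1) > 1e-9) stop("n0 must be a unit vector")
  r <- sqrt(theta_g)
  r * diag(3) + (1 - r) * tcrossprod(n0)
}

#' Growth tensor of the isotropically growing white-matter ECM
#'
#' Isotropic volumetric growth \eqn{F^g = \vartheta^{1/3} I} with
#' \eqn{\det F^g = \vartheta}.
#'
#' @inheritParams cortical_growth_tensor
#' @return 3x3 growth tensor
#' @export
subcortical_growth_tensor <- function(theta_g) {
  if (theta_g < 1) stop("growth multiplier must be >= 1")
  theta_g^(1 / 3) * diag(3)
}

#' Advance a growth multiplier by linear kinetics
#'
#' Forward-Euler update of \eqn{\dot\vartheta = G}: exact for the linear
#' kinetic law, so step subdivision does not change the result.
#'
#' @param theta_g current multiplier
#' @param rate growth rate G (1/day), non-negative
#' @param dt time increment (day)
#' @param kinetics `"linear"` (\eqn{\dot\vartheta = G}) or `"exponential"`
#'   (\eqn{\dot\vartheta = G\vartheta}, integrated exactly over `dt`)
#' @return updated multiplier
#' @export
advance_growth_multiplier <- function(theta_g, rate, dt,
                                      kinetics = c("linear", "exponential")) {
  stopifnot(rate >= 0, dt > 0)
  kinetics <- match.arg(kinetics)
  if (kinetics == "linear") theta_g + rate * dt else theta_g * exp(rate * dt)
}

#' Elastic part of the deformation gradient
#'
#' \eqn{F^e = F \cdot (F^g)^{-1}}.
#'
#' @param F total deformation gradient (3x3)
#' @param Fg growth tensor (3x3, invertible)
#' @return elastic deformation gradient (3x3)
#' @export
elastic_part <- function(F, Fg) {
  d <- det(Fg)
  if (!is.finite(d) || abs(d) < 1e-300) stop("singular growth tensor")
  F %*% solve(Fg)
}

#' Cauchy stress of the compressible neo-Hookean law
#'
#' Free energy \eqn{W = \frac{\mu}{2}(J_e^{-2/3}\,\mathrm{tr}(F_e^T F_e) - 3)
#' + \frac{k}{2}(J_e - 1)^2} (isochoric neo-Hookean plus quadratic volumetric
#' penalty), giving \eqn{T = \mu J_e^{-5/3}\,\mathrm{dev}(b_e) + k(J_e-1)I}
#' with \eqn{b_e = F_e F_e^T}.
#'
#' @param Fe elastic deformation gradient (3x3, det > 0)
#' @param mu shear modulus (Pa)
#' @param k bulk modulus (Pa)
#' @return 3x3 symmetric Cauchy stress (Pa)
#' @export
cauchy_stress <- function(Fe, mu, k) {
  Je <- det(Fe)
  if (Je <= 0) stop("element inversion: det(Fe) <= 0")
  be <- tcrossprod(Fe)
  trb <- sum(diag(be))
  mu * Je^(-5 / 3) * (be - trb / 3 * diag(3)) + k * (Je - 1) * diag(3)
}

#' Strain energy density of the neo-Hookean law
#'
#' @inheritParams cauchy_stress
#' @return scalar energy density (Pa, per unit intermediate volume)
#' @export
neo_hookean_energy <- function(Fe, mu, k) {
  Je <- det(Fe)
  if (Je <= 0) stop("element inversion: det(Fe) <= 0")
  0.5 * mu * (Je^(-2 / 3) * sum(Fe^2) - 3) + 0.5 * k * (Je - 1)^2
}

#' Principal decomposition of a symmetric Cauchy stress
#'
#' Eigen-decomposition with principal values sorted descending.  The
#' `degenerate` flag marks leading principal values equal within
#' `tol_rel * max(|sigma1|, mu_ref)`; consumers of the decomposition for
#' agent guidance must skip reorientation when it is set (the attractor
#' direction is then undefined).
#'
#' @param T symmetric stress tensor (2x2 or 3x3)
#' @param tol_rel relative degeneracy tolerance (default 1e-6)
#' @param mu_ref stress scale floor for the tolerance (Pa); defaults to 100,
#'   the package's default ECM shear modulus
#' @return list of class `principal_stress` with `sigma` (descending),
#'   `n` (columns = unit directions) and `degenerate`
#' @export
principal_decomposition <- function(T, tol_rel = 1e-6, mu_ref = 100) {
  if (max(abs(T - t(T))) > 1e-8 * max(abs(T), 1))
    stop("stress tensor must be symmetric")
  e <- eigen((T + t(T)) / 2, symmetric = TRUE)
  o <- order(e$values, decreasing = TRUE)
  sig <- e$values[o]
  n <- e$vectors[, o, drop = FALSE]
  degen <- (sig[1] - sig[2]) <= tol_rel * max(abs(sig[1]), mu_ref)
  structure(list(sigma = sig, n = n, degenerate = degen),
            class = "principal_stress")
}

# embed a 2-vector into 3-D (z = 0); pass 3-vectors through
embed3 <- function(v) {
  if (length(v) == 2) c(v, 0) else if (length(v) == 3) v else
    stop("expected a 2- or 3-vector")
}

# in-plane (2x2) principal decomposition used for agent guidance
principal_inplane <- function(sxx, syy, sxy, tol_rel = 1e-6, mu_ref = 100) {
  tr2 <- (sxx + syy) / 2
  disc <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  s1 <- tr2 + disc
  s2 <- tr2 - disc
  phi <- 0.5 * atan2(2 * sxy, sxx - syy)
  list(sigma = c(s1, s2), angle = phi,
       n1 = c(cos(phi), sin(phi)),
       degenerate = (s1 - s2) <= tol_rel * max(abs(s1), mu_ref))
}
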