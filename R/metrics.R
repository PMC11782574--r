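# Quantitative readouts: gyrification index, gyral/sulcal classification and
# fiber densities, volume fractions, local and equivalent stiffness ratios,
# angular distributions.

#' Gyrification index of a pial polyline
#'
#' Ratio of the arc length of the pial contour to the length of its convex
#' hull.  Only the upper chain of the hull spanning the pial endpoints is
#' used, so a straight or convex contour scores exactly 1 (closing the hull
#' along the bottom would bias the index upward).
#'
#' @param pial n x 2 matrix of ordered pial points (mm)
#' @return dimensionless GI >= 1
#' @export
gyrification_index <- function(pial) {
  pial <- as.matrix(pial)
  if (nrow(pial) < 2) stop("pial polyline needs at least 2 points")
  arc <- sum(sqrt(rowSums(diff(pial)^2)))
  hull <- upper_hull(pial)
  hull_len <- sum(sqrt(rowSums(diff(hull)^2)))
  if (hull_len <= 0) return(1)
  gi <- arc / hull_len
  # a convex contour's hull is the contour itself up to summation order;
  # snap rounding residue so convex lines score exactly 1
  if (gi <= 1 + 1e-12) 1 else gi
}

# Andrew's monotone chain, upper hull only (points sorted by x, then y)
upper_hull <- function(p) {
  o <- order(p[, 1], p[, 2])
  p <- p[o, , drop = FALSE]
  n <- nrow(p)
  if (n <= 2) return(p)
  idx <- integer(0)
  for (i in seq_len(n)) {
    while (length(idx) >= 2) {
      a <- p[idx[length(idx) - 1], ]; b <- p[idx[length(idx)], ]; c <- p[i, ]
      cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      if (cross >= 0) idx <- idx[-length(idx)] else break
    }
    idx <- c(idx, i)
  }
  p[idx, , drop = FALSE]
}

#' Classify interface points as gyral or sulcal
#'
#' The mid-surface is the pointwise mean of the pial and interface heights
#' at matched samples (matched columns of the structured grid); its average
#' height is the reference level approximating the average position of the
#' cortical surface.  Points where the mid-surface sits at or above that
#' level are gyral (outward ridges); below it, sulcal (inward valleys).
#' The tie rule (equality is gyral) makes the labels a partition, and a
#' flat geometry — every point on the reference level — is entirely gyral
#' by that rule.
#'
#' @param interface n x 2 matrix of ordered cortex-WM interface points
#' @param pial n x 2 matrix of matched pial points (same column order)
#' @return character vector of labels `"gyral"` / `"sulcal"` per interface
#'   point
#' @export
classify_gyri_sulci <- function(interface, pial) {
  interface <- as.matrix(interface); pial <- as.matrix(pial)
  if (nrow(interface) != nrow(pial))
    stop("interface and pial must have matched samples")
  mid <- (interface[, 2] + pial[, 2]) / 2
  ifelse(mid >= mean(mid), "gyral", "sulcal")
}

#' Normalized gyral and sulcal fiber densities
#'
#' Each settled tip is assigned to the nearest interface point; the raw
#' density per region is the settled count divided by the region's arc
#' length (the 2-D analogue of an area), and the two densities are
#' normalized to sum to 100.
#'
#' @param settled_tips m x 2 matrix of settled tip positions (deformed mm)
#' @param labels per-interface-point labels from [classify_gyri_sulci()]
#' @param interface n x 2 matrix of interface points (deformed mm)
#' @return list: `gyral_density_pct`, `sulcal_density_pct` (sum 100),
#'   `counts`, `region_lengths` (mm); densities are `NA` when no tip settled
#' @export
fiber_density <- function(settled_tips, labels, interface) {
  interface <- as.matrix(interface)
  n <- nrow(interface)
  # arc length attributed to each interface point: half of adjacent segments
  seg <- sqrt(rowSums(diff(interface)^2))
  pt_len <- c(seg / 2, 0) + c(0, seg / 2)
  len <- c(gyral = sum(pt_len[labels == "gyral"]),
           sulcal = sum(pt_len[labels == "sulcal"]))
  if (is.null(settled_tips) || NROW(settled_tips) == 0) {
    return(list(gyral_density_pct = NA_real_, sulcal_density_pct = NA_real_,
                counts = c(gyral = 0, sulcal = 0), region_lengths = len))
  }
  settled_tips <- matrix(as.numeric(as.matrix(settled_tips)), ncol = 2)
  nearest <- vapply(seq_len(nrow(settled_tips)), function(i) {
    d2 <- (interface[, 1] - settled_tips[i, 1])^2 +
          (interface[, 2] - settled_tips[i, 2])^2
    which.min(d2)
  }, integer(1))
  cnt <- c(gyral = sum(labels[nearest] == "gyral"),
           sulcal = sum(labels[nearest] == "sulcal"))
  dens <- ifelse(len > 0, cnt / len, 0)
  tot <- sum(dens)
  if (tot == 0)
    return(list(gyral_density_pct = NA_real_, sulcal_density_pct = NA_real_,
                counts = cnt, region_lengths = len))
  list(gyral_density_pct = 100 * dens[["gyral"]] / tot,
       sulcal_density_pct = 100 * dens[["sulcal"]] / tot,
       counts = cnt, region_lengths = len)
}

#' Fiber and ECM volume fractions of the white matter
#'
#' Deformed-area fractions of fiber versus ECM elements over the
#' white-matter region; the two fractions sum to 1 by construction.
#'
#' @param mesh a [build_bilayer_mesh()] mesh
#' @param elem_region per-element region factor (cortex/ecm/fiber)
#' @param u nodal displacement vector (interleaved); zero if missing
#' @return named vector `c(V_f = ..., V_ecm = ...)`
#' @export
volume_fractions <- function(mesh, elem_region = mesh$elem_region, u = NULL) {
  if (is.null(u)) u <- numeric(2 * nrow(mesh$nodes))
  A <- element_areas_deformed(mesh, u)
  wm <- elem_region != "cortex"
  af <- sum(A[wm & elem_region == "fiber"])
  ae <- sum(A[wm & elem_region == "ecm"])
  tot <- af + ae
  if (tot == 0) return(c(V_f = 0, V_ecm = 1))
  c(V_f = af / tot, V_ecm = ae / tot)
}

#' Local stiffness ratio map of the white matter
#'
#' For each query point, the area-weighted shear-stiffness ratio
#' \eqn{V_f(\mu_f/\mu_s) + V_{ECM}} evaluated over the white-matter material
#' inside a disc of given radius (discs are clipped at the domain
#' boundary).  For a fiber/ECM ratio of 2 this reduces to the local fiber
#' volume fraction plus one.
#'
#' @param mesh mesh
#' @param elem_region per-element region factor
#' @param points m x 2 matrix of evaluation points (mm, same frame as the
#'   coordinates used for the element geometry); defaults to the centroids
#'   of all white-matter elements
#' @param radius disc radius (mm, default 1)
#' @param mu_ratio fiber/ECM stiffness ratio (default 2)
#' @param u optional displacement vector (deformed-frame evaluation)
#' @param nsub element subdivision per axis for the area sums (default 4)
#' @return numeric vector of local stiffness ratios, in `[1, mu_ratio]`
#' @export
local_stiffness_map <- function(mesh, elem_region = mesh$elem_region,
                                points = NULL, radius = 1, mu_ratio = 2,
                                u = NULL, nsub = 4) {
  stopifnot(radius > 0)
  if (is.null(u)) u <- numeric(2 * nrow(mesh$nodes))
  ux <- u[seq(1, length(u), 2)]; uy <- u[seq(2, length(u), 2)]
  xn <- mesh$nodes[, 1] + ux; yn <- mesh$nodes[, 2] + uy
  wm <- which(elem_region != "cortex")
  q <- mesh$quads
  # subcell sample points (bilinear images of a regular parent-grid)
  s <- (seq_len(nsub) - 0.5) / nsub * 2 - 1
  sub <- expand.grid(xi = s, eta = s)
  N <- cbind((1 - sub$xi) * (1 - sub$eta), (1 + sub$xi) * (1 - sub$eta),
             (1 + sub$xi) * (1 + sub$eta), (1 - sub$xi) * (1 + sub$eta)) / 4
  px <- N %*% rbind(xn[q[wm, 1]], xn[q[wm, 2]], xn[q[wm, 3]], xn[q[wm, 4]])
  py <- N %*% rbind(yn[q[wm, 1]], yn[q[wm, 2]], yn[q[wm, 3]], yn[q[wm, 4]])
  A <- element_areas_deformed(mesh, u)[wm] / nsub^2
  is_f <- elem_region[wm] == "fiber"
  if (is.null(points)) {
    points <- cbind(colMeans(matrix(xn[t(q[wm, ])], nrow = 4)),
                    colMeans(matrix(yn[t(q[wm, ])], nrow = 4)))
  }
  points <- matrix(as.numeric(as.matrix(points)), ncol = 2)
  out <- numeric(nrow(points))
  r2 <- radius^2
  for (i in seq_len(nrow(points))) {
    d2 <- (px - points[i, 1])^2 + (py - points[i, 2])^2
    inside <- d2 <= r2                       # nsub^2 x n_wm logical
    wsum <- colSums(inside) * A              # area of each element in disc
    af <- sum(wsum[is_f]); atot <- sum(wsum)
    vf <- if (atot > 0) af / atot else 0
    out[i] <- vf * mu_ratio + (1 - vf)
  }
  out
}

#' Equivalent stiffness ratio of the white matter
#'
#' Global volume-fraction-weighted shear-modulus ratio
#' \eqn{V_f(\mu_f/\mu_s) + V_{ECM}} over the entire white-matter region.
#'
#' @param mesh mesh
#' @param elem_region per-element region factor
#' @param mu_ratio fiber/ECM stiffness ratio
#' @param u optional displacement vector
#' @return dimensionless equivalent stiffness ratio
#' @export
equivalent_stiffness <- function(mesh, elem_region = mesh$elem_region,
                                 mu_ratio = 2, u = NULL) {
  vf <- volume_fractions(mesh, elem_region, u)
  vf[["V_f"]] * mu_ratio + vf[["V_ecm"]]
}

#' Angular distribution of bundle tip directions
#'
#' Tip angles are folded into `[0, pi]` (a direction and its opposite are
#' the same fiber orientation) and binned; each bin holds the fraction of
#' the total agent count `N`, so the bins sum to (agents counted) / N.
#'
#' @param theta tip angles (rad)
#' @param n_bins number of bins (>= 2)
#' @param n_total total agent count used for normalization (defaults to
#'   `length(theta)`)
#' @return list: `breaks`, `mid`, `freq` (normalized frequencies)
#' @export
angular_distribution <- function(theta, n_bins = 18, n_total = length(theta)) {
  stopifnot(n_bins >= 2)
  th <- theta[is.finite(theta)] %% pi
  breaks <- seq(0, pi, length.out = n_bins + 1)
  cut_idx <- pmin(pmax(findInterval(th, breaks, rightmost.closed = TRUE), 1L),
                  n_bins)
  freq <- tabulate(cut_idx, nbins = n_bins) / n_total
  list(breaks = breaks, mid = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
       freq = freq)
}

#' Number of bundles that reached the cortex
#'
#' @param status vector/factor of agent statuses
#' @return count of settled agents
#' @export
count_reached <- function(status) sum(status == "settled")

#' Metrics report for a simulation result
#'
#' Recomputes every readout from the stored mesh, displacement field, region
#' labels and trajectories of a [run_simulation()] result.
#'
#' @param result a `foldax_result`
#' @param n_bins bins for the angular distribution
#' @return list of class `foldax_metrics`: `GI`, `gyral_density_pct`,
#'   `sulcal_density_pct`, `n_reached`, `V_f`, `V_ecm`,
#'   `equivalent_stiffness`, `angular_hist`, `flags`
#' @export
metrics_report <- function(result, n_bins = 18) {
  mesh <- result$mesh
  u <- result$u
  pial <- polyline_deformed(mesh, u, mesh$pial)
  interf <- polyline_deformed(mesh, u, mesh$interface)
  labels <- classify_gyri_sulci(interf, pial)
  settled <- result$agents[result$agents$status == "settled", , drop = FALSE]
  dens <- fiber_density(cbind(settled$x_def, settled$y_def), labels, interf)
  vf <- volume_fractions(mesh, result$elem_region, u)
  ang <- angular_distribution(result$agents$theta, n_bins,
                              n_total = nrow(result$agents))
  structure(list(
    GI = gyrification_index(pial),
    gyral_density_pct = dens$gyral_density_pct,
    sulcal_density_pct = dens$sulcal_density_pct,
    settled_counts = dens$counts,
    n_reached = count_reached(result$agents$status),
    V_f = vf[["V_f"]], V_ecm = vf[["V_ecm"]],
    equivalent_stiffness = vf[["V_f"]] * result$config$mu_f_over_mu_s +
      vf[["V_ecm"]],
    angular_hist = ang,
    flags = result$flags), class = "foldax_metrics")
}

#' @export
print.foldax_metrics <- function(x, ...) {
  cat("foldax metrics report\n")
  cat(sprintf("  GI: %.4f\n", x$GI))
  cat(sprintf("  fiber density: %.1f%% gyral / %.1f%% sulcal (n settled = %d)\n",
              x$gyral_density_pct, x$sulcal_density_pct, x$n_reached))
  cat(sprintf("  V_f: %.4f, equivalent stiffness ratio: %.4f\n",
              x$V_f, x$equivalent_stiffness))
  invisible(x)
}
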