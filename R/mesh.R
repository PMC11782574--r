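#' Build the structured bilayer mesh
#'
#' Structured grid of 4-node quadrilaterals over a rectangular slice: a
#' white-matter slab of height `h` under a cortical plate of thickness `t_c`,
#' width `w`.  Elements whose centroid lies above `y = h` are labelled
#' cortex; all others start as ECM (fiber elements appear only by
#' conversion during a run).  Node numbering is row-major from the bottom
#' left; element nodes are counter-clockwise.
#'
#' @param w,h,t_c geometry (mm); see [simulation_config()]
#' @param elem_size element edge length (mm)
#' @return object of class `foldax_mesh`: `nodes` (n x 2 reference coords),
#'   `quads` (nel x 4 connectivity, 1-based CCW), `elem_region` (factor
#'   cortex/ecm/fiber), `sets` (left/right/bottom/top node indices),
#'   `interface` and `pial` (ordered node indices of the cortex-WM interface
#'   and the top surface), plus grid metadata
#' @export
build_bilayer_mesh <- function(w, h, t_c, elem_size) {
  if (w <= 0 || h <= 0 || t_c <= 0 || elem_size <= 0)
    stop("dimensions must be positive")
  if (t_c < elem_size) stop("cortex thickness must be >= element size")
  nex <- round(w / elem_size)
  ney <- round((h + t_c) / elem_size)
  if (abs(nex * elem_size - w) > 1e-8 || abs(ney * elem_size - (h + t_c)) > 1e-8)
    stop("elem_size must divide w and h + t_c")
  nnx <- nex + 1L
  nny <- ney + 1L
  xs <- (0:nex) * elem_size
  ys <- (0:ney) * elem_size
  nodes <- cbind(x = rep(xs, times = nny), y = rep(ys, each = nnx))
  node <- function(i, j) j * nnx + i + 1L  # i, j zero-based
  e_i <- rep(0:(nex - 1L), times = ney)
  e_j <- rep(0:(ney - 1L), each = nex)
  quads <- cbind(node(e_i, e_j), node(e_i + 1L, e_j),
                 node(e_i + 1L, e_j + 1L), node(e_i, e_j + 1L))
  cy <- (e_j + 0.5) * elem_size
  elem_region <- factor(ifelse(cy > h, "cortex", "ecm"),
                        levels = c("cortex", "ecm", "fiber"))
  sets <- list(left = node(0L, 0:ney), right = node(nex, 0:ney),
               bottom = node(0:nex, 0L), top = node(0:nex, ney))
  j_int <- round(h / elem_size)
  structure(list(nodes = nodes, quads = quads, elem_region = elem_region,
                 sets = sets, interface = node(0:nex, j_int),
                 pial = node(0:nex, ney),
                 w = w, h = h, t_c = t_c, elem_size = elem_size,
                 nex = nex, ney = ney, nnx = nnx, nny = nny),
            class = "foldax_mesh")
}

#' @export
print.foldax_mesh <- function(x, ...) {
  cat(sprintf("foldax bilayer mesh: %d x %d elements (%g mm), %d nodes\n",
              x$nex, x$ney, x$elem_size, nrow(x$nodes)))
  cat(sprintf("  cortex elements: %d, white matter: %d\n",
              sum(x$elem_region == "cortex"), sum(x$elem_region != "cortex")))
  invisible(x)
}

#' Reference Jacobians of all elements
#'
#' @param mesh a `foldax_mesh`
#' @return numeric vector of (constant) reference Jacobian determinants per
#'   element, evaluated at the centroid
#' @export
mesh_jacobians <- function(mesh) {
  q <- mesh$quads
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  # bilinear Jacobian at centroid
  0.25 * ((x[q[, 2]] - x[q[, 1]] + x[q[, 3]] - x[q[, 4]]) / 2 *
            (y[q[, 4]] - y[q[, 1]] + y[q[, 3]] - y[q[, 2]]) / 2 -
          (x[q[, 4]] - x[q[, 1]] + x[q[, 3]] - x[q[, 2]]) / 2 *
            (y[q[, 2]] - y[q[, 1]] + y[q[, 3]] - y[q[, 4]]) / 2) * 4
}

# deformed areas of all elements given a displacement vector (2N, interleaved)
element_areas_deformed <- function(mesh, u) {
  ux <- u[seq(1, length(u), 2)]
  uy <- u[seq(2, length(u), 2)]
  x <- mesh$nodes[, 1] + ux
  y <- mesh$nodes[, 2] + uy
  q <- mesh$quads
  0.5 * abs((x[q[, 3]] - x[q[, 1]]) * (y[q[, 4]] - y[q[, 2]]) -
            (x[q[, 4]] - x[q[, 2]]) * (y[q[, 3]] - y[q[, 1]]))
}

# element index of the grid cell containing a reference point
locate_cell <- function(mesh, p) {
  i <- min(max(floor(p[1] / mesh$elem_size), 0), mesh$nex - 1)
  j <- min(max(floor(p[2] / mesh$elem_size), 0), mesh$ney - 1)
  as.integer(j * mesh$nex + i + 1)
}

# deformed coordinates of an ordered node index set
polyline_deformed <- function(mesh, u, idx) {
  ux <- u[2 * idx - 1]
  uy <- u[2 * idx]
  cbind(x = mesh$nodes[idx, 1] + ux, y = mesh$nodes[idx, 2] + uy)
}

# does an ordered polyline self-intersect? (non-adjacent segment pairs)
polyline_self_intersects <- function(p) {
  n <- nrow(p) - 1
  if (n < 3) return(FALSE)
  seg_int <- function(a, b, c, d) {
    cr <- function(o, p1, p2)
      (p1[1] - o[1]) * (p2[2] - o[2]) - (p1[2] - o[2]) * (p2[1] - o[1])
    d1 <- cr(c, d, a); d2 <- cr(c, d, b); d3 <- cr(a, b, c); d4 <- cr(a, b, d)
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (seg_int(p[i, ], p[i + 1, ], p[j, ], p[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}
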