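# Shared fixtures and oracles for the test suite.

# deterministic random rotation about a random axis (3x3)
random_rotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# reduced-scale study configuration used by the coupled-run tests: a narrow
# deep slab that keeps the paper's axon-travel-versus-folding-onset timing
# while staying desk-tractable (see the methods vignette)
test_config <- function(...) {
  args <- modifyList(list(w = 12, h = 24, t_c = 1.2, elem_size = 0.4,
                          n_fibers = 20, agent_steps = 200, substeps = 50,
                          seed_band = 4, seed = 42), list(...))
  do.call(simulation_config, args)
}

# lazily cached ensembles shared across acceptance blocks
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

trend_ensemble <- function(key, n_replicates = 10, base_seed = 42, ...) {
  cached(key, {
    ens <- run_ensemble(test_config(...), n_replicates = n_replicates,
                        base_seed = base_seed)
    ens$results <- NULL  # keep the cache light
    ens
  })
}

# O(N) brute-force oracles -------------------------------------------------

# segment-vs-quad intersection: does segment (p0, p1) touch the axis-aligned
# cell [x0,x0+es] x [y0,y0+es]?  (Liang-Barsky clip)
segment_hits_cell <- function(p0, p1, x0, y0, es) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    lo <- c(x0, y0)[k]; hi <- lo + es
    if (abs(d[k]) < 1e-300) {
      if (p0[k] < lo || p0[k] > hi) return(FALSE)
    } else {
      ta <- (lo - p0[k]) / d[k]; tb <- (hi - p0[k]) / d[k]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

# all cells of a structured grid hit by a segment (oracle for traversal)
cells_hit_oracle <- function(mesh, p0, p1) {
  hits <- integer(0)
  for (e in seq_len(mesh$nex * mesh$ney)) {
    i <- (e - 1) %% mesh$nex
    j <- (e - 1) %/% mesh$nex
    if (segment_hits_cell(p0, p1, i * mesh$elem_size, j * mesh$elem_size,
                          mesh$elem_size))
      hits <- c(hits, e)
  }
  hits
}

# point-in-deformed-quad element search (oracle for probe_stress location)
locate_oracle <- function(mesh, u, p) {
  ux <- u[seq(1, length(u), 2)]; uy <- u[seq(2, length(u), 2)]
  x <- mesh$nodes[, 1] + ux; y <- mesh$nodes[, 2] + uy
  for (e in seq_len(nrow(mesh$quads))) {
    q <- mesh$quads[e, ]
    inside <- TRUE
    for (a in 1:4) {
      b <- q[c(2, 3, 4, 1)[a]]
      cr <- (x[b] - x[q[a]]) * (p[2] - y[q[a]]) -
            (y[b] - y[q[a]]) * (p[1] - x[q[a]])
      if (cr < -1e-12) { inside <- FALSE; break }
    }
    if (inside) return(e)
  }
  NA_integer_
}
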