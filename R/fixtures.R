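# Analytic stress-field fixtures and a mesh-free agent sandbox, so the agent
# model can be exercised and tested without any finite-element run.

#' Analytic stress field fixtures
#'
#' Closed-form Cauchy stress fields with documented principal directions:
#' * `uniform` — a constant tensor (`params$T`, 2x2 symmetric);
#' * `rotated_uniaxial` — uniaxial tension of magnitude `params$s` along a
#'   direction at `params$angle` rad from +x;
#' * `spatially_varying` — a base tensor plus componentwise linear
#'   gradients, `T(x) = T0 + x * Gx + y * Gy`;
#' * `degenerate` — an equibiaxial state `c * I` whose in-plane principal
#'   values are exactly equal everywhere (reorientation must be skipped).
#'
#' @param kind one of `"uniform"`, `"rotated_uniaxial"`,
#'   `"spatially_varying"`, `"degenerate"`
#' @param params list of parameters for the chosen kind
#' @return object of class `stress_field`: a list with `kind`, `params` and
#'   `evaluate(x)` returning a symmetric 2x2 stress at a position
#' @export
make_field <- function(kind = c("uniform", "rotated_uniaxial",
                                "spatially_varying", "degenerate"),
                       params = list()) {
  kind <- match.arg(kind)
  ev <- switch(kind,
    uniform = {
      T0 <- params$T
      if (is.null(T0)) stop("uniform field needs params$T")
      T0 <- (T0 + t(T0)) / 2
      function(x) T0
    },
    rotated_uniaxial = {
      ang <- params$angle %||% 0
      s <- params$s %||% 1
      d <- c(cos(ang), sin(ang))
      T0 <- s * tcrossprod(d)
      function(x) T0
    },
    spatially_varying = {
      T0 <- (params$T0 %||% diag(0, 2))
      Gx <- (params$Gx %||% diag(0, 2))
      Gy <- (params$Gy %||% diag(0, 2))
      sym <- function(A) (A + t(A)) / 2
      T0 <- sym(T0); Gx <- sym(Gx); Gy <- sym(Gy)
      function(x) T0 + x[1] * Gx + x[2] * Gy
    },
    degenerate = {
      cc <- params$c %||% 1
      function(x) diag(cc, 2)
    })
  structure(list(kind = kind, params = params, evaluate = ev),
            class = "stress_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the agent model against an analytic stress field
#'
#' Full agent dynamics (seeding, per-step noise, reorientation, tip + towed
#' elongation, termination at `y = h`) with the finite-element stress probe
#' replaced by an analytic evaluator — or by any function of position.
#' Deterministic under the configuration seed, using the same per-agent
#' streams as the coupled solver.
#'
#' @param field a [make_field()] fixture, or a `function(x)` returning a
#'   symmetric 2x2 stress
#' @param config a [simulation_config()]
#' @param n_steps number of agent steps
#' @param dt_agent time per agent step (day); defaults to the coupled
#'   loop's value `1 / (G_ctx * agent_steps)`
#' @return data.frame of trajectories: `id`, `step`, `x`, `y`, `theta`,
#'   `sigma`, `status`
#' @export
agent_sandbox <- function(field, config, n_steps,
                          dt_agent = 1 / (config$G_ctx * config$agent_steps)) {
  evaluate <- if (inherits(field, "stress_field")) field$evaluate else
    match.fun(field)
  b <- seed_bundles(config$n_fibers, config)
  noise <- lapply(seq_len(config$n_fibers), function(i)
    cpp_agent_noise(config$seed, i, n_steps))
  rows <- vector("list", config$n_fibers * n_steps)
  ri <- 0L
  for (k in seq_len(n_steps)) {
    for (i in seq_len(config$n_fibers)) {
      if (b$status[i] == "growing") {
        T2 <- evaluate(c(b$x[i], b$y[i]))
        b$theta[i] <- add_angle_noise(b$theta[i], config$noise_std,
                                      noise[[i]][k])
        pr <- principal_inplane(T2[1, 1], T2[2, 2], T2[1, 2],
                                tol_rel = config$degenerate_tol,
                                mu_ref = config$mu_s)
        nA <- c(cos(b$theta[i]), sin(b$theta[i]))
        if (config$reorientation_enabled && !pr$degenerate &&
            pr$sigma[1] >= 0) {
          nA <- reorient(nA, pr$n1, config$t_star, dt = 1)
          b$theta[i] <- atan2(nA[2], nA[1])
        }
        sig <- axial_stress(T2, nA)
        dL <- elongation_increment(sig, config, dt_agent)
        bi <- advance_tip(b[i, ], dL)
        b$x[i] <- bi$x; b$y[i] <- bi$y; b$length[i] <- bi$length
        if (b$x[i] < 0 || b$x[i] > config$w || b$y[i] < 0) {
          b$status[i] <- "stalled"
        } else if (b$y[i] >= config$h) {
          b$status[i] <- "settled"
        }
      } else sig <- NA_real_
      ri <- ri + 1L
      rows[[ri]] <- data.frame(id = i, step = k, x = b$x[i], y = b$y[i],
                               theta = b$theta[i], sigma = sig,
                               status = as.character(b$status[i]))
    }
  }
  out <- do.call(rbind, rows)
  out$status <- factor(out$status, levels = c("growing", "settled", "stalled"))
  out
}
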