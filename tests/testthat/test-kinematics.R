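# Growth-tensor kinematics and the neo-Hookean stress law.

test_that("cortical growth tensor has the tangential-growth structure", {
  expect_equal(cortical_growth_tensor(1, c(0, 1)), diag(3))
  expect_equal(cortical_growth_tensor(4, c(0, 1)), diag(c(2, 1, 2)))
  expect_equal(det(cortical_growth_tensor(2.5, c(0, 1))), 2.5,
               tolerance = 1e-12)
  # determinant equals the multiplier for arbitrary unit normals
  set.seed(11)
  for (i in 1:10) {
    n0 <- rnorm(3); n0 <- n0 / sqrt(sum(n0^2))
    th <- runif(1, 1, 5)
    expect_equal(det(cortical_growth_tensor(th, n0)), th, tolerance = 1e-10)
  }
  expect_error(cortical_growth_tensor(0.9, c(0, 1)), "multiplier")
  expect_error(cortical_growth_tensor(2, c(0, 2)), "unit")
})

test_that("subcortical growth tensor is isotropic with det = theta", {
  expect_equal(subcortical_growth_tensor(1), diag(3))
  expect_equal(subcortical_growth_tensor(8), 2 * diag(3))
  expect_equal(det(subcortical_growth_tensor(3.7)), 3.7, tolerance = 1e-12)
  expect_error(subcortical_growth_tensor(0.5), "multiplier")
})

test_that("growth multiplier kinetics integrate the linear rate law", {
  # closed form: theta(t) = 1 + G t, independent of step subdivision
  th <- 1
  for (i in 1:500) th <- advance_growth_multiplier(th, 0.02, 0.1)
  expect_equal(th, 2, tolerance = 1e-12)
  expect_equal(advance_growth_multiplier(1, 0.02, 50), 2)
  expect_equal(advance_growth_multiplier(1, 0, 10), 1)
  # cortex/ECM increments stay in the growth-rate ratio of 6
  d_ctx <- advance_growth_multiplier(1, 0.02, 5) - 1
  d_sub <- advance_growth_multiplier(1, 0.02 / 6, 5) - 1
  expect_equal(d_ctx / d_sub, 6, tolerance = 1e-12)
  # exponential switch integrates exactly
  expect_equal(advance_growth_multiplier(1, 0.02, 50, "exponential"), exp(1))
})

test_that("elastic part inverts the growth tensor", {
  Fg <- diag(c(2, 1, 2))
  expect_equal(elastic_part(Fg, Fg), diag(3))
  expect_equal(elastic_part(diag(3), Fg), diag(c(0.5, 1, 0.5)))
  set.seed(21)
  for (i in 1:10) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
    Fg <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
    expect_equal(elastic_part(F, Fg) %*% Fg, F, tolerance = 1e-12)
    expect_equal(det(F), det(elastic_part(F, Fg)) * det(Fg),
                 tolerance = 1e-10 * abs(det(F)))
  }
  expect_error(elastic_part(diag(3), matrix(0, 3, 3)), "singular")
})

test_that("neo-Hookean stress matches its analytic limits", {
  mu <- 100; k <- 5000
  expect_equal(cauchy_stress(diag(3), mu, k), matrix(0, 3, 3))
  # pure volumetric: isochoric part vanishes, pressure is k(lambda^3 - 1)
  lam <- 1.03
  T <- cauchy_stress(lam * diag(3), mu, k)
  expect_equal(T, k * (lam^3 - 1) * diag(3), tolerance = 1e-12)
  # simple shear at gamma = 0.1: T12 = mu * gamma exactly (J = 1)
  gam <- 0.1
  Fe <- diag(3); Fe[1, 2] <- gam
  T <- cauchy_stress(Fe, mu, k)
  expect_equal(T[1, 2], mu * gam, tolerance = 1e-12)
  expect_equal(T[2, 1], T[1, 2])
  expect_error(cauchy_stress(-diag(3), mu, k), "inversion")
})

test_that("free growth is stress-free for both growth modes", {
  mu <- 100; k <- 5000
  for (th in c(1, 1.5, 2, 4)) {
    for (Fg in list(cortical_growth_tensor(th, c(0, 1)),
                    subcortical_growth_tensor(th))) {
      T <- cauchy_stress(elastic_part(Fg, Fg), mu, k)
      expect_lt(max(abs(T)), 1e-9 * mu)
    }
  }
})

test_that("stress law is objective under superposed rotations", {
  mu <- 100; k <- 5000
  set.seed(31)
  Fe <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3)
  T <- cauchy_stress(Fe, mu, k)
  for (i in 1:5) {
    Q <- random_rotation()
    TQ <- cauchy_stress(Q %*% Fe, mu, k)
    expect_lt(max(abs(TQ - Q %*% T %*% t(Q))), 1e-9 * max(abs(T)))
  }
})

test_that("small strains recover linear elasticity with lambda = k - 2mu/3", {
  mu <- 100; k <- 5000
  lam <- k - 2 * mu / 3
  eps <- 1e-5
  set.seed(41)
  for (i in 1:5) {
    H <- matrix(rnorm(9), 3, 3)
    T <- cauchy_stress(diag(3) + eps * H, mu, k)
    E <- eps * (H + t(H)) / 2
    T_lin <- lam * sum(diag(E)) * diag(3) + 2 * mu * E
    # agreement to O(eps^2) in units of the elastic moduli
    expect_lt(max(abs(T - T_lin)), 50 * (mu + k) * eps^2)
  }
})

test_that("principal decomposition orders, reconstructs and flags ties", {
  p <- principal_decomposition(diag(c(2, 1, 0)))
  expect_equal(p$sigma, c(2, 1, 0))
  expect_equal(abs(p$n[, 1]), c(1, 0, 0))
  expect_false(p$degenerate)
  expect_true(principal_decomposition(diag(c(3, 3, 1)))$degenerate)
  # rotated uniaxial state: leading direction recovered at 37 degrees
  ang <- 37 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  T2 <- R %*% diag(c(5, 0)) %*% t(R)
  p <- principal_decomposition(T2)
  got <- atan2(p$n[2, 1], p$n[1, 1]) %% pi
  expect_equal(got, ang, tolerance = 1e-8)
  # reconstruction sum sigma_i n_i n_i^T
  set.seed(51)
  A <- matrix(rnorm(9), 3, 3); T3 <- (A + t(A)) / 2
  p <- principal_decomposition(T3)
  rec <- Reduce(`+`, lapply(1:3, function(i)
    p$sigma[i] * tcrossprod(p$n[, i])))
  expect_lt(max(abs(rec - T3)), 1e-8 * max(abs(T3)))
  # directions orthonormal
  expect_lt(max(abs(crossprod(p$n) - diag(3))), 1e-10)
  expect_error(principal_decomposition(matrix(c(0, 1, 0, 0), 2, 2)),
               "symmetric")
})

test_that("compiled constitutive path agrees with the R implementation", {
  mu <- 120; k <- 6000
  set.seed(61)
  for (region in c(0L, 1L)) {
    for (i in 1:5) {
      F2 <- diag(2) + matrix(rnorm(4, sd = 0.15), 2, 2)
      th_ctx <- runif(1, 1, 2); th_sub <- runif(1, 1, 1.3)
      s <- foldax:::cpp_stress_point(F2, region, th_ctx, th_sub, mu, k)
      Fg <- if (region == 1L) cortical_growth_tensor(th_ctx, c(0, 1)) else
        subcortical_growth_tensor(th_sub)
      F3 <- diag(3); F3[1:2, 1:2] <- F2
      T <- cauchy_stress(elastic_part(F3, Fg), mu, k)
      expect_equal(unname(s[c("T11", "T22", "T12", "T33")]),
                   c(T[1, 1], T[2, 2], T[1, 2], T[3, 3]), tolerance = 1e-12)
    }
  }
})
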