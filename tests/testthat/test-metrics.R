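# Gyrification index, gyral/sulcal classification, densities, volume
# fractions, stiffness maps and angular distributions.

test_that("gyrification index is exactly 1 for straight and convex lines", {
  x <- seq(0, 10, by = 0.1)
  expect_equal(gyrification_index(cbind(x, 0 * x)), 1)
  expect_equal(gyrification_index(cbind(x, 2 + 0.3 * x)), 1)
  # any convex arc: hull equals curve
  th <- seq(pi * 0.1, pi * 0.9, length.out = 200)
  arc <- cbind(5 * cos(th), 5 * sin(th))
  expect_equal(gyrification_index(arc), 1)
})

test_that("gyrification index of a sinusoid matches quadrature", {
  # y = sin(2 pi x / 10) sampled crest-to-crest (x in [2.5, 52.5]) so the
  # convex hull's upper chain is the straight crest line of length 50 and
  # the index is exactly (arc length) / 50, computable by quadrature
  A <- 1; lam <- 10
  f_arc <- function(x) sqrt(1 + (A * 2 * pi / lam * cos(2 * pi * x / lam))^2)
  arc_len <- integrate(f_arc, 2.5, 52.5, rel.tol = 1e-12)$value
  x <- seq(2.5, 52.5, length.out = 200001)
  gi <- gyrification_index(cbind(x, A * sin(2 * pi * x / lam)))
  expect_equal(gi, arc_len / 50, tolerance = 1e-6)
  expect_gte(gi, 1)
  # over a span with interior crests the hull climbs onto the crest line,
  # so the index is below the naive arc/x-extent ratio
  x2 <- seq(0, 60, length.out = 50001)
  gi2 <- gyrification_index(cbind(x2, A * sin(2 * pi * x2 / lam)))
  arc2 <- integrate(f_arc, 0, 60, rel.tol = 1e-12)$value
  expect_lt(gi2, arc2 / 60)
  expect_gt(gi2, 1)
})

test_that("gyral/sulcal classification follows the mid-surface level", {
  x <- seq(0, 20, by = 0.25)
  # flat geometry: every point on the reference level; tie rule -> gyral
  lab <- classify_gyri_sulci(cbind(x, 3), cbind(x, 4.5))
  expect_true(all(lab == "gyral"))
  # in-phase sinusoidal folds: crests gyral, troughs sulcal, full partition
  yi <- 3 + sin(2 * pi * x / 10)
  lab2 <- classify_gyri_sulci(cbind(x, yi), cbind(x, yi + 1.5))
  expect_true(all(lab2 %in% c("gyral", "sulcal")))
  expect_true(all(lab2[yi > 3 + 1e-9] == "gyral"))
  expect_true(all(lab2[yi < 3 - 1e-9] == "sulcal"))
  expect_error(classify_gyri_sulci(cbind(x, yi), cbind(x[-1], 1)), "matched")
})

test_that("fiber densities normalize to 100 with region-length weighting", {
  # 4 interface points at unit spacing: per-point lengths 0.5, 1, 1, 0.5,
  # so a gyral/gyral/sulcal/sulcal labelling gives equal 1.5 mm regions
  interface <- cbind(0:3, 0)
  labels <- c("gyral", "gyral", "sulcal", "sulcal")
  set.seed(8)
  tips <- cbind(c(runif(8, 0, 1.4), runif(2, 1.6, 3)), 0)
  d <- fiber_density(tips, labels, interface)
  expect_equal(d$gyral_density_pct, 80)
  expect_equal(d$sulcal_density_pct, 20)
  expect_equal(d$gyral_density_pct + d$sulcal_density_pct, 100)
  expect_equal(unname(d$region_lengths), c(1.5, 1.5))
  # all tips gyral
  d2 <- fiber_density(cbind(runif(5, 0, 1.4), 0), labels, interface)
  expect_equal(d2$gyral_density_pct, 100)
  # shrinking the sulcal region raises its raw density by the length ratio
  labels3 <- c("gyral", "gyral", "gyral", "sulcal")  # lengths 2.5 and 0.5
  d3 <- fiber_density(tips, labels3, interface)
  tips3_sulcal <- sum(tips[, 1] > 2.5)   # nearest-point reassignment
  raw_g <- (10 - tips3_sulcal) / 2.5; raw_s <- tips3_sulcal / 0.5
  expect_equal(d3$gyral_density_pct, 100 * raw_g / (raw_g + raw_s))
  # no settled tips: densities undefined
  d4 <- fiber_density(NULL, labels, interface)
  expect_true(is.na(d4$gyral_density_pct))
})

test_that("volume fractions sum to one and track conversions", {
  mesh <- build_bilayer_mesh(5, 4, 1, 0.5)
  vf <- volume_fractions(mesh)
  expect_equal(vf, c(V_f = 0, V_ecm = 1))
  reg <- mesh$elem_region
  wm <- which(reg == "ecm")
  reg[wm[1:20]] <- "fiber"   # 20 of 80 equal-area WM elements
  vf2 <- volume_fractions(mesh, reg)
  expect_equal(vf2, c(V_f = 0.25, V_ecm = 0.75))
  expect_equal(sum(vf2), 1, tolerance = 1e-12)
})

test_that("local stiffness map matches a Monte-Carlo disc oracle", {
  mesh <- build_bilayer_mesh(6, 4, 1, 0.1)
  reg <- mesh$elem_region
  set.seed(17)
  wm <- which(reg == "ecm")
  reg[sample(wm, length(wm) %/% 3)] <- "fiber"
  pts <- cbind(runif(5, 1.5, 4.5), runif(5, 1.5, 2.5))
  got <- local_stiffness_map(mesh, reg, points = pts, radius = 1,
                             mu_ratio = 2)
  # Monte-Carlo oracle: uniform samples in the disc, classified by cell
  for (i in seq_len(nrow(pts))) {
    ns <- 40000
    r <- sqrt(runif(ns)); a <- runif(ns, 0, 2 * pi)
    sx <- pts[i, 1] + r * cos(a); sy <- pts[i, 2] + r * sin(a)
    keep <- sx >= 0 & sx <= 6 & sy >= 0 & sy <= 4  # clip at domain
    ci <- pmin(pmax(floor(sx[keep] / 0.1), 0), mesh$nex - 1)
    cj <- pmin(pmax(floor(sy[keep] / 0.1), 0), mesh$ney - 1)
    e <- cj * mesh$nex + ci + 1
    wmk <- reg[e] != "cortex"
    vf <- mean(reg[e][wmk] == "fiber")
    expect_equal(got[i], vf * 2 + (1 - vf), tolerance = 0.01)
  }
  expect_true(all(got >= 1 & got <= 2))
  # limiting cases
  expect_equal(local_stiffness_map(mesh, mesh$elem_region,
                                   points = cbind(3, 2), radius = 1), 1)
  reg_all <- mesh$elem_region
  reg_all[reg_all == "ecm"] <- "fiber"
  expect_equal(local_stiffness_map(mesh, reg_all, points = cbind(3, 2),
                                   radius = 1, mu_ratio = 2), 2)
})

test_that("equivalent stiffness is the fraction-weighted modulus ratio", {
  mesh <- build_bilayer_mesh(4, 2, 1, 0.5)
  expect_equal(equivalent_stiffness(mesh), 1)
  reg <- mesh$elem_region
  wm <- which(reg == "ecm")
  reg[wm[seq_len(length(wm) / 2)]] <- "fiber"  # V_f = 0.5
  expect_equal(equivalent_stiffness(mesh, reg, mu_ratio = 2), 1.5)
})

test_that("angular distribution folds to [0, pi] and normalizes by N", {
  a <- angular_distribution(rep(pi / 2, 40), n_bins = 10)
  expect_equal(sum(a$freq), 1)
  expect_equal(max(a$freq), 1)
  expect_equal(a$mid[which.max(a$freq)], pi / 2, tolerance = pi / 10)
  # folding: a direction and its opposite share a bin
  a2 <- angular_distribution(c(pi / 4, pi / 4 + pi), n_bins = 8)
  expect_equal(max(a2$freq), 1)
  set.seed(3)
  a3 <- angular_distribution(runif(20000, 0, pi), n_bins = 10)
  expect_equal(a3$freq, rep(0.1, 10), tolerance = 0.05)
  # normalization by the full agent count bounds the mass at 1
  a4 <- angular_distribution(c(1, 2, NA), n_bins = 4, n_total = 3)
  expect_lte(sum(a4$freq), 1)
})

test_that("settled counts partition the agent population", {
  st <- factor(c("settled", "settled", "growing", "stalled"),
               levels = c("growing", "settled", "stalled"))
  expect_equal(count_reached(st), 2)
  expect_equal(count_reached(st) + sum(st == "growing") +
                 sum(st == "stalled"), length(st))
})
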