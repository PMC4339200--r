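# Scaffold quadric geometry: heights, normals, contact angles, rim samples,
# rigid placements.

test_that("surface height solves the quadric with the apex as reference", {
  sph <- scaffold_shape(rho_a = 5, rho_b = 5, r_a = 1, r_b = 1)
  expect_identical(surface_height(sph, 0, 0), 0)
  # spherical case: drop below apex at x = 1 is 5 - sqrt(24)
  expect_equal(-surface_height(sph, 1, 0), 5 - sqrt(24), tolerance = 1e-12)
  expect_equal(surface_height(sph, 0, 1), surface_height(sph, 1, 0))
  # saddle: the surface falls along the positively curved axis (x) and rises
  # along the negatively curved axis (y)
  sad <- scaffold_shape(rho_a = 5, rho_b = -5, r_a = 1, r_b = 1)
  expect_lt(surface_height(sad, 0.8, 0), 0)
  expect_gt(surface_height(sad, 0, 0.8), 0)
  # cylinder-like: flat along y
  cyl <- scaffold_shape(rho_a = 5, rho_b = Inf, r_a = 1, r_b = 1)
  expect_equal(surface_height(cyl, 0, 0.9), 0)
  expect_lt(surface_height(cyl, 0.9, 0), 0)
  expect_error(surface_height(sph, 1.2, 0.2), "footprint")
})

test_that("contact angle matches arcsin(r/rho) and carries the rho_b sign", {
  iso <- scaffold_shape(rho_a = 5, rho_b = 5, r_a = 1, r_b = 1)
  az <- seq(0, 350, by = 10)
  ca <- contact_angle(iso, az)
  expect_equal(ca, rep(asin(0.2) * 180 / pi, length(az)), tolerance = 1e-12)
  # monotone in r/rho for circular caps
  ratios <- c(0.1, 0.2, 0.4, 0.6)
  angs <- vapply(ratios, function(r)
    contact_angle(scaffold_shape(5, 5, 5 * r, 5 * r), 0), numeric(1))
  expect_true(all(diff(angs) > 0))
  expect_equal(angs, asin(ratios) * 180 / pi, tolerance = 1e-12)
  # BAR preset: long-axis contact angle is arcsin(6.5/8.5)
  bar <- shape_preset("endophilin_nbar", c_b = 0.2)
  expect_equal(contact_angle(bar, 0), asin(6.5 / 8.5) * 180 / pi,
               tolerance = 1e-12)
  # saddle short-axis angle is negative (inward tilt), long-axis positive
  sad <- scaffold_shape(rho_a = 5, rho_b = -5, r_a = 1, r_b = 1)
  expect_lt(contact_angle(sad, 90), 0)
  expect_gt(contact_angle(sad, 0), 0)
  expect_equal(sad$phi_b, -asin(0.2) * 180 / pi)
})

test_that("rim samples lie on both defining surfaces with analytic normals", {
  sh <- scaffold_shape(rho_a = 6, rho_b = -8, r_a = 1.2, r_b = 0.7)
  rs <- rim_samples(sh, 36)
  p <- rs$points
  # footprint cylinder residual
  expect_lt(max(abs((p[, 1] / sh$r_a)^2 + (p[, 2] / sh$r_b)^2 - 1)), 1e-10)
  # quadric residual (z unshifted)
  z <- p[, 3] + sh$rho_a
  res <- (p[, 1] / sh$rho_a)^2 + sign(sh$rho_b) * (p[, 2] / sh$rho_b)^2 +
    (z / sh$rho_a)^2 - 1
  expect_lt(max(abs(res)), 1e-10)
  # unit normals agreeing with finite differences of the height field
  expect_equal(rowSums(rs$normals^2), rep(1, 36), tolerance = 1e-12)
  eps <- 1e-7
  sc <- 1 - 1e-6
  hx <- (surface_height(sh, sc * p[, 1] + eps, sc * p[, 2]) -
           surface_height(sh, sc * p[, 1] - eps, sc * p[, 2])) / (2 * eps)
  hy <- (surface_height(sh, sc * p[, 1], sc * p[, 2] + eps) -
           surface_height(sh, sc * p[, 1], sc * p[, 2] - eps)) / (2 * eps)
  n_fd <- cbind(-hx, -hy, 1)
  n_fd <- n_fd / sqrt(rowSums(n_fd^2))
  # interior-offset finite differences approximate the rim normal to O(eps)
  n_an <- scaffold_normal(sh, sc * p[, 1], sc * p[, 2])
  expect_lt(max(abs(n_fd - n_an)), 1e-5)
  expect_error(rim_samples(sh, 8), "12")
})

test_that("scaffold area matches the spherical-cap closed form", {
  sph <- scaffold_shape(rho_a = 5, rho_b = 5, r_a = 1, r_b = 1)
  cap <- 2 * pi * 25 * (1 - cos(asin(0.2)))
  expect_equal(sph$A, cap, tolerance = 1e-6)
})

test_that("shape validation rejects invalid parameter sets", {
  expect_error(scaffold_shape(5, 5, -1, 1), "positive")
  expect_error(scaffold_shape(5, 5, 6, 1), "r_a < rho_a")
  expect_error(scaffold_shape(5, 2, 1, 2.5), "rho_b")
  expect_error(scaffold_shape(-5, 5, 1, 1), "rho_a")
})

test_that("pair placement is mirror-symmetric and rigid", {
  sh <- scaffold_shape(rho_a = 6, rho_b = 12, r_a = 1.5, r_b = 0.8)
  cfg <- pair_config(d = 6, phi = 30, theta = 5)
  pl <- place_pair(sh, cfg)
  rs <- rim_samples(sh, 24)
  p1 <- apply_transform(pl[[1]], rs$points)
  p2 <- apply_transform(pl[[2]], rs$points)
  # identity orientation gives pure translations
  pl0 <- place_pair(sh, pair_config(d = 6))
  expect_equal(pl0[[1]]$R, diag(3))
  expect_equal(pl0[[2]]$R, diag(3))
  q1 <- apply_transform(pl0[[1]], rs$points)
  expect_equal(sweep(q1, 2, c(-3, 0, 0)), unname(rs$points), tolerance = 1e-12)
  # mirror symmetry: reflecting placement 1 across x = 0 reproduces the
  # placement-2 point set (the quadric is even in both footprint axes)
  m1 <- p1 %*% diag(c(-1, 1, 1))
  match_dist <- vapply(seq_len(nrow(m1)), function(i)
    min(sqrt(rowSums(sweep(p2, 2, m1[i, ])^2))), numeric(1))
  expect_lt(max(match_dist), 1e-10)
  # rigid-body property: pairwise distances preserved
  d_loc <- as.matrix(dist(rs$points))
  expect_equal(as.matrix(dist(p1)), d_loc, tolerance = 1e-10)
  expect_equal(as.matrix(dist(p2)), d_loc, tolerance = 1e-10)
  # overlap guard reports the minimum allowed distance
  expect_error(place_pair(sh, pair_config(d = 2.0)), "minimum allowed d")
})

test_that("presets encode the documented geometries", {
  sh <- shape_preset("shallow_circular", cb_over_ca = 0.75)
  expect_equal(sh$r_a, 1)
  expect_equal(sh$r_a / sh$rho_a, 0.2)
  expect_equal(sh$c_b / sh$c_a, 0.75)
  cyl <- shape_preset("shallow_circular", cb_over_ca = 0)
  expect_identical(cyl$c_b, 0)
  bar <- shape_preset("endophilin_nbar", c_b = 0.2)
  expect_equal(c(bar$r_a, bar$r_b, bar$rho_a), c(6.5, 1.5, 8.5))
  expect_equal(bar$c_b, 0.2)
  expect_identical(bar$units, "nm")
})
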