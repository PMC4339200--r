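# Mesh construction, validity, regularization, refinement and mesh I/O.

test_that("single- and two-scaffold meshes have the expected topology", {
  p <- coarse_params()
  sh <- shape_preset("shallow_circular")
  m1 <- build_membrane_mesh(sh, NULL, p)
  v1 <- validate_mesh(m1)
  expect_equal(v1$loops, 2)          # collar hole + outer rim
  m2 <- build_membrane_mesh(sh, pair_config(5), p)
  v2 <- validate_mesh(m2)
  expect_equal(v2$loops, 3)          # two collar holes + outer rim
  expect_lt(v2$surface_residual, 1e-8 * sh$r_a)
  # at least 24 rim vertices per scaffold
  expect_gte(sum(m2$tags$kind == "rim" & m2$tags$sc == 1), 24)
  expect_gte(sum(m2$tags$kind == "rim" & m2$tags$sc == 2), 24)
  # patch radius covers 30x the larger of d and r_a
  expect_gte(m2$L, 30 * 5)
})

test_that("halving the edge length roughly quadruples the near-field density", {
  sh <- shape_preset("shallow_circular")
  m_c <- build_membrane_mesh(sh, pair_config(5), coarse_params())
  m_f <- build_membrane_mesh(sh, pair_config(5), coarse_params(h = m_c$h / 2))
  near <- function(m) sum(sqrt((abs(m$V[, 1]) - 2.5)^2 + m$V[, 2]^2) < 2)
  ratio <- near(m_f) / near(m_c)
  expect_gt(ratio, 2)
  expect_lt(ratio, 7)
})

test_that("regularization improves skewed flat meshes and fixes nothing else", {
  m <- as_membrane_fixture(make_flat_patch(12, 12, jitter = 0.35))
  a0 <- memscaffold:::min_triangle_angle(m)
  m2 <- regularize_mesh(m, n_smooth = 3, lambda = 0.5, flips = TRUE)
  a1 <- memscaffold:::min_triangle_angle(m2)
  expect_gt(a1, a0)
  # fixed (boundary) vertices untouched
  expect_equal(unname(m2$V[m$fixed, ]), unname(m$V[m$fixed, ]))
  # an already-uniform (equilateral) flat mesh is a fixed point away from
  # the ragged lattice boundary
  mu <- as_membrane_fixture(make_flat_hex(9, 0.1))
  mu2 <- regularize_mesh(mu, n_smooth = 2, lambda = 0.5, flips = TRUE)
  deep <- mu$V[, 1] > 0.18 & mu$V[, 1] < 0.62 &
    mu$V[, 2] > 0.18 & mu$V[, 2] < 0.52
  expect_lt(max(abs(mu2$V[deep, ] - mu$V[deep, ])), 1e-7)
})

test_that("subdivision re-projects new ring vertices onto the scaffold", {
  p <- coarse_params()
  sh <- shape_preset("shallow_circular", cb_over_ca = -0.75)
  m <- build_membrane_mesh(sh, pair_config(5, phi = 20, theta = 3), p)
  m2 <- subdivide_mesh(m)
  expect_equal(nrow(m2$F), 4 * nrow(m$F))
  expect_lt(memscaffold:::fixed_ring_residual(m2), 1e-8 * sh$r_a)
  v <- validate_mesh(m2)
  expect_equal(v$loops, 3)
  # new outer vertices back on the circle of radius L
  out2 <- which(m2$tags$kind == "outer")
  rr <- sqrt(m2$V[out2, 1]^2 + m2$V[out2, 2]^2)
  expect_lt(max(abs(rr - m2$L)), 1e-9 * m2$L)
})

test_that("mesh I/O round-trips through PLY and OFF", {
  p <- coarse_params()
  sh <- shape_preset("shallow_circular")
  m <- build_membrane_mesh(sh, NULL, p)
  tf <- tempfile(fileext = ".ply")
  write_mesh_ply(m, tf)
  back <- read_mesh_ply(tf)
  expect_equal(back$V, unname(m$V), tolerance = 1e-12)
  expect_identical(back$F, matrix(as.integer(m$F), ncol = 3))
  expect_identical(back$fixed, unname(m$fixed))
  tf2 <- tempfile(fileext = ".off")
  write_mesh_off(m, tf2)
  back2 <- read_mesh_off(tf2)
  expect_equal(back2$V, unname(m$V), tolerance = 1e-12)
  expect_identical(back2$F, matrix(as.integer(m$F), ncol = 3))
})
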