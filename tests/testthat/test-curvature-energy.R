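# Discrete curvature operator and Helfrich/tension energies against closed
# forms: sphere, cylinder, catenoid, flat patches; analytic gradient against
# finite differences; invariances.

test_that("icosphere curvature and bending energy match the closed forms", {
  p <- model_params(kappa = 20)
  for (R in c(1, 3.7)) {
    s <- make_icosphere(4, radius = R)
    cf <- vertex_total_curvature(s)
    expect_equal(mean(cf$J), 2 / R, tolerance = 0.01)
    en <- bending_energy(s, p)
    expect_equal(en$bending, 8 * pi * p$kappa, tolerance = 0.01)
  }
})

test_that("flat interiors have exactly zero curvature and energy", {
  m <- make_flat_patch(12, 12, jitter = 0.2)
  cf <- vertex_total_curvature(m)
  expect_lt(max(cf$J[m$interior], na.rm = TRUE), 1e-10)
  expect_lt(bending_energy(m, model_params())$bending, 1e-20)
  expect_identical(tension_energy(as_membrane_fixture(m), model_params()), 0)
})

test_that("cylinder and catenoid curvatures approach 1/rho and 0", {
  cyl <- make_cylinder(radius = 2, height = 8, n_theta = 64, n_z = 40)
  cf <- vertex_total_curvature(cyl)
  expect_equal(mean(cf$J[cyl$interior]), 1 / 2, tolerance = 0.01)
  cat1 <- make_catenoid(1, 0.8, 48, 14)
  cat2 <- make_catenoid(1, 0.8, 96, 28)
  e1 <- bending_energy(cat1, model_params())$bending
  e2 <- bending_energy(cat2, model_params())$bending
  expect_lt(e2, e1 / 2)      # refinement drives the energy toward zero
  expect_lt(e2, 0.1)
})

test_that("mixed Voronoi areas partition the total mesh area", {
  m <- make_flat_patch(10, 10, jitter = 0.3)
  m$V[, 3] <- 0.2 * sin(3 * m$V[, 1]) * cos(2 * m$V[, 2])
  cf <- vertex_total_curvature(m)
  expect_equal(sum(cf$A_mixed), mesh_area(m), tolerance = 1e-10)
})

test_that("analytic energy gradient matches central finite differences", {
  m <- make_flat_patch(7, 7, jitter = 0.3)
  set.seed(11)
  m$V[, 3] <- 0.15 * sin(4 * m$V[, 1]) * cos(3 * m$V[, 2]) +
    0.02 * runif(nrow(m$V))
  mask <- rep(TRUE, nrow(m$V))
  F0 <- m$F - 1L
  r <- memscaffold:::mesh_energy_cpp(m$V, F0, mask, 20, 0.7, 0.9, TRUE)
  hh <- 1e-6
  idx <- cbind(sample(nrow(m$V), 20, replace = TRUE),
               sample(3, 20, replace = TRUE))
  for (k in seq_len(nrow(idx))) {
    Vp <- m$V; Vm <- m$V
    Vp[idx[k, 1], idx[k, 2]] <- Vp[idx[k, 1], idx[k, 2]] + hh
    Vm[idx[k, 1], idx[k, 2]] <- Vm[idx[k, 1], idx[k, 2]] - hh
    fd <- (memscaffold:::mesh_energy_cpp(Vp, F0, mask, 20, 0.7, 0.9, FALSE)$E -
             memscaffold:::mesh_energy_cpp(Vm, F0, mask, 20, 0.7, 0.9, FALSE)$E) / (2 * hh)
    expect_equal(r$grad[idx[k, 1], idx[k, 2]], fd, tolerance = 1e-5)
  }
})

test_that("bending energy is invariant under rigid motions and scaling", {
  s <- make_icosphere(3, radius = 2)
  p <- model_params(kappa = 20, gamma = 0.3)
  e0 <- bending_energy(s, p)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  s_rot <- s
  s_rot$V <- sweep(s$V %*% Rz, 2, c(0.3, -1, 2), "+")
  e_rot <- bending_energy(s_rot, p)
  expect_equal(e_rot$bending, e0$bending, tolerance = 1e-12)
  # scale-free bending; tension term scales with the area (s^2)
  s_sc <- s
  s_sc$V <- 2.5 * s$V
  e_sc <- bending_energy(s_sc, p)
  expect_equal(e_sc$bending, e0$bending, tolerance = 1e-12)
  expect_equal(e_sc$tension / e0$tension, 2.5^2, tolerance = 1e-12)
})

test_that("degenerate triangles are reported by index", {
  m <- make_flat_patch(5, 5)
  m$V[m$F[3, 2], ] <- m$V[m$F[3, 1], ]
  expect_error(vertex_total_curvature(m), "triangle")
})
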