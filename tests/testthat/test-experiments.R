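# The scripted figure-level sweeps run end-to-end on reduced grids and emit
# well-formed CSV output.  (The tension and asymmetric-orientation controls
# run with their full logic in the acceptance suite.)

test_that("curvature-anisotropy and aspect-ratio sweeps run end-to-end", {
  p <- model_params(profile = "coarse", d_ref_factor = 10)
  outdir <- tempfile("sweeps")
  res <- run_shallow_curvature_sweep(ratios = -0.75, d_grid = c(3, 4.5, 7),
                                     params = p, outdir = outdir,
                                     phi_grid = c(0, 45, 90),
                                     theta_grid = c(0, 1, 2))
  cur <- res[["cb_over_ca_-0.75"]]
  expect_s3_class(cur, "interaction_curve")
  expect_true(all(is.finite(cur$F_el)))
  # saddle-like anisotropy attracts at these distances
  expect_lt(min(cur$F_el), 0)
  f <- file.path(outdir, "shallow_cb_over_ca_-0.75.csv")
  expect_true(file.exists(f))
  expect_true(file.exists(paste0(f, ".manifest")))
  back <- read_curve(f)
  expect_equal(back$F_el, signif(cur$F_el, 12))

  res2 <- run_aspect_ratio_sweep(aspects = 2, d_grid = c(3.5, 5, 8),
                                 params = p, phi_grid = c(0, 45, 90),
                                 theta_grid = c(0, 1, 2))
  cur2 <- res2[["aspect_2"]]
  expect_s3_class(cur2, "interaction_curve")
  # elongation-driven anisotropy also produces far-field attraction
  expect_lt(cur2$F_el[cur2$d == 8], 0.05)
})

test_that("the BAR sweep produces a deep well and exports meshes", {
  p <- model_params(profile = "coarse", d_ref_factor = 10)
  outdir <- tempfile("bar")
  res <- run_bar_sweep(c_b_values = 0.05, d_grid = c(5, 7, 10), params = p,
                       outdir = outdir, mesh_outdir = outdir,
                       phi_grid = 90, theta_grid = c(0, 4, 8, 16))
  cur <- res[["cb_0.05"]]
  expect_lt(min(cur$F_el), -5)
  ply <- list.files(outdir, pattern = "\\.ply$", full.names = TRUE)
  expect_length(ply, 1)
  mesh <- read_mesh_ply(ply)
  expect_gt(nrow(mesh$V), 100)
  expect_true(any(mesh$fixed))
})

test_that("the free-energy sweep returns referenced curves", {
  p <- model_params(profile = "coarse", d_ref_factor = 10, n_phi = 3,
                    n_theta = 4)
  res <- run_free_energy_sweep(ratios = -1, d_grid = c(3.2, 4.5),
                               params = p, phi_grid = c(0, 45, 90),
                               theta_grid = c(0, 1, 2))
  fe <- res[["cb_over_ca_-1"]]
  expect_s3_class(fe, "free_energy_curve")
  expect_equal(fe$F_ent, fe$F - fe$F_el, tolerance = 1e-12)
  ref <- which(fe$d == attr(fe, "d_ref"))
  expect_equal(fe$F[ref], 0)
})
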