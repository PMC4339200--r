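# Interaction-energy assembly: power-law fits, curve minima, orientation
# optimization, and the free-energy identity on a small case.

test_that("power-law fit recovers a constructed exponent exactly", {
  d <- c(3, 4, 6, 8, 12, 16)
  cur <- data.frame(d = d, F_el = 7.3 / d^3)
  pf <- fit_power_law(cur, c(3, 16))
  expect_equal(unname(coef(pf)["exponent"]), -3, tolerance = 1e-10)
  expect_equal(predict(pf, data.frame(d = 5)), 7.3 / 125, tolerance = 1e-9)
  # attractive branch keeps its sign
  cur2 <- data.frame(d = d, F_el = -2 / d^2)
  pf2 <- fit_power_law(cur2, c(3, 16))
  expect_equal(unname(coef(pf2)["exponent"]), -2, tolerance = 1e-10)
  expect_identical(pf2$sign, -1)
  # guard rails
  expect_error(fit_power_law(data.frame(d = d, F_el = c(1, 1, -1, 1, 1, 1))),
               "sign")
  expect_error(fit_power_law(data.frame(d = d[1:3], F_el = d[1:3])), "4 points")
})

test_that("curve_minimum interpolates a quadratic minimum", {
  d <- seq(2, 6, by = 0.5)
  cur <- data.frame(d = d, F_el = (d - 3.3)^2 - 1)
  mn <- curve_minimum(cur)
  expect_true(mn$interior)
  expect_equal(mn$d_star, 3.3, tolerance = 1e-9)
  expect_equal(mn$depth, -1, tolerance = 1e-9)
  # edge minimum flagged
  mn2 <- curve_minimum(data.frame(d = d, F_el = d))
  expect_false(mn2$interior)
})

test_that("axisymmetric scaffolds have phi-independent energy", {
  p <- coarse_params()
  sh <- shape_preset("shallow_circular")
  d <- 5
  ev <- memscaffold:::fm_evaluator(sh, d, p)
  f0 <- ev$fm(0, 2)
  f45 <- ev$fm(45, 2)
  expect_lt(abs(f0 - f45), 2 * p$tol_energy)
  # tie-break reports phi* = 0
  opt <- optimal_orientation(sh, d, p)
  expect_identical(opt$phi_star, 0)
  expect_gt(opt$theta_star, 0)   # caps tilt away from each other
})

test_that("free energy obeys F_ent = F - F_el exactly and is referenced", {
  p <- coarse_params(n_theta = 4)
  sh <- shape_preset("shallow_circular")
  fe <- free_energy_curve(sh, 6, p)
  expect_equal(fe$F_ent, fe$F - fe$F_el, tolerance = 1e-12)
  ref <- which(fe$d == attr(fe, "d_ref"))
  expect_equal(fe$F[ref], 0)
  expect_equal(fe$F_el[ref], 0)
  expect_equal(fe$F_ent[ref], 0)
})
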