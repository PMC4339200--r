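# Monge-gauge linearized solver sanity: grid convergence and the qualitative
# behaviour it must share with the mesh engine.

test_that("linearized pair energy is grid-consistent and repulsive", {
  sh <- shape_preset("shallow_circular")
  p <- model_params()
  e1 <- monge_pair_energy(sh, 6, p, half_width = 14, n = 101)$energy
  e2 <- monge_pair_energy(sh, 6, p, half_width = 14, n = 151)$energy
  expect_gt(e1, 0)
  expect_lt(abs(e1 - e2) / e2, 0.2)
  # the pair energy decreases with separation (repulsive interaction); the
  # distances stay well clear of the clamped box edge
  hw <- 17
  ee <- vapply(c(4, 6, 9), function(d)
    monge_pair_energy(sh, d, p, half_width = hw, n = 201)$energy, numeric(1))
  expect_true(all(diff(ee) < 0))
  # strong mirror-symmetric tilts are penalized quadratically
  e_t0 <- monge_pair_energy(sh, 6, p, half_width = hw, n = 201)$energy
  e_t12 <- monge_pair_energy(sh, 6, p, half_width = hw, n = 201, theta = 12)$energy
  expect_gt(e_t12, e_t0)
})
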