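test_that("complex conductivity matches direct arithmetic and limits", {
  # zero conductivity: purely imaginary j*omega*eps0*eps
  v <- complex_conductivity(dielectric_material(78, 0), 2 * pi * 1e6)
  expect_equal(Re(v), 0)
  expect_equal(Im(v), 2 * pi * 1e6 * 8.854e-12 * 78)

  # frozen hand evaluation at the stretching-buffer values
  v2 <- complex_conductivity(dep_medium(), 2 * pi * 1e6)
  expect_equal(Re(v2), 5.29e-3)
  expect_equal(Im(v2), 4.339243171e-3, tolerance = 1e-9)

  # high-frequency limit: imaginary part dominates
  v3 <- complex_conductivity(dep_medium(), 2 * pi * 1e12)
  expect_gt(Mod(Im(v3)) / Mod(Re(v3)), 1e5)

  expect_error(complex_conductivity(dep_medium(), -1), "omega")
})

test_that("Clausius-Mossotti factor: identity, DC limits, frozen value", {
  med <- dep_medium()
  same <- cell_dielectric(cytoplasm = dielectric_material(78, 5.29e-3))
  expect_equal(clausius_mossotti(same, med, 2 * pi * 1e6)$real_part, 0,
               tolerance = 1e-12)

  # DC conductivity limits of the homogeneous-sphere formula
  hi <- cell_dielectric(cytoplasm = dielectric_material(60, 50))
  expect_equal(clausius_mossotti(hi, med, 2 * pi * 1e-2)$real_part, 1,
               tolerance = 1e-3)
  lo <- cell_dielectric(cytoplasm = dielectric_material(60, 0))
  expect_equal(clausius_mossotti(lo, med, 2 * pi * 1e-2)$real_part, -0.5,
               tolerance = 1e-3)

  # frozen independent complex-arithmetic evaluation; pDEP at 1 MHz
  k <- clausius_mossotti(cell_dielectric(), med, 2 * pi * 1e6)
  expect_equal(k$real_part, 0.9213652110, tolerance = 1e-9)
  expect_gt(k$real_part, 0)
})

test_that("Re[K] stays within [-0.5, 1] over physical parameter sweeps", {
  withr::with_seed(42, {
    for (rep in 1:200) {
      cell <- cell_dielectric(cytoplasm = dielectric_material(
        runif(1, 1, 120), 10^runif(1, -6, 1)))
      med <- dielectric_material(runif(1, 1, 120), 10^runif(1, -6, 1))
      f <- 10^runif(1, 0, 9)
      re_k <- clausius_mossotti(cell, med, 2 * pi * f)$real_part
      expect_gte(re_k, -0.5 - 1e-9)
      expect_lte(re_k, 1 + 1e-9)
    }
  })
})

test_that("crossover frequency agrees with a dense grid scan", {
  med <- dep_medium()
  # low-conductivity, high-permittivity particle: conduction-dominated
  # nDEP at low f, dielectric pDEP at high f -> one crossover
  p <- cell_dielectric(cytoplasm = dielectric_material(100, 1e-4))
  f_x <- crossover_frequency(p, med, 1e3, 5e7)
  expect_false(is.null(f_x))
  expect_lt(abs(clausius_mossotti(p, med, 2 * pi * f_x)$real_part), 1e-6)

  # oracle: densest sign change on 1000 log-spaced points
  fs <- exp(seq(log(1e3), log(5e7), length.out = 1000))
  re <- clausius_mossotti(p, med, 2 * pi * fs)$real_part
  flip <- which(sign(re[-1]) * sign(re[-1000]) < 0)[1]
  expect_gte(f_x, fs[flip])
  expect_lte(f_x, fs[flip + 1])

  # the default homogeneous cell has sigma_c >> sigma_m: pDEP over the whole
  # experimental bracket, so no crossover is reported
  expect_null(crossover_frequency(cell_dielectric(), med, 1e2, 5e6))
})

test_that("EDM force formula: zeros and direct arithmetic", {
  cell <- cell_dielectric()
  med <- dep_medium()
  expect_equal(dep_force_edm(cell, med, 0.9, c(0, 0)), c(0, 0))
  expect_equal(dep_force_edm(cell, med, 0, c(1e15, -2e15)), c(0, 0))
  g <- c(3e14, -1e15)
  expect_equal(dep_force_edm(cell, med, 0.92, g),
               2 * pi * (7e-6)^3 * 8.854e-12 * 78 * 0.92 * g)
})

test_that("simplified force reproduces quadratic scaling and units", {
  cell <- cell_dielectric()
  med80 <- dep_medium(rel_permittivity = 80)
  f2 <- dep_force_simplified(drive(2), 20e-6, cell, med80)
  expect_equal(f2, 0.25 * 8.854e-12 * 80 * (2 / 20e-6)^2 * 4 * pi * (7e-6)^2)
  expect_equal(dep_force_simplified(drive(0), 20e-6, cell, med80), 0)
  f4 <- dep_force_simplified(drive(4), 20e-6, cell, med80)
  expect_equal(f4 / f2, 4)
  # linear in the medium permittivity
  f2b <- dep_force_simplified(drive(2), 20e-6, cell,
                              dep_medium(rel_permittivity = 40))
  expect_equal(f2 / f2b, 2)
  expect_error(dep_force_simplified(drive(2), -1e-6), "gap")
})

test_that("voltage conversions are inverse and halving", {
  expect_equal(vpp_to_amplitude(8), 4)
  expect_equal(amplitude_to_vpp(vpp_to_amplitude(3.7)), 3.7)
})
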