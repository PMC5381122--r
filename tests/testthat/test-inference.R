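test_that("modulus fit: exact line, scaling, equivariance, R^2", {
  r0 <- 7e-6
  area <- pi * r0^2
  s <- c(0.05, 0.1, 0.15, 0.2)
  cv <- strain_force_curve(tibble::tibble(force_N = 50 * s * area,
                                          strain_mean = s))
  mf <- estimate_modulus(cv, r0)
  expect_equal(mf$modulus, 50)
  expect_equal(mf$r_squared, 1)
  # doubling the forces doubles the modulus
  cv2 <- cv; cv2$force_N <- 2 * cv$force_N
  expect_equal(estimate_modulus(cv2, r0)$modulus, 100)
  # r0 equivariance under the cross-section convention
  expect_equal(estimate_modulus(cv, 2 * r0)$modulus, 50 / 4)
  # surface convention is 4x smaller stress
  expect_equal(estimate_modulus(cv, r0, "surface")$modulus, 50 / 4)
  # degenerate all-zero strains
  cv0 <- strain_force_curve(tibble::tibble(force_N = c(1e-9, 2e-9),
                                           strain_mean = c(0, 0)))
  expect_error(estimate_modulus(cv0), class = "cytostretch_degenerate_error")
})

test_that("network-generated curves are near-linear in stress-strain", {
  cv <- simulate_stretch_curve(small_params(), test_forces, replicates = 3,
                               seed = 12, config = fast_config())
  mf <- estimate_modulus(cv)
  expect_gt(mf$r_squared, 0.95)
})

test_that("fit with no free parameters returns the plain loss", {
  cv <- simulate_stretch_curve(small_params(), test_forces[1:3],
                               replicates = 2, seed = 4,
                               config = fast_config())
  fit <- fit_parameters(cv, character(0), fixed = small_params(),
                        replicates = 2, seed = 4, config = fast_config())
  expect_equal(fit$n_evaluations, 1L)
  expect_identical(fit$params_hat, small_params())
  # same seed, same protocol: the model reproduces the curve exactly
  expect_equal(fit$loss, 0)
})

test_that("loss at the optimum never exceeds the starting loss", {
  cv <- simulate_stretch_curve(small_params(c_af = 20), test_forces[1:3],
                               replicates = 2, seed = 8,
                               config = fast_config())
  fit <- fit_parameters(cv, "c_af", bounds = list(c_af = c(10, 40)),
                        fixed = small_params(), replicates = 2, seed = 8,
                        config = fast_config(), max_evals = 15)
  start_loss <- fit$trace$loss[1]
  expect_lte(fit$loss, start_loss)
  expect_equal(min(fit$trace$loss), fit$loss)
  expect_true(all(fit$theta[["c_af"]] >= 10 & fit$theta[["c_af"]] <= 40))
})

test_that("single-parameter recovery on a noiseless self-generated curve", {
  truth <- small_params()
  cfg <- fast_config()
  cv <- simulate_stretch_curve(truth, test_forces, replicates = 3, seed = 5,
                               config = cfg)
  fit <- fit_parameters(cv, "c_af", bounds = list(c_af = c(5, 40)),
                        fixed = truth, replicates = 3, seed = 5,
                        config = cfg, max_evals = 20)
  expect_lt(abs(fit$theta[["c_af"]] - truth$c_af) / truth$c_af, 0.1)
})

test_that("identifiability guard warns on over-parameterized fits", {
  cv <- strain_force_curve(tibble::tibble(force_N = test_forces,
                                          strain_mean = 1:5 * 0.03))
  expect_warning(
    fit_parameters(cv, c("c_af", "delta_r0", "r_e", "r_i"),
                   fixed = small_params(), replicates = 1, seed = 1,
                   config = relax_config(max_iterations = 10), max_evals = 6),
    "weakly identified")
})

test_that("invalid fit setups error cleanly", {
  cv <- strain_force_curve(tibble::tibble(force_N = test_forces[1:2],
                                          strain_mean = c(0.1, 0.2)))
  expect_error(fit_parameters(cv, "c_af"), "3 force levels")
  cv3 <- strain_force_curve(tibble::tibble(force_N = test_forces[1:3],
                                           strain_mean = 1:3 / 10))
  expect_error(fit_parameters(cv3, "not_a_param"), "among")
  expect_error(fit_parameters(cv3, "c_af", bounds = list(c_af = c(5, 5))),
               "lower < upper")
})

test_that("group comparison: identity, halved strains, modulus ratio", {
  cv <- strain_force_curve(tibble::tibble(force_N = test_forces,
                                          strain_mean = 1:5 * 0.04))
  same <- compare_groups(cv, cv)
  expect_equal(same$modulus_ratio, 1)
  expect_equal(same$verdict, "indistinguishable")

  half <- cv; half$strain_mean <- cv$strain_mean / 2
  cmp <- compare_groups(cv, half)
  expect_equal(cmp$modulus_ratio, 2)
  expect_equal(cmp$verdict, "b stiffer")
  expect_equal(cmp$levels$strain_diff, -cv$strain_mean / 2)

  far <- strain_force_curve(tibble::tibble(force_N = test_forces + 1,
                                           strain_mean = 1:5 * 0.04))
  expect_error(compare_groups(cv, far), "overlap")
})

test_that("tidy and glance methods return the documented shapes", {
  cv <- simulate_stretch_curve(small_params(), test_forces[1:3],
                               replicates = 2, seed = 4,
                               config = fast_config())
  fit <- fit_parameters(cv, character(0), fixed = small_params(),
                        replicates = 2, seed = 4, config = fast_config())
  expect_named(tidy(fit), c("parameter", "estimate"))
  expect_named(glance(fit), c("loss", "n_evaluations", "converged"))
  mf <- estimate_modulus(cv)
  expect_named(glance(mf),
               c("modulus", "r_squared", "area_convention", "n_levels"))
  net <- build_network(small_params(), 1)
  td <- tidy(net)
  expect_named(td, c("vertex", "x", "y", "z", "pole"))
  expect_equal(nrow(td), nrow(net$vertices))
})
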