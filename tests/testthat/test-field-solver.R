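# Coarse grids (h = 1 um) keep these fast; the acceptance suite re-checks
# the same physics at the production grid.

test_that("parallel-plate fixture reproduces the analytic capacitor field", {
  chip <- fixture_chip("parallel_plate", grid_spacing = 1e-6)
  sol <- solve_potential(chip, dep_medium(), 2 * pi * 1e6)
  e_exact <- chip$driven_potential / chip$domain_height
  expect_lt(max(abs(sqrt(sol$e2) - e_exact)) / e_exact, 1e-3)
  # no field gradient: EDM force density vanishes
  g <- grad_e2_at(sol, c(50e-6, 25e-6))
  expect_lt(sqrt(sum(g^2)), 1e-3 * e_exact^2 / chip$domain_height)
})

test_that("a particle made of the medium does not perturb the solution", {
  chip <- coarse_chip()
  med <- dep_medium()
  p <- particle_inclusion(c(50e-6, 25e-6), 7e-6, med)
  s0 <- solve_potential(chip, med, 2 * pi * 1e6)
  s1 <- solve_potential(chip, med, 2 * pi * 1e6, p)
  expect_lt(max(Mod(s1$phi - s0$phi)), 1e-8 * chip$driven_potential)
})

test_that("solution scales linearly in U; forces quadratically", {
  med <- dep_medium()
  chip1 <- coarse_chip(driven_potential = 1)
  chip3 <- coarse_chip(driven_potential = 3)
  s1 <- solve_potential(chip1, med, 2 * pi * 1e6)
  s3 <- solve_potential(chip3, med, 2 * pi * 1e6)
  expect_equal(s3$phi, 3 * s1$phi, tolerance = 1e-10)
  pr <- c(40e-6, 10e-6)
  expect_equal(grad_e2_at(s3, pr), 9 * grad_e2_at(s1, pr),
               tolerance = 1e-10)
  p <- chip_particle(chip1)
  sp1 <- solve_potential(chip1, med, 2 * pi * 1e6, p)
  sp3 <- solve_potential(chip3, med, 2 * pi * 1e6, p)
  expect_equal(integrate_mst(sp3), 9 * integrate_mst(sp1),
               tolerance = 1e-9)
})

test_that("mirror symmetry: x-gradient vanishes on the midplane", {
  # symmetric electrodes about the gap center
  chip <- coarse_chip()
  sol <- solve_potential(chip, dep_medium(), 2 * pi * 1e6)
  g <- grad_e2_at(sol, c(chip$domain_width / 2, 10e-6))
  # |E|^2 is symmetric even though phi is antisymmetric
  scale <- sqrt(sum(grad_e2_at(sol, c(40e-6, 10e-6))^2))
  expect_lt(abs(g[1]), 0.02 * scale)
})

test_that("MST on a non-perturbing inclusion in a uniform field is ~zero", {
  chip <- fixture_chip("parallel_plate", grid_spacing = 1e-6)
  med <- dep_medium()
  p <- particle_inclusion(c(50e-6, 25e-6), 7e-6, med)
  sol <- solve_potential(chip, med, 2 * pi * 1e6, p)
  f <- integrate_mst(sol)
  e <- chip$driven_potential / chip$domain_height
  bound <- 1e-3 * 0.25 * 8.854e-12 * med$rel_permittivity * e^2 *
    2 * p$radius * chip$out_of_plane_thickness
  expect_lt(sqrt(sum(f^2)), bound)
})

test_that("discrete conservation: net flux through a closed contour ~ 0", {
  chip <- coarse_chip()
  med <- dep_medium()
  sol <- solve_potential(chip, med, 2 * pi * 1e6)
  # closed rectangular contour in the source-free medium (constant
  # coefficient): the net normal flux of E must vanish
  x0 <- 25e-6; x1 <- 75e-6; y0 <- 10e-6; y1 <- 40e-6
  m <- 200
  xs <- seq(x0, x1, length.out = m); ys <- seq(y0, y1, length.out = m)
  dlx <- (x1 - x0) / (m - 1); dly <- (y1 - y0) / (m - 1)
  ex <- function(px, py) cytostretch:::interp_grid(sol$ex, sol$x, sol$y, px, py)
  ey <- function(px, py) cytostretch:::interp_grid(sol$ey, sol$x, sol$y, px, py)
  flux <- sum(ey(xs, rep(y1, m))) * dlx - sum(ey(xs, rep(y0, m))) * dlx +
    sum(ex(rep(x1, m), ys)) * dly - sum(ex(rep(x0, m), ys)) * dly
  circ <- sum(Mod(ey(xs, rep(y0, m)))) * dlx + sum(Mod(ey(xs, rep(y1, m)))) * dlx +
    sum(Mod(ex(rep(x0, m), ys))) * dly + sum(Mod(ex(rep(x1, m), ys))) * dly
  expect_lt(Mod(flux) / circ, 0.02)
})

test_that("probe validation and solver configuration errors", {
  chip <- coarse_chip()
  sol <- solve_potential(chip, dep_medium(), 2 * pi * 1e6)
  expect_error(grad_e2_at(sol, c(-1e-6, 10e-6)),
               class = "cytostretch_range_error")
  expect_error(field_at(sol, c(200e-6, 10e-6)),
               class = "cytostretch_range_error")
  # no Dirichlet segment -> configuration error
  bad <- coarse_chip()
  bad$electrodes <- list()
  expect_error(solve_potential(bad, dep_medium(), 2 * pi * 1e6),
               class = "cytostretch_config_error")
  # particle outside the domain
  expect_error(
    solve_potential(chip, dep_medium(), 2 * pi * 1e6,
                    particle_inclusion(c(1e-6, 1e-6), 7e-6)),
    "inside the domain")
})

test_that("fixture chips satisfy their stated geometry", {
  pp <- fixture_chip("parallel_plate")
  expect_equal(pp$gap, pp$domain_height)
  sides <- vapply(pp$electrodes, `[[`, "", "side")
  expect_setequal(sides, c("bottom", "top"))
  tt <- fixture_chip("tip_to_tip")
  expect_equal(tt$gap, 20e-6)
  expect_true(all(vapply(tt$electrodes, `[[`, "", "side") == "bottom"))
})
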