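test_that("contour length: R-dropout, scaling law, frozen arithmetic", {
  # R = 1 removes the crosslink-density factor
  expect_equal(contour_length(1, 7, 15),
               100 * (7 / 2) * sqrt(pi / 15) * 1e-3)
  # doubling C_AF divides L_c by sqrt(2) exactly
  expect_equal(contour_length(3, 7, 10) / contour_length(3, 7, 20), sqrt(2))
  # frozen independent evaluation (R=2, d=7 nm, C_AF=15 uM)
  expect_equal(contour_length(2, 7, 15), 0.1839938684, tolerance = 1e-9)
  expect_error(contour_length(-1, 7, 15), "> 0")
})

test_that("WLC force law: zero, monotonicity, divergence, frozen value", {
  expect_equal(wlc_force(0, 0, l_p = 10, l_c = 0.3), 0)
  # continuous and strictly increasing through delta_r + delta_r0 = 0
  lim <- wlc_extension_limit(10, 0.3)
  xs <- seq(-0.4, 0.9, by = 0.05) * lim
  fs <- vapply(xs, wlc_force, 0, delta_r0 = 0, l_p = 10, l_c = 0.3)
  expect_true(all(diff(fs) > 0))
  expect_lt(abs(wlc_force(1e-9, 0, 10, 0.3) - wlc_force(-1e-9, 0, 10, 0.3)),
            1e-15)
  # unbounded growth approaching the extension limit
  expect_gt(wlc_force(lim * 0.999, 0, 10, 0.3), 1e4 * wlc_force(lim / 2, 0, 10, 0.3))
  expect_error(wlc_force(lim, 0, 10, 0.3), class = "cytostretch_domain_error")
  expect_error(wlc_force(lim * 1.5, 0, 10, 0.3),
               class = "cytostretch_domain_error")
  # prestress shifts the operating point: f(0; dr0) = f(dr0; 0)
  expect_equal(wlc_force(0, 1e-4, 10, 0.3), wlc_force(1e-4, 0, 10, 0.3))
  # frozen arbitrary-precision oracle (dr = 0.01 um, Lp = 10 um, Lc = 1 um)
  expect_equal(wlc_force(0.01, 0, 10, 1, 300), 1.612969745e-12,
               tolerance = 1e-8)
})

test_that("ABP force is Hookean", {
  expect_equal(abp_force(0, 1e-3), 0)
  expect_equal(abp_force(0.2, 1e-3), 2 * abp_force(0.1, 1e-3))
  expect_equal(abp_force(0.1, 1e-5), 1e-12)
  expect_equal(abp_force(-0.1, 1e-5), -1e-12)
})

test_that("network build: determinism, shell containment, crosslink rule", {
  p <- network_params(n_af = 500)
  n1 <- build_network(p, 7)
  n2 <- build_network(p, 7)
  expect_identical(n1$vertices, n2$vertices)
  expect_identical(n1$abp_edges, n2$abp_edges)
  n3 <- build_network(p, 8)
  expect_false(identical(n1$vertices, n3$vertices))

  # all endpoints in the shell
  r <- sqrt(rowSums(n1$vertices^2))
  expect_true(all(r >= p$r_i - 1e-9 & r <= p$r_e + 1e-9))
  # filament rest length equals the contour length
  expect_equal(unique(n1$fil_edges$rest), n1$lc)
  # realized crosslink count within 5% of the density rule R * N_AF
  expect_gte(nrow(n1$abp_edges), 0.95 * round(p$r_crosslink * p$n_af))
  expect_lte(nrow(n1$abp_edges), round(p$r_crosslink * p$n_af))
  # per-end multiplicity cap respected
  ends <- c(n1$abp_edges$a, n1$abp_edges$b)
  expect_lte(max(table(ends)), p$max_abp_per_end)
  # pole caps: disjoint, within the cap half-angle
  expect_length(intersect(n1$pole_plus, n1$pole_minus), 0)
  cosx <- n1$vertices[n1$pole_plus, 1] /
    sqrt(rowSums(n1$vertices[n1$pole_plus, , drop = FALSE]^2))
  expect_true(all(cosx >= cos(p$cap_angle_deg * pi / 180) - 1e-12))
})

test_that("single-filament build has no crosslinks", {
  p <- network_params(n_af = 1)
  net <- suppressWarnings(build_network(p, 3))
  expect_equal(nrow(net$fil_edges), 1)
  expect_equal(nrow(net$abp_edges), 0)
})

test_that("infeasible placement errors out", {
  # contour length larger than the cell: impossible to place in the shell
  expect_error(
    build_network(network_params(n_af = 10, lc_scale = 1e4), 1),
    class = "cytostretch_config_error")
})

test_that("strain definition: identity, affine stretch, reported deformation scale", {
  net <- build_network(small_params(), 1)
  expect_equal(strain_of(net, net), 0)
  stretched <- net
  stretched$vertices[, 1] <- 1.2 * net$vertices[, 1]
  expect_equal(strain_of(stretched, net), 0.2, tolerance = 1e-12)
  # a 7 um half-extent cloud stretched to 8.61 um reads strain 0.23, the
  # deformation scale reported for leukemia cells at the top DEP force
  cell_like <- net
  cell_like$vertices <- net$vertices * (7 / max(abs(net$vertices[, 1])))
  pulled <- cell_like
  pulled$vertices[, 1] <- pulled$vertices[, 1] * (8.61 / 7)
  expect_equal(round(strain_of(pulled, cell_like), 2), 0.23)
  other <- build_network(small_params(), 2)
  expect_error(strain_of(net, other), "topology")
})
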