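# Shared small fixtures; everything is generated in code at test time.

fast_config <- function(max_iterations = 1000) {
  relax_config(max_iterations = max_iterations)
}

small_params <- function(...) {
  network_params(n_af = 150, ...)
}

test_forces <- c(0.5, 1, 1.6, 2.2, 2.9) * 1e-9

# Minimal hand-built two-vertex network: one filament along x at its rest
# (contour) length, poles = the two vertices.
two_vertex_network <- function(params = network_params(n_af = 1, delta_r0 = 0)) {
  lc <- contour_length(params$r_crosslink, params$d_actin, params$c_af,
                       params$lc_scale)
  structure(list(
    vertices = rbind(c(-lc / 2, 0, 0), c(lc / 2, 0, 0)),
    fil_edges = tibble::tibble(a = 1L, b = 2L, rest = lc),
    abp_edges = tibble::tibble(a = integer(0), b = integer(0),
                               rest = numeric(0)),
    pole_plus = 2L, pole_minus = 1L, lc = lc, params = params, seed = 0L),
    class = "actin_network")
}

coarse_chip <- function(h = 1e-6, ...) chip_model(grid_spacing = h, ...)
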