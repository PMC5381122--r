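#' Coarse-grained actin network parameters
#'
#' Structural and material parameters of the shell-like cortical actin
#' network: filaments are straight WLC segments of contour length
#' [contour_length()] placed in the spherical shell `[r_i, r_e]`, crosslinked
#' at their endpoints by Hookean ABP springs. Geometry defaults are
#' leukemia-cell scale (external radius 7.02 um, internal radius 6.21 um,
#' F-actin concentration 15 uM); the remaining constants are documented
#' modeling choices, all configurable.
#'
#' @param r_e External shell radius in um.
#' @param r_i Internal shell radius in um (`0 < r_i < r_e`).
#' @param c_af F-actin concentration in uM.
#' @param r_crosslink Crosslink density R: target ABP crosslinks per
#'   filament (also enters the contour-length relation), default 4.
#' @param n_af Number of coarse-grained filaments, default 500. Each
#'   coarse filament stands for a bundle of real filaments; counts in the
#'   hundreds keep relaxation tractable while preserving network statistics.
#' @param l_p Persistence length in um, default 10 (F-actin scale).
#' @param d_actin Filament diameter in nm, default 7.
#' @param k_c Single-ABP spring stiffness scale in N/m at the reference
#'   concentration, default `2e-3` (filamin-like pN/nm scale; the edge
#'   stiffness actually used is [kc_effective()], which scales this with
#'   `(c_af/caf_ref)^1.5`). Calibrated so nanoNewton loads on the default
#'   network give strains on the 0.1--0.3 scale seen in electro-deformation.
#' @param delta_r0 Filament pre-extension (prestress) in um, default `1e-4`
#'   (0.1 nm, well inside the WLC extension limit).
#' @param temperature Absolute temperature in K, default 300.
#' @param eta Cytoplasm viscosity in Pa s, default `1e-3`.
#' @param lc_scale Contour-length conversion constant, see
#'   [contour_length()].
#' @param capture_radius ABP wiring capture radius in um: two filament
#'   endpoints closer than this may be joined by an ABP. The default
#'   (`NULL`) scales with the mean endpoint spacing,
#'   `2.6 * (V_shell / (2 n_af))^(1/3)` (about 2 um at the default
#'   `n_af = 500`), so the wiring target stays reachable and the wired
#'   network percolates pole to pole at any coarse-graining level.
#' @param max_abp_per_end Maximum ABPs attached to one filament end,
#'   default 6.
#' @param caf_ref Reference F-actin concentration in uM for the
#'   [kc_effective()] coarse-graining rule, default 15.
#' @param cap_angle_deg Half-angle of the polar caps over which the
#'   stretching load is distributed, default 30 degrees.
#' @return An object of class `network_params`.
#' @export
#' @examples
#' network_params()
network_params <- function(r_e = 7.02, r_i = 6.21, c_af = 15,
                           r_crosslink = 4, n_af = 500,
                           l_p = 10, d_actin = 7, k_c = 2e-3,
                           delta_r0 = 1e-4, temperature = 300, eta = 1e-3,
                           lc_scale = 100, capture_radius = NULL,
                           max_abp_per_end = 6, cap_angle_deg = 30,
                           caf_ref = 15) {
  if (!(r_i > 0 && r_i < r_e)) abort("Need 0 < r_i < r_e.")
  if (c_af <= 0) abort("`c_af` must be > 0.")
  if (n_af < 1) abort("`n_af` must be >= 1.")
  if (l_p <= 0 || d_actin <= 0 || k_c < 0 || temperature <= 0 || eta <= 0)
    abort("Material parameters must be positive.")
  if (delta_r0 < 0) abort("`delta_r0` must be >= 0.")
  lc <- contour_length(r_crosslink, d_actin, c_af, lc_scale)
  if (delta_r0 >= wlc_extension_limit(l_p, lc, 0))
    abort("`delta_r0` is at/beyond the WLC extension limit for these parameters.")
  if (is.null(capture_radius)) {
    shell_vol <- 4 / 3 * pi * (r_e^3 - r_i^3)
    capture_radius <- 2.6 * (shell_vol / (2 * n_af))^(1 / 3)
  }
  structure(list(r_e = r_e, r_i = r_i, c_af = c_af,
                 r_crosslink = r_crosslink, n_af = as.integer(n_af),
                 l_p = l_p, d_actin = d_actin, k_c = k_c,
                 delta_r0 = delta_r0, temperature = temperature, eta = eta,
                 lc_scale = lc_scale, capture_radius = capture_radius,
                 max_abp_per_end = as.integer(max_abp_per_end),
                 cap_angle_deg = cap_angle_deg, caf_ref = caf_ref),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(paste0("<network_params> shell [%g, %g] um, C_AF = %g uM, ",
                     "R = %g, N_AF = %d, L_c = %.3g um\n"),
              x$r_i, x$r_e, x$c_af, x$r_crosslink, x$n_af,
              contour_length(x$r_crosslink, x$d_actin, x$c_af, x$lc_scale)))
  invisible(x)
}

#' Effective coarse-grained crosslinker stiffness
#'
#' Each ABP edge of the coarse network stands for the bundle of physical
#' crosslinkers that would occupy its neighborhood in the real cortex. At a
#' fixed crosslink density R the number of physical crosslinkers scales with
#' the filament number density, which is proportional to
#' \eqn{C_{AF}/L_c \propto C_{AF}^{3/2}} (since \eqn{L_c \propto
#' C_{AF}^{-1/2}}). The effective edge stiffness is therefore
#' \deqn{k_c^{eff} = k_c\,(C_{AF}/C_{ref})^{3/2},\qquad C_{ref} = 15\,uM,}
#' which is how the F-actin concentration enters the mechanics of the
#' coarse model (denser actin, stiffer network).
#'
#' @param params A [network_params()].
#' @return Stiffness in N/m.
#' @export
kc_effective <- function(params) {
  params$k_c * (params$c_af / params$caf_ref)^1.5
}

# simple union-find for connected components
components_of <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# all endpoint pairs closer than `radius`, excluding same-filament pairs;
# block-wise to bound memory. Returns matrix (a, b, dist) with a < b.
close_pairs <- function(pts, radius, filament_id) {
  n <- nrow(pts)
  out <- vector("list", 0)
  block <- 512L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    idx <- s:e
    d2 <- outer(pts[idx, 1], pts[, 1], "-")^2 +
      outer(pts[idx, 2], pts[, 2], "-")^2 +
      outer(pts[idx, 3], pts[, 3], "-")^2
    hit <- which(d2 <= radius^2, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    a <- idx[hit[, 1]]; b <- hit[, 2]
    keep <- a < b & filament_id[a] != filament_id[b]
    if (!any(keep)) next
    out[[length(out) + 1]] <-
      cbind(a = a[keep], b = b[keep],
            dist = sqrt(d2[hit][keep]))
  }
  if (length(out) == 0) return(matrix(numeric(0), 0, 3,
                                      dimnames = list(NULL, c("a", "b", "dist"))))
  do.call(rbind, out)
}

#' Build a random actin network
#'
#' Places `n_af` straight filament segments of contour length [contour_length()]
#' in the shell `[r_i, r_e]` (midpoints uniform in the shell volume,
#' orientations uniform on the sphere, endpoint rejection sampling with
#' bounded retries), then wires ABP crosslinks between filament endpoints:
#' candidate endpoint pairs closer than `capture_radius` are added in random
#' order, each end hosting at most `max_abp_per_end` springs, until the
#' target crosslink count `round(r_crosslink * n_af)` is reached. ABP rest
#' lengths equal the as-built endpoint separation, so the unloaded,
#' prestress-free network is in equilibrium by construction. Polar caps of
#' half-angle `cap_angle_deg` about the +/- x axis define the pole vertex
#' sets for load application. Fully deterministic for a fixed seed.
#'
#' @param params A [network_params()].
#' @param seed Integer RNG seed.
#' @return An object of class `actin_network`: `vertices` (n x 3 matrix,
#'   um), `fil_edges` / `abp_edges` tibbles, `pole_plus` / `pole_minus`
#'   index vectors, `lc`, `params`, `seed`.
#' @export
#' @examples
#' net <- build_network(network_params(n_af = 50), seed = 1)
#' net
build_network <- function(params, seed) {
  stopifnot(inherits(params, "network_params"))
  seed <- as.integer(seed)
  lc <- contour_length(params$r_crosslink, params$d_actin, params$c_af,
                       params$lc_scale)
  if (lc >= 2 * params$r_e)
    abort("Contour length exceeds the cell diameter; infeasible placement.",
          class = "cytostretch_config_error")
  withr::with_seed(seed, {
    n_af <- params$n_af
    ends_a <- matrix(NA_real_, n_af, 3)
    ends_b <- matrix(NA_real_, n_af, 3)
    placed <- 0L
    tries <- 0L
    max_tries <- 10000L
    while (placed < n_af) {
      m <- max(2L * (n_af - placed), 64L)
      u <- runif(m)
      rad <- (params$r_i^3 + u * (params$r_e^3 - params$r_i^3))^(1 / 3)
      dirm <- matrix(rnorm(3 * m), m, 3)
      dirm <- dirm / sqrt(rowSums(dirm^2))
      mid <- dirm * rad
      ori <- matrix(rnorm(3 * m), m, 3)
      ori <- ori / sqrt(rowSums(ori^2))
      pa <- mid + (lc / 2) * ori
      pb <- mid - (lc / 2) * ori
      ra <- sqrt(rowSums(pa^2)); rb <- sqrt(rowSums(pb^2))
      ok <- ra >= params$r_i & ra <= params$r_e &
        rb >= params$r_i & rb <= params$r_e
      k <- which(ok)
      if (length(k) > 0) {
        k <- k[seq_len(min(length(k), n_af - placed))]
        rows <- placed + seq_along(k)
        ends_a[rows, ] <- pa[k, , drop = FALSE]
        ends_b[rows, ] <- pb[k, , drop = FALSE]
        placed <- placed + length(k)
      }
      tries <- tries + 1L
      if (tries > max_tries)
        abort("Could not place filaments in the shell (too many rejections).",
              class = "cytostretch_config_error")
    }
    vertices <- rbind(ends_a, ends_b)     # vertex i and i + n_af are one filament
    fil_edges <- tibble(a = seq_len(n_af), b = seq_len(n_af) + n_af,
                        rest = rep(lc, n_af))
    filament_id <- rep(seq_len(n_af), 2)

    target <- round(params$r_crosslink * n_af)
    abp_edges <- tibble(a = integer(0), b = integer(0), rest = numeric(0))
    if (target > 0 && n_af > 1) {
      cand <- close_pairs(vertices, params$capture_radius, filament_id)
      if (nrow(cand) > 0) {
        ord <- sample.int(nrow(cand))
        cand <- cand[ord, , drop = FALSE]
        used <- integer(nrow(vertices))
        sel <- logical(nrow(cand))
        n_sel <- 0L
        for (k in seq_len(nrow(cand))) {
          a <- cand[k, 1]; b <- cand[k, 2]
          if (used[a] < params$max_abp_per_end &&
              used[b] < params$max_abp_per_end) {
            used[a] <- used[a] + 1L; used[b] <- used[b] + 1L
            sel[k] <- TRUE
            n_sel <- n_sel + 1L
            if (n_sel >= target) break
          }
        }
        picked <- cand[sel, , drop = FALSE]
        abp_edges <- tibble(a = as.integer(picked[, 1]),
                            b = as.integer(picked[, 2]),
                            rest = as.numeric(picked[, 3]))
      }
    }
    cosc <- cos(params$cap_angle_deg * pi / 180)
    vr <- sqrt(rowSums(vertices^2))
    cosx <- vertices[, 1] / pmax(vr, 1e-12)
    pole_plus <- which(cosx >= cosc)
    pole_minus <- which(cosx <= -cosc)
    if (length(pole_plus) == 0 || length(pole_minus) == 0)
      warn("Empty pole cap; the network cannot be loaded as built.")
    structure(list(vertices = vertices, fil_edges = fil_edges,
                   abp_edges = abp_edges, pole_plus = pole_plus,
                   pole_minus = pole_minus, lc = lc, params = params,
                   seed = seed),
              class = "actin_network")
  })
}

#' @export
print.actin_network <- function(x, ...) {
  cat(sprintf(paste0("<actin_network> %d vertices, %d filaments, %d ABPs, ",
                     "poles %d/%d, seed %d\n"),
              nrow(x$vertices), nrow(x$fil_edges), nrow(x$abp_edges),
              length(x$pole_plus), length(x$pole_minus), x$seed))
  invisible(x)
}

#' Stretching load specification
#'
#' The total stretching force is distributed over the pole caps: each vertex
#' of the +x cap receives an equal share of `+total_force` along x, each
#' vertex of the -x cap an equal share of `-total_force` (a DEP-like
#' distributed pull; net force on the cell is zero). `mode = "point"`
#' instead loads only the extreme vertex of each cap, mimicking an optical
#' tweezers bead contact. Load is restricted to cap vertices belonging to
#' the largest connected component, which is the part of the network that
#' can transmit stress between the poles.
#'
#' @param total_force Total stretching force in N (>= 0).
#' @param mode `"cap"` (default) or `"point"`.
#' @return An object of class `load_spec`.
#' @export
load_spec <- function(total_force, mode = c("cap", "point")) {
  stopifnot(is.numeric(total_force), length(total_force) == 1,
            total_force >= 0)
  structure(list(total_force = total_force, mode = match.arg(mode)),
            class = "load_spec")
}

# n x 3 matrix of external per-vertex forces (N)
external_forces <- function(network, load) {
  n <- nrow(network$vertices)
  ext <- matrix(0, n, 3)
  if (is.null(load) || load$total_force == 0) return(ext)
  edges <- rbind(as.matrix(network$fil_edges[, c("a", "b")]),
                 as.matrix(network$abp_edges[, c("a", "b")]))
  comp <- components_of(n, edges)
  giant <- as.integer(names(which.max(table(comp))))
  pp <- intersect(network$pole_plus, which(comp == giant))
  pm <- intersect(network$pole_minus, which(comp == giant))
  if (length(pp) == 0 || length(pm) == 0)
    abort("Pole caps are not connected through the network; cannot load.",
          class = "cytostretch_config_error")
  if (load$mode == "point") {
    pp <- pp[which.max(network$vertices[pp, 1])]
    pm <- pm[which.min(network$vertices[pm, 1])]
  }
  ext[pp, 1] <- load$total_force / length(pp)
  ext[pm, 1] <- -load$total_force / length(pm)
  ext
}

#' Forces on all network vertices
#'
#' Sum of WLC filament forces, Hookean ABP forces and the external load on
#' every vertex. Uses the compiled force kernel; [vertex_force()] is an
#' independent pure-R evaluation of the same sum for one vertex.
#'
#' @param network An [build_network()] result.
#' @param load A [load_spec()] or `NULL`.
#' @param strict Error if any filament extension lies beyond the exact WLC
#'   domain (default `FALSE`: such filaments use the integrator's linear
#'   continuation, and the forces reported match what the integrator saw).
#' @return n x 3 matrix of forces in N.
#' @export
network_forces <- function(network, load = NULL, strict = FALSE) {
  stopifnot(inherits(network, "actin_network"))
  p <- network$params
  ext <- external_forces(network, load)
  res <- network_forces_cpp(
    network$vertices * 1e-6,
    as.matrix(network$fil_edges[, c("a", "b")]) - 1L,
    network$fil_edges$rest * 1e-6,
    as.matrix(network$abp_edges[, c("a", "b")]) - 1L,
    network$abp_edges$rest * 1e-6,
    ext,
    physical_constants()$kB * p$temperature,
    p$l_p * 1e-6, network$lc * 1e-6, p$delta_r0 * 1e-6, kc_effective(p), 0.2)
  if (strict && !res$in_domain)
    abort("WLC extension outside its domain.", class = "cytostretch_domain_error")
  res$forces
}

#' Force on a single vertex (pure R)
#'
#' Independent evaluation of the per-vertex force balance
#' \eqn{F_i = \sum f_a + \sum f_c + f_s} from the scalar force laws
#' [wlc_force()] and [abp_force()]; used to cross-check the compiled kernel.
#'
#' @param network An [build_network()] result.
#' @param i Vertex index.
#' @param load A [load_spec()] or `NULL`.
#' @return Numeric length-3 force in N.
#' @export
vertex_force <- function(network, i, load = NULL) {
  stopifnot(inherits(network, "actin_network"))
  n <- nrow(network$vertices)
  if (!(i >= 1 && i <= n)) abort("Invalid vertex index.")
  p <- network$params
  pos <- network$vertices
  f <- c(0, 0, 0)
  add_edge <- function(f, a, b, rest, wlc) {
    other <- if (a == i) b else a
    d <- pos[other, ] - pos[i, ]
    len <- sqrt(sum(d^2))
    mag <- if (wlc) {
      wlc_force(len - rest, p$delta_r0, p$l_p, network$lc, p$temperature)
    } else {
      abp_force(len - rest, kc_effective(p))
    }
    f + mag * d / len
  }
  fe <- network$fil_edges
  for (k in which(fe$a == i | fe$b == i))
    f <- add_edge(f, fe$a[k], fe$b[k], fe$rest[k], wlc = TRUE)
  ae <- network$abp_edges
  for (k in which(ae$a == i | ae$b == i))
    f <- add_edge(f, ae$a[k], ae$b[k], ae$rest[k], wlc = FALSE)
  f + external_forces(network, load)[i, ]
}

#' Axial strain between two network configurations
#'
#' Strain is `(r - r0) / r0` with `r` the half-extent of the vertex cloud
#' along the stretch (x) axis.
#'
#' @param deformed,reference `actin_network` objects with identical topology.
#' @return Dimensionless strain.
#' @export
strain_of <- function(deformed, reference) {
  stopifnot(inherits(deformed, "actin_network"),
            inherits(reference, "actin_network"))
  if (nrow(deformed$vertices) != nrow(reference$vertices) ||
      !identical(deformed$fil_edges[, c("a", "b")],
                 reference$fil_edges[, c("a", "b")]) ||
      !identical(deformed$abp_edges[, c("a", "b")],
                 reference$abp_edges[, c("a", "b")]))
    abort("Networks do not share the same topology.")
  r <- diff(range(deformed$vertices[, 1])) / 2
  r0 <- diff(range(reference$vertices[, 1])) / 2
  (r - r0) / r0
}
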