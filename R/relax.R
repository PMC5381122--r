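#' Relaxation configuration
#'
#' Controls the integrator that drives the network to mechanical
#' equilibrium, i.e. to \eqn{\max_i |F_i| <} `force_tolerance`.
#' `method = "euler"` integrates the overdamped limit
#' \eqn{\eta \dot r_i = F_i} with explicit Euler steps and adaptive step
#' halving (on WLC-domain violations or force blow-up). `method = "fire"`
#' (default) integrates the inertial form \eqn{m_i\ddot r_i = F_i} with
#' FIRE-style adaptive damping -- velocities are mixed toward the force
#' direction and zeroed whenever power becomes negative, which plays the
#' role of the viscous term while converging to the same equilibria in far
#' fewer steps on stiff networks.
#'
#' @param method `"fire"` (default) or `"euler"`.
#' @param fictitious_mass Vertex mass in kg for the inertial mode; `NULL`
#'   (default) auto-scales from the stiffest spring in the network.
#' @param time_step Initial time step in s; `NULL` auto-scales.
#' @param max_iterations Iteration cap, default `30000`.
#' @param force_tolerance Absolute floor of the convergence threshold on
#'   the max vertex force in N, default `1e-13`.
#' @param rel_tolerance Relative part of the convergence threshold: the
#'   effective tolerance is `max(force_tolerance, rel_tolerance * s)` with
#'   `s` the largest per-vertex applied force, default 0.02. Residual
#'   forces 50x below the local load leave position slack far below the
#'   deformation scale being measured.
#' @param drag_radius Effective Stokes radius of a vertex in m (drag
#'   `gamma = 6 pi eta a`), default `1e-7`; used by the overdamped mode.
#' @param dt_max_factor Upper bound on the adaptive step, as a multiple of
#'   the initial step, default 1000.
#' @param domain_margin Fraction of the WLC extension range near either
#'   divergence over which the integrator replaces the exact force law by
#'   its C1 linear continuation, default 0.2. The continuation only
#'   engages at per-filament tensions far above the applied load scale, so
#'   converged equilibria are unaffected; it exists to keep transient
#'   integrator overshoots finite.
#' @return An object of class `relax_config`.
#' @export
relax_config <- function(method = c("fire", "euler"),
                         fictitious_mass = NULL, time_step = NULL,
                         max_iterations = 30000, force_tolerance = 1e-13,
                         rel_tolerance = 0.02,
                         drag_radius = 1e-7, dt_max_factor = 1000,
                         domain_margin = 0.2) {
  method <- match.arg(method)
  if (!is.null(time_step) && time_step <= 0) abort("`time_step` must be > 0.")
  if (force_tolerance <= 0) abort("`force_tolerance` must be > 0.")
  structure(list(method = method, fictitious_mass = fictitious_mass,
                 time_step = time_step,
                 max_iterations = as.integer(max_iterations),
                 force_tolerance = force_tolerance,
                 rel_tolerance = rel_tolerance,
                 drag_radius = drag_radius, dt_max_factor = dt_max_factor,
                 domain_margin = domain_margin),
            class = "relax_config")
}

# stiffness of the regularized WLC at its linear-continuation knee (N/m, SI)
wlc_knee_stiffness <- function(params, lc_um, margin) {
  kBT <- physical_constants()$kB * params$temperature
  lp <- params$l_p * 1e-6; lc <- lc_um * 1e-6
  xmax <- lc^2 / (6 * lp)
  x_hi <- (1 - margin) * xmax
  h <- 1e-7 * xmax
  f <- function(x) {
    d1 <- lc^2 - 6 * lp * x
    d2 <- lc^2 + 3 * lp * x
    81 * kBT * lp^2 * lc^2 * x / (d1^2 * d2)
  }
  (f(x_hi + h) - f(x_hi - h)) / (2 * h)
}

# per-vertex stiffness sums (N/m, SI) for diagonal mass preconditioning
vertex_stiffness <- function(network, margin) {
  p <- network$params
  k_fil <- wlc_knee_stiffness(p, network$lc, margin)
  k_abp <- kc_effective(p)
  n <- nrow(network$vertices)
  ks <- numeric(n)
  fe <- network$fil_edges; ae <- network$abp_edges
  for (col in c("a", "b")) {
    tf <- tabulate(fe[[col]], nbins = n)
    ta <- tabulate(ae[[col]], nbins = n)
    ks <- ks + tf * k_fil + ta * k_abp
  }
  pmax(ks, k_abp)  # isolated vertices get the soft scale
}

#' Relax a network to mechanical equilibrium
#'
#' Integrates the vertex equations of motion under the chosen
#' [relax_config()] until the maximum residual vertex force drops below the
#' tolerance or the iteration cap is reached. Returns the network with
#' updated vertex positions and a `relax` field holding the convergence
#' diagnostics (`converged`, `iterations`, `fmax`).
#'
#' @param network An [build_network()] result (optionally pre-deformed).
#' @param load A [load_spec()] or `NULL` for free relaxation.
#' @param config A [relax_config()].
#' @return The equilibrated `actin_network`.
#' @export
#' @examples
#' net <- build_network(network_params(n_af = 100), seed = 1)
#' eq <- relax_network(net, load_spec(1e-10))
#' eq$relax$converged
relax_network <- function(network, load = NULL, config = relax_config()) {
  stopifnot(inherits(network, "actin_network"),
            inherits(config, "relax_config"))
  p <- network$params
  ext <- external_forces(network, load)
  load_share <- if (any(ext != 0)) max(sqrt(rowSums(ext^2))) else 0
  tol_eff <- max(config$force_tolerance, config$rel_tolerance * load_share)
  ks <- vertex_stiffness(network, config$domain_margin)
  kmax <- max(ks)
  gamma <- 6 * pi * p$eta * config$drag_radius
  if (config$method == "euler") {
    dt0 <- config$time_step %||% (0.2 * gamma / kmax)
    mass <- 1  # unused
    method <- 0L
  } else {
    # mass_i ~ sum of incident stiffnesses: every local stretch mode then
    # oscillates at ~1/tau, so the FIRE step is not throttled by the
    # stiffest chain (diagonal preconditioning)
    tau <- 1e-4
    mass <- config$fictitious_mass %||% (ks * tau^2)
    dt0 <- config$time_step %||% (0.1 * tau)
    method <- 1L
  }
  res <- relax_cpp(
    network$vertices * 1e-6,
    as.matrix(network$fil_edges[, c("a", "b")]) - 1L,
    network$fil_edges$rest * 1e-6,
    as.matrix(network$abp_edges[, c("a", "b")]) - 1L,
    network$abp_edges$rest * 1e-6,
    ext,
    physical_constants()$kB * p$temperature,
    p$l_p * 1e-6, network$lc * 1e-6, p$delta_r0 * 1e-6, kc_effective(p),
    gamma, dt0, dt0 * config$dt_max_factor,
    config$max_iterations, tol_eff, method, mass,
    config$domain_margin)
  if (!all(is.finite(res$pos)))
    abort("Relaxation diverged (non-finite positions).",
          class = "cytostretch_integration_error")
  out <- network
  out$vertices <- res$pos * 1e6
  out$relax <- list(converged = res$converged, iterations = res$iterations,
                    fmax = res$fmax, dt_final = res$dt_final)
  out
}
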