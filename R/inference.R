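fittable_params <- c("r_e", "r_i", "c_af", "n_af", "r_crosslink", "delta_r0")

default_bounds <- function(fixed) {
  list(r_e = c(fixed$r_i * 1.001, fixed$r_e * 2),
       r_i = c(fixed$r_i * 0.5, fixed$r_e * 0.999),
       c_af = c(2, 80),
       n_af = c(100, 2000),
       r_crosslink = c(1, 20),
       delta_r0 = c(0, 3e-4))
}

#' Fit network structural parameters to a strain-force curve
#'
#' Minimizes the weighted sum of squared differences between the curve's
#' mean strains and the model strains from [simulate_stretch_curve()],
#' \deqn{L(\theta) = \sum_l w_l\,(\hat s(f_l;\theta) - s_l)^2,\qquad
#'       w_l = 1/se_l^2}
#' (unit weights when standard errors are absent or zero), over the chosen
#' free parameters inside box bounds. The optimizer is a derivative-free
#' Nelder--Mead simplex with candidate projection onto the bounds; every
#' loss evaluation reuses one fixed set of replicate seeds (common random
#' numbers), which makes the loss surface deterministic and the fit
#' reproducible. Simulation failures at a trial point score `+Inf` and the
#' search continues.
#'
#' @param curve A [strain_force_curve()] with at least 3 force levels.
#' @param free Character vector of parameters to fit, a subset of
#'   `r_e, r_i, c_af, n_af, r_crosslink, delta_r0`. Fitting more than 3
#'   parameters to a single curve triggers an identifiability warning.
#' @param bounds Named list of `c(lower, upper)` per free parameter;
#'   defaults provided for all fittable parameters.
#' @param fixed A [network_params()] supplying every non-free parameter.
#' @param replicates Networks per loss evaluation, default 5.
#' @param seed Integer seed for the common random numbers.
#' @param config Relaxation protocol, as in [simulate_stretch_curve()].
#' @param max_evals Loss-evaluation budget, default 200.
#' @param xtol_rel Stop when the simplex collapses below this fraction of
#'   each bound range, default `5e-3`.
#' @return An object of class `cyto_fit`: `params_hat` (full
#'   [network_params()]), `theta` (named free-parameter estimates), `loss`,
#'   `n_evaluations`, `converged`, `trace` (tibble of evaluated points),
#'   `seed_set`.
#' @export
fit_parameters <- function(curve, free, bounds = list(),
                           fixed = network_params(), replicates = 5,
                           seed = 1,
                           config = relax_config(max_iterations = 2000),
                           max_evals = 200, xtol_rel = 5e-3) {
  curve <- strain_force_curve(curve)
  stopifnot(inherits(fixed, "network_params"))
  if (length(free) > 0 && !all(free %in% fittable_params))
    abort(sprintf("Free parameters must be among: %s.",
                  paste(fittable_params, collapse = ", ")))
  if (nrow(curve) < 3) abort("Need at least 3 force levels to fit.")
  if (length(free) > 3)
    warn(paste("Fitting more than 3 parameters to a single curve is weakly",
               "identified; interpret the estimates with care."))
  w <- if (has_se(curve) && all(curve$strain_se > 0)) {
    1 / curve$strain_se^2
  } else {
    rep(1, nrow(curve))
  }

  n_evals <- 0L
  trace <- list()
  loss_fn <- function(theta) {
    n_evals <<- n_evals + 1L
    p <- tryCatch({
      args <- unclass(fixed)
      args[free] <- as.list(theta)
      if ("n_af" %in% free) args$n_af <- round(args$n_af)
      do.call(network_params, args)
    }, error = function(e) NULL)
    val <- if (is.null(p)) {
      Inf
    } else {
      tryCatch({
        sim <- simulate_stretch_curve(p, curve$force_N, replicates, seed,
                                      config)
        sum(w * (sim$strain_mean - curve$strain_mean)^2)
      }, error = function(e) Inf)
    }
    trace[[length(trace) + 1L]] <<- c(theta, loss = val)
    val
  }

  if (length(free) == 0) {
    loss0 <- loss_fn(setNames(numeric(0), character(0)))
    return(structure(list(params_hat = fixed,
                          theta = setNames(numeric(0), character(0)),
                          loss = loss0, n_evaluations = n_evals,
                          converged = TRUE, trace = trace_tbl(trace, free),
                          seed_set = seed),
                     class = "cyto_fit"))
  }

  b <- modifyList(default_bounds(fixed), bounds)[free]
  lo <- vapply(b, `[`, 0, 1); hi <- vapply(b, `[`, 0, 2)
  if (any(!is.finite(c(lo, hi))) || any(lo >= hi))
    abort("Bounds must be finite intervals with lower < upper.")
  start <- pmin(pmax(vapply(free, function(nm) {
    v <- unclass(fixed)[[nm]]
    if (is.null(v)) mean(c(lo[nm], hi[nm])) else as.numeric(v)
  }, 0), lo), hi)

  res <- nelder_mead_box(loss_fn, start, lo, hi, max_evals = max_evals,
                         xtol_rel = xtol_rel)

  args <- unclass(fixed)
  args[free] <- as.list(res$par)
  if ("n_af" %in% free) args$n_af <- round(args$n_af)
  params_hat <- do.call(network_params, args)
  structure(list(params_hat = params_hat,
                 theta = setNames(res$par, free),
                 loss = res$value, n_evaluations = n_evals,
                 converged = res$converged,
                 trace = trace_tbl(trace, free), seed_set = seed),
            class = "cyto_fit")
}

trace_tbl <- function(trace, free) {
  if (length(trace) == 0)
    return(tibble(!!!setNames(rep(list(numeric(0)), length(free) + 1),
                              c(free, "loss"))))
  m <- do.call(rbind, trace)
  colnames(m) <- c(free, "loss")
  as_tibble(m)
}

# Nelder-Mead simplex restricted to a box by projecting candidates.
nelder_mead_box <- function(f, start, lo, hi, max_evals = 200,
                            xtol_rel = 5e-3) {
  d <- length(start)
  proj <- function(x) pmin(pmax(x, lo), hi)
  # initial simplex: start plus steps of 15% of each range (flipped if at
  # the upper bound)
  pts <- matrix(rep(start, d + 1), d + 1, d, byrow = TRUE)
  for (k in seq_len(d)) {
    step <- 0.15 * (hi[k] - lo[k])
    pts[k + 1, k] <- if (start[k] + step <= hi[k]) start[k] + step
                     else start[k] - step
  }
  vals <- apply(pts, 1, function(x) f(proj(x)))
  evals <- d + 1
  alpha <- 1; gamma_e <- 2; rho <- 0.5; sigma <- 0.5
  while (evals < max_evals) {
    ord <- order(vals)
    pts <- pts[ord, , drop = FALSE]; vals <- vals[ord]
    size <- max(vapply(seq_len(d), function(k)
      diff(range(pts[, k])) / (hi[k] - lo[k]), 0))
    if (size < xtol_rel) break
    centroid <- colMeans(pts[seq_len(d), , drop = FALSE])
    worst <- pts[d + 1, ]
    xr <- proj(centroid + alpha * (centroid - worst))
    fr <- f(xr); evals <- evals + 1
    if (fr < vals[1]) {
      xe <- proj(centroid + gamma_e * (centroid - worst))
      fe <- f(xe); evals <- evals + 1
      if (fe < fr) { pts[d + 1, ] <- xe; vals[d + 1] <- fe }
      else { pts[d + 1, ] <- xr; vals[d + 1] <- fr }
    } else if (fr < vals[d]) {
      pts[d + 1, ] <- xr; vals[d + 1] <- fr
    } else {
      xc <- proj(centroid + rho * (worst - centroid))
      fc <- f(xc); evals <- evals + 1
      if (fc < vals[d + 1]) { pts[d + 1, ] <- xc; vals[d + 1] <- fc }
      else {
        for (k in 2:(d + 1)) {
          pts[k, ] <- proj(pts[1, ] + sigma * (pts[k, ] - pts[1, ]))
          vals[k] <- f(pts[k, ]); evals <- evals + 1
        }
      }
    }
  }
  best <- which.min(vals)
  list(par = setNames(pts[best, ], names(start)), value = vals[best],
       evals = evals, converged = TRUE)
}

#' @export
print.cyto_fit <- function(x, ...) {
  cat("<cyto_fit>\n")
  if (length(x$theta)) {
    for (nm in names(x$theta))
      cat(sprintf("  %-12s %.6g\n", nm, x$theta[[nm]]))
  } else {
    cat("  (no free parameters)\n")
  }
  cat(sprintf("  loss %.4g after %d evaluations\n", x$loss, x$n_evaluations))
  invisible(x)
}

#' Apparent elastic modulus from a strain-force curve
#'
#' Converts forces to stresses with a stated area convention
#' (`cross_section`: \eqn{\pi r_0^2}; `surface`: \eqn{4\pi r_0^2}), then
#' fits stress = E x strain by least squares through the origin (zero force
#' implies zero strain by the strain definition). `r_squared` is computed
#' for the through-origin fit.
#'
#' @param curve A [strain_force_curve()] with at least 2 levels.
#' @param r0 Undeformed cell radius in m, default `7e-6`.
#' @param area_convention `"cross_section"` (default) or `"surface"`. The
#'   convention is reported in the result; moduli are only comparable under
#'   the same convention.
#' @return An object of class `modulus_fit` with `modulus` (Pa),
#'   `r_squared`, `area_convention`, `area` (m^2) and `n_levels`.
#' @export
#' @examples
#' cv <- strain_force_curve(tibble::tibble(force_N = 1:4 * 1e-9,
#'                                         strain_mean = 1:4 * 0.05))
#' estimate_modulus(cv)
estimate_modulus <- function(curve, r0 = 7e-6,
                             area_convention = c("cross_section", "surface")) {
  curve <- strain_force_curve(curve)
  area_convention <- match.arg(area_convention)
  if (nrow(curve) < 2) abort("Need at least 2 levels.")
  if (r0 <= 0) abort("`r0` must be > 0.")
  area <- if (area_convention == "cross_section") pi * r0^2 else 4 * pi * r0^2
  stress <- curve$force_N / area
  s <- curve$strain_mean
  if (all(s == 0)) abort("All strains are zero; modulus fit is degenerate.",
                         class = "cytostretch_degenerate_error")
  E <- sum(s * stress) / sum(s^2)
  ss_res <- sum((stress - E * s)^2)
  ss_tot <- sum(stress^2)
  structure(list(modulus = E, r_squared = 1 - ss_res / ss_tot,
                 area_convention = area_convention, area = area, r0 = r0,
                 n_levels = nrow(curve)),
            class = "modulus_fit")
}

#' @export
print.modulus_fit <- function(x, ...) {
  cat(sprintf("<modulus_fit> E = %.3g Pa (%s area), R^2 = %.4f, %d levels\n",
              x$modulus, x$area_convention, x$r_squared, x$n_levels))
  invisible(x)
}

#' Compare two strain-force curves
#'
#' Per-level strain differences over the shared force levels, the modulus
#' ratio, and a stiffer/softer verdict (based on the modulus ordering under
#' a common area convention).
#'
#' @param curve_a,curve_b [strain_force_curve()] objects with overlapping
#'   force ranges; labels default to their `label` attributes.
#' @param r0 Cell radius for the modulus fits, m.
#' @param area_convention Passed to [estimate_modulus()].
#' @param rel_tol Relative modulus difference below which the groups are
#'   called indistinguishable, default `1e-6`.
#' @return An object of class `group_comparison`: `levels` (tibble of
#'   per-level strains and differences at shared force levels), `modulus_a`,
#'   `modulus_b`, `modulus_ratio` (b over a), `verdict`.
#' @export
compare_groups <- function(curve_a, curve_b, r0 = 7e-6,
                           area_convention = "cross_section",
                           rel_tol = 1e-6) {
  curve_a <- strain_force_curve(curve_a, label = attr(curve_a, "label"))
  curve_b <- strain_force_curve(curve_b, label = attr(curve_b, "label"))
  if (min(curve_a$force_N) > max(curve_b$force_N) ||
      min(curve_b$force_N) > max(curve_a$force_N))
    abort("Force ranges do not overlap; the curves cannot be compared.")
  lv <- inner_join(
    select(as_tibble(curve_a), force_N, strain_a = strain_mean),
    select(as_tibble(curve_b), force_N, strain_b = strain_mean),
    by = "force_N")
  lv <- mutate(lv, strain_diff = .data$strain_b - .data$strain_a)
  ma <- estimate_modulus(curve_a, r0, area_convention)
  mb <- estimate_modulus(curve_b, r0, area_convention)
  ratio <- mb$modulus / ma$modulus
  verdict <- if (abs(ratio - 1) <= rel_tol) {
    "indistinguishable"
  } else if (ratio > 1) {
    "b stiffer"
  } else {
    "a stiffer"
  }
  structure(list(levels = lv, modulus_a = ma$modulus, modulus_b = mb$modulus,
                 modulus_ratio = ratio, verdict = verdict,
                 label_a = attr(curve_a, "label") %||% "a",
                 label_b = attr(curve_b, "label") %||% "b"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s: modulus %.3g vs %.3g Pa (ratio %.3g) -> %s\n",
              x$label_a, x$label_b, x$modulus_a, x$modulus_b,
              x$modulus_ratio, x$verdict))
  print(x$levels)
  invisible(x)
}
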