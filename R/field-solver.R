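#' Solve the quasi-electrostatic phasor potential in the chip
#'
#' Discretizes \eqn{-\nabla\cdot((\sigma + j\omega\varepsilon_0\varepsilon)
#' \nabla\phi)=0} with a conservative cell-centered finite-volume scheme on
#' the chip's uniform Cartesian grid. Face conductances use the harmonic mean
#' of the two adjacent cell coefficients, which builds flux continuity across
#' the medium/particle interface into the discretization. Electrode segments
#' are Dirichlet (driven amplitude / ground) applied through boundary ghost
#' faces; every other boundary is insulating (zero normal flux). When all
#' materials share the same complex phase (e.g. no particle, or a particle
#' made of the medium) the system reduces to a real one and is solved as
#' such; otherwise the complex system is solved in block-real form.
#'
#' @param chip A [chip_model()].
#' @param medium A [dielectric_material()] filling the channel.
#' @param omega Angular frequency in rad/s (> 0).
#' @param particle Optional [particle_inclusion()]; its disc is rasterized by
#'   cell-center material assignment.
#' @return An object of class `field_solution`: complex matrices `phi`, `ex`,
#'   `ey` (nx x ny, cell-centered; E = -grad phi), the squared field
#'   amplitude `e2 = |Ex|^2 + |Ey|^2`, grid coordinates `x`, `y`, spacing
#'   `h`, and the inputs.
#' @export
#' @examples
#' chip <- fixture_chip("parallel_plate", grid_spacing = 2e-6)
#' sol <- solve_potential(chip, dep_medium(), 2 * pi * 1e6)
#' max(abs(sqrt(sol$e2) - chip$driven_potential / chip$domain_height))
solve_potential <- function(chip, medium, omega, particle = NULL) {
  stopifnot(inherits(chip, "chip_model"), inherits(medium, "dielectric_material"))
  if (!is.numeric(omega) || length(omega) != 1 || omega <= 0)
    abort("`omega` must be a single value > 0.")
  if (!is.null(particle)) {
    stopifnot(inherits(particle, "particle_inclusion"))
    p <- particle
    if (p$center[1] - p$radius < 0 || p$center[1] + p$radius > chip$domain_width ||
        p$center[2] - p$radius < 0 || p$center[2] + p$radius > chip$domain_height)
      abort("Particle disc must lie inside the domain.")
  }
  h <- chip$grid_spacing
  nx <- chip$nx; ny <- chip$ny
  n <- nx * ny
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  idx <- function(i, j) (j - 1L) * nx + i

  cm <- complex_conductivity(medium, omega)
  coef <- rep(cm, n)
  if (!is.null(particle)) {
    cp <- complex_conductivity(particle$material, omega)
    X <- matrix(xc, nx, ny)
    Y <- matrix(yc, nx, ny, byrow = TRUE)
    inside <- (X - particle$center[1])^2 + (Y - particle$center[2])^2 <=
      particle$radius^2
    coef[as.vector(inside)] <- cp
  }

  # face conductances (per unit depth; face area h / distance h = 1)
  i <- rep(seq_len(nx - 1L), ny); j <- rep(seq_len(ny), each = nx - 1L)
  aH <- idx(i, j); bH <- idx(i + 1L, j)
  tH <- 2 * coef[aH] * coef[bH] / (coef[aH] + coef[bH])
  i2 <- rep(seq_len(nx), ny - 1L); j2 <- rep(seq_len(ny - 1L), each = nx)
  aV <- idx(i2, j2); bV <- idx(i2, j2 + 1L)
  tV <- 2 * coef[aV] * coef[bV] / (coef[aV] + coef[bV])

  I <- c(aH, bH, aH, bH, aV, bV, aV, bV)
  J <- c(aH, bH, bH, aH, aV, bV, bV, aV)
  V <- c(tH, tH, -tH, -tH, tV, tV, -tV, -tV)
  rhs <- rep(0 + 0i, n)

  any_dirichlet <- FALSE
  for (e in chip$electrodes) {
    cells_i <- which(xc >= e$x0 - 1e-15 & xc <= e$x1 + 1e-15)
    if (length(cells_i) == 0) next
    any_dirichlet <- TRUE
    jrow <- if (e$side == "bottom") 1L else ny
    cells <- idx(cells_i, jrow)
    I <- c(I, cells); J <- c(J, cells); V <- c(V, 2 * coef[cells])
    rhs[cells] <- rhs[cells] + 2 * coef[cells] * e$potential
  }
  if (!any_dirichlet)
    abort("Ill-posed setup: no electrode (Dirichlet) segment on the grid.",
          class = "cytostretch_config_error")

  # reduce to a real system when all coefficients share one complex phase
  Ar <- Matrix::sparseMatrix(i = I, j = J, x = Re(V), dims = c(n, n))
  Ai <- Matrix::sparseMatrix(i = I, j = J, x = Im(V), dims = c(n, n))
  phase <- coef / Mod(coef)
  phase_ref <- phase[1]
  real_ok <- max(Mod(phase - phase_ref)) < 1e-12
  if (real_ok) {
    As <- Matrix::sparseMatrix(i = I, j = J, x = Re(V / phase_ref),
                               dims = c(n, n))
    phi <- as.numeric(Matrix::solve(As, Re(rhs / phase_ref)))
    phi <- complex(real = phi, imaginary = 0)
  } else {
    B <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
    sol <- as.numeric(Matrix::solve(B, c(Re(rhs), Im(rhs))))
    phi <- complex(real = sol[seq_len(n)], imaginary = sol[n + seq_len(n)])
  }
  res <- resid_norm(Ar, Ai, phi, rhs)
  if (!is.finite(res) || res > 1e-8)
    abort(sprintf("Field solve failed to converge (relative residual %.3e).", res),
          class = "cytostretch_solver_error")

  phi_m <- matrix(phi, nx, ny)
  ex <- -d_dx(phi_m, h)
  ey <- -d_dy(phi_m, h)
  structure(list(phi = phi_m, ex = ex, ey = ey,
                 e2 = Mod(ex)^2 + Mod(ey)^2,
                 x = xc, y = yc, h = h, chip = chip, medium = medium,
                 omega = omega, particle = particle, residual = res),
            class = "field_solution")
}

resid_norm <- function(Ar, Ai, phi, rhs) {
  pr <- Re(phi); pi_ <- Im(phi)
  rr <- as.numeric(Ar %*% pr - Ai %*% pi_) - Re(rhs)
  ri <- as.numeric(Ar %*% pi_ + Ai %*% pr) - Im(rhs)
  sqrt(sum(rr^2 + ri^2)) / max(sqrt(sum(Mod(rhs)^2)), 1e-300)
}

# central differences inside, one-sided at the boundary (matrix nx x ny)
d_dx <- function(m, h) {
  nx <- nrow(m)
  out <- m
  out[2:(nx - 1), ] <- (m[3:nx, ] - m[1:(nx - 2), ]) / (2 * h)
  out[1, ] <- (m[2, ] - m[1, ]) / h
  out[nx, ] <- (m[nx, ] - m[nx - 1, ]) / h
  out
}

d_dy <- function(m, h) {
  ny <- ncol(m)
  out <- m
  out[, 2:(ny - 1)] <- (m[, 3:ny] - m[, 1:(ny - 2)]) / (2 * h)
  out[, 1] <- (m[, 2] - m[, 1]) / h
  out[, ny] <- (m[, ny] - m[, ny - 1]) / h
  out
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %d x %d cells, h = %g um, %s particle\n",
              nrow(x$phi), ncol(x$phi), x$h * 1e6,
              if (is.null(x$particle)) "no" else "with"))
  invisible(x)
}

# bilinear interpolation of a (possibly complex) cell-centered grid at points
interp_grid <- function(vals, xc, yc, px, py) {
  h <- xc[2] - xc[1]
  nx <- length(xc); ny <- length(yc)
  fx <- (px - xc[1]) / h
  fy <- (py - yc[1]) / h
  i0 <- pmin(pmax(floor(fx), 0), nx - 2)
  j0 <- pmin(pmax(floor(fy), 0), ny - 2)
  tx <- fx - i0; ty <- fy - j0
  i0 <- as.integer(i0) + 1L; j0 <- as.integer(j0) + 1L
  v00 <- vals[cbind(i0, j0)];     v10 <- vals[cbind(i0 + 1L, j0)]
  v01 <- vals[cbind(i0, j0 + 1L)]; v11 <- vals[cbind(i0 + 1L, j0 + 1L)]
  v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
    v01 * (1 - tx) * ty + v11 * tx * ty
}

check_inside <- function(sol, point, margin_cells = 2) {
  m <- margin_cells * sol$h
  if (point[1] < m || point[1] > sol$chip$domain_width - m ||
      point[2] < m || point[2] > sol$chip$domain_height - m)
    abort("Probe point outside the domain (or too close to the boundary).",
          class = "cytostretch_range_error")
}

#' Query the complex field at a point
#'
#' Bilinear interpolation of the phasor field components from the solved
#' grid.
#'
#' @param solution A [solve_potential()] result.
#' @param point Numeric length-2 (x, y) in m.
#' @return List with complex `ex`, `ey` (V/m).
#' @export
field_at <- function(solution, point) {
  stopifnot(inherits(solution, "field_solution"))
  check_inside(solution, point, margin_cells = 1)
  list(ex = interp_grid(solution$ex, solution$x, solution$y, point[1], point[2]),
       ey = interp_grid(solution$ey, solution$x, solution$y, point[1], point[2]))
}

#' Gradient of the squared field at a point
#'
#' Central-difference gradient of the squared field amplitude
#' \eqn{|E|^2 = E\cdot E^*} on the grid, bilinearly interpolated at the
#' requested point. With `rms = TRUE` the gradient of the squared RMS field
#' (\eqn{\tfrac12|E|^2}) is returned, which is the quantity the
#' equivalent-dipole force estimator expects for phasor amplitudes.
#'
#' @param solution A [solve_potential()] result.
#' @param point Numeric length-2 (x, y) in m; must lie at least 2 grid cells
#'   inside the domain.
#' @param rms Logical; divide by 2 to convert amplitude-squared to
#'   RMS-squared. Default `FALSE`.
#' @return Numeric length-2 gradient in V^2/m^3.
#' @export
grad_e2_at <- function(solution, point, rms = FALSE) {
  stopifnot(inherits(solution, "field_solution"))
  check_inside(solution, point)
  gx <- d_dx(solution$e2, solution$h)
  gy <- d_dy(solution$e2, solution$h)
  g <- c(interp_grid(gx, solution$x, solution$y, point[1], point[2]),
         interp_grid(gy, solution$x, solution$y, point[1], point[2]))
  if (rms) g / 2 else g
}

#' Maxwell-stress-tensor force on a particle
#'
#' Integrates the time-averaged 2D Maxwell stress tensor
#' \deqn{T = \tfrac14\varepsilon_0\varepsilon_m\,(E E^* + E^* E - |E|^2 I)}
#' over a circular contour enclosing the particle (evaluated on the medium
#' side of the interface) against outward normals by the trapezoid rule, and
#' multiplies by the chip's out-of-plane thickness to produce a force. The
#' quarter prefactor is the time-average convention for phasor amplitudes.
#' Because the medium is source-free, the integral is contour-independent;
#' the default contour sits a couple of grid cells outside the rasterized
#' interface where the interpolated field is smooth.
#'
#' @param solution A [solve_potential()] result computed *with* the particle
#'   present.
#' @param particle The [particle_inclusion()] the solve used (defaults to the
#'   one stored in the solution).
#' @param medium Medium material (defaults to the solution's).
#' @param thickness Out-of-plane thickness in m (defaults to the chip's).
#' @param n_points Number of contour quadrature points, default 720.
#' @param offset Contour standoff outside the particle radius in m; default
#'   `2 * h`.
#' @return Numeric length-2 force (Fx, Fy) in N.
#' @export
integrate_mst <- function(solution, particle = solution$particle,
                          medium = solution$medium,
                          thickness = solution$chip$out_of_plane_thickness,
                          n_points = 720, offset = NULL) {
  stopifnot(inherits(solution, "field_solution"))
  if (is.null(particle)) abort("`particle` is required (solve with a particle).")
  cx <- particle$center[1]; cy <- particle$center[2]
  # largest contour that stays half a cell inside the domain
  rc_max <- min(cx, solution$chip$domain_width - cx,
                cy, solution$chip$domain_height - cy) - solution$h / 2
  offset <- offset %||% min(2 * solution$h, rc_max - particle$radius)
  rc <- particle$radius + offset
  if (offset <= 0 || rc > rc_max + 1e-15)
    abort("Integration contour intersects the domain boundary.",
          class = "cytostretch_range_error")
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  px <- cx + rc * cos(th); py <- cy + rc * sin(th)
  ex <- interp_grid(solution$ex, solution$x, solution$y, px, py)
  ey <- interp_grid(solution$ey, solution$x, solution$y, px, py)
  ex2 <- Mod(ex)^2; ey2 <- Mod(ey)^2
  txx <- ex2 - ey2
  tyy <- ey2 - ex2
  txy <- 2 * Re(ex * Conj(ey))
  nxv <- cos(th); nyv <- sin(th)
  fx_dens <- txx * nxv + txy * nyv
  fy_dens <- txy * nxv + tyy * nyv
  dl <- rc * 2 * pi / n_points
  eps0 <- physical_constants()$eps0
  pref <- 0.25 * eps0 * medium$rel_permittivity * dl * thickness
  c(pref * sum(fx_dens), pref * sum(fy_dens))
}
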