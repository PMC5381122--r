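#' DEP force from the equivalent dipole moment (EDM)
#'
#' The point-dipole estimate of the time-averaged DEP force on a spherical
#' cell,
#' \deqn{F = 2\pi r^3 \varepsilon_0 \varepsilon_m \, \mathrm{Re}[K(\omega)]
#'       \, \nabla E^2,}
#' applied componentwise to the supplied gradient. `grad_e2` is the gradient
#' of the squared RMS field \eqn{\nabla E_{rms}^2}; when working from phasor
#' amplitudes (as [solve_potential()] returns), pass
#' \eqn{\tfrac12\nabla|E|^2} -- [grad_e2_at()] has an `rms` argument that does
#' this. Using RMS here keeps the estimator consistent with the
#' quarter-factor (amplitude) convention of the Maxwell-stress integration.
#'
#' @param cell A [cell_dielectric()]; supplies the radius r.
#' @param medium A [dielectric_material()]; supplies \eqn{\varepsilon_m}.
#' @param re_k Real part of the Clausius--Mossotti factor (dimensionless).
#' @param grad_e2 Numeric vector, gradient of the squared RMS field in
#'   V^2/m^3.
#' @return Force vector in N, same length as `grad_e2`.
#' @export
#' @examples
#' K <- clausius_mossotti(cell_dielectric(), dep_medium(), 2 * pi * 1e6)
#' dep_force_edm(cell_dielectric(), dep_medium(), K$real_part, c(0, 2e15))
dep_force_edm <- function(cell, medium, re_k, grad_e2) {
  stopifnot(inherits(cell, "cell_dielectric"),
            inherits(medium, "dielectric_material"),
            is.numeric(re_k), length(re_k) == 1, is.numeric(grad_e2))
  if (!all(is.finite(c(re_k, grad_e2)))) abort("Inputs must be finite.")
  eps0 <- physical_constants()$eps0
  2 * pi * cell$radius^3 * eps0 * medium$rel_permittivity * re_k * grad_e2
}

#' Simplified DEP force approximation
#'
#' The tip-to-tip electrode approximation that treats the field inside the
#' cell as negligible compared to the outside field:
#' \deqn{F = \tfrac14 \varepsilon_0 \varepsilon_m E^2 A,\qquad E = U/d,}
#' with A the cell surface area \eqn{4\pi r^2}, U the applied voltage
#' amplitude and d the electrode gap. Frequency (and hence the sign of the
#' DEP response) is ignored; the estimate scales exactly as \eqn{U^2} and
#' tends to overestimate the force.
#'
#' @param drive A [drive()]; supplies the amplitude U.
#' @param gap Electrode gap d in m (> 0), default `20e-6`.
#' @param cell A [cell_dielectric()]; supplies the radius.
#' @param medium A [dielectric_material()]; supplies \eqn{\varepsilon_m}.
#' @return Force magnitude in N.
#' @export
#' @examples
#' # 2 V amplitude across a 20 um gap, 7 um cell, eps_m = 80: about 1.09 nN
#' dep_force_simplified(drive(2), 20e-6, cell_dielectric(),
#'                      dep_medium(rel_permittivity = 80)) * 1e9
dep_force_simplified <- function(drive, gap = 20e-6, cell = cell_dielectric(),
                                 medium = dep_medium()) {
  stopifnot(inherits(drive, "drive"), inherits(cell, "cell_dielectric"),
            inherits(medium, "dielectric_material"))
  if (!is.numeric(gap) || length(gap) != 1 || gap <= 0)
    abort("`gap` must be a single value > 0.")
  eps0 <- physical_constants()$eps0
  E <- drive$voltage_amplitude / gap
  A <- 4 * pi * cell$radius^2
  0.25 * eps0 * medium$rel_permittivity * E^2 * A
}
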