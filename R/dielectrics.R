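#' Dielectric material description
#'
#' A material is characterized by its relative permittivity \eqn{\varepsilon}
#' (dimensionless, >= 1) and its electrical conductivity \eqn{\sigma} (S/m).
#' Together they define the complex conductivity \eqn{\sigma + j\omega
#' \varepsilon_0\varepsilon} that governs the quasi-electrostatic field.
#'
#' @param rel_permittivity Relative permittivity (dimensionless, >= 1).
#' @param conductivity Conductivity in S/m (>= 0).
#' @return An object of class `dielectric_material`.
#' @export
#' @examples
#' dep_medium()           # low-conductivity isotonic stretching buffer
#' dielectric_material(60, 0.2)
dielectric_material <- function(rel_permittivity, conductivity) {
  stopifnot(is.numeric(rel_permittivity), length(rel_permittivity) == 1,
            is.numeric(conductivity), length(conductivity) == 1)
  if (rel_permittivity < 1) abort("`rel_permittivity` must be >= 1.")
  if (conductivity < 0) abort("`conductivity` must be >= 0.")
  structure(list(rel_permittivity = rel_permittivity,
                 conductivity = conductivity),
            class = "dielectric_material")
}

#' @export
print.dielectric_material <- function(x, ...) {
  cat(sprintf("<dielectric_material> eps_r = %g, sigma = %g S/m\n",
              x$rel_permittivity, x$conductivity))
  invisible(x)
}

#' Default suspension medium
#'
#' The low-conductivity isotonic sucrose/dextrose buffer used for DEP
#' stretching: relative permittivity 78 (water-like) and conductivity
#' 5.29 mS/m.
#'
#' @param rel_permittivity Relative permittivity, default 78.
#' @param conductivity Conductivity in S/m, default 5.29e-3.
#' @return A `dielectric_material`.
#' @export
dep_medium <- function(rel_permittivity = 78, conductivity = 5.29e-3) {
  dielectric_material(rel_permittivity, conductivity)
}

#' Cell dielectric description
#'
#' A cell is modeled as a homogeneous dielectric sphere: a radius plus the
#' cytoplasm material. Defaults are cytoplasm-like values (sigma_c = 0.2 S/m,
#' eps_c = 60) for a 7 um leukemia cell; the cytoplasm conductivity exceeds
#' the stretching-medium conductivity, which is the regime in which captured
#' cells elongate along the field lines.
#'
#' @param radius Cell radius in m, default `7e-6`.
#' @param cytoplasm A `dielectric_material`, default
#'   `dielectric_material(60, 0.2)`.
#' @return An object of class `cell_dielectric`.
#' @export
#' @examples
#' cell_dielectric()
cell_dielectric <- function(radius = 7e-6,
                            cytoplasm = dielectric_material(60, 0.2)) {
  stopifnot(is.numeric(radius), length(radius) == 1)
  if (!inherits(cytoplasm, "dielectric_material"))
    abort("`cytoplasm` must be a dielectric_material.")
  if (radius <= 0) abort("`radius` must be > 0.")
  structure(list(radius = radius, cytoplasm = cytoplasm),
            class = "cell_dielectric")
}

#' @export
print.cell_dielectric <- function(x, ...) {
  cat(sprintf("<cell_dielectric> r = %g um, eps_c = %g, sigma_c = %g S/m\n",
              x$radius * 1e6, x$cytoplasm$rel_permittivity,
              x$cytoplasm$conductivity))
  invisible(x)
}

#' AC drive description
#'
#' Voltage amplitude and frequency of the sinusoidal potential applied across
#' the electrode pair. All package APIs use the voltage *amplitude* U; use
#' [vpp_to_amplitude()] / [amplitude_to_vpp()] to convert from/to the
#' peak-to-peak values a function generator displays.
#'
#' @param voltage_amplitude Amplitude U in volts (not peak-to-peak).
#' @param frequency Frequency in Hz (> 0), default 1 MHz.
#' @return An object of class `drive` with fields `voltage_amplitude`,
#'   `frequency` and `angular_frequency` (`2 * pi * frequency`).
#' @export
#' @examples
#' drive(2, 1e6)
#' drive(vpp_to_amplitude(4))  # 4 Vpp == 2 V amplitude
drive <- function(voltage_amplitude, frequency = 1e6) {
  stopifnot(is.numeric(voltage_amplitude), length(voltage_amplitude) == 1,
            is.numeric(frequency), length(frequency) == 1)
  if (frequency <= 0) abort("`frequency` must be > 0.")
  structure(list(voltage_amplitude = voltage_amplitude,
                 frequency = frequency,
                 angular_frequency = 2 * pi * frequency),
            class = "drive")
}

#' @export
print.drive <- function(x, ...) {
  cat(sprintf("<drive> U = %g V (amplitude), f = %g Hz\n",
              x$voltage_amplitude, x$frequency))
  invisible(x)
}

#' Convert between peak-to-peak voltage and amplitude
#'
#' @param vpp Peak-to-peak voltage.
#' @param amplitude Voltage amplitude.
#' @return The converted voltage (amplitude = vpp / 2).
#' @export
vpp_to_amplitude <- function(vpp) vpp / 2

#' @rdname vpp_to_amplitude
#' @export
amplitude_to_vpp <- function(amplitude) amplitude * 2
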