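#' Complex conductivity of a material
#'
#' Returns \eqn{\sigma + j\omega\varepsilon_0\varepsilon}, the coefficient of
#' the quasi-electrostatic charge-conservation equation
#' \eqn{-\nabla\cdot((\sigma + j\omega\varepsilon_0\varepsilon)\nabla\phi)=0}.
#' The equivalent complex-permittivity convention is
#' \eqn{\varepsilon^* = \varepsilon_0\varepsilon - j\sigma/\omega}; the two
#' are related by \eqn{\sigma^* = j\omega\varepsilon^*} and the package uses
#' the complex-conductivity form in the field solver and the
#' complex-permittivity form in the Clausius--Mossotti factor (the CM ratio is
#' identical under either convention).
#'
#' @param material A [dielectric_material()].
#' @param omega Angular frequency in rad/s (> 0).
#' @return Complex scalar, S/m.
#' @export
#' @examples
#' complex_conductivity(dep_medium(), 2 * pi * 1e6)
complex_conductivity <- function(material, omega) {
  stopifnot(inherits(material, "dielectric_material"))
  if (!is.numeric(omega) || any(omega <= 0))
    abort("`omega` must be > 0.")
  eps0 <- physical_constants()$eps0
  complex(real = material$conductivity,
          imaginary = omega * eps0 * material$rel_permittivity)
}

#' Complex permittivity of a material
#'
#' \eqn{\varepsilon^* = \varepsilon_0\varepsilon - j\sigma/\omega}. See
#' [complex_conductivity()] for the convention.
#'
#' @inheritParams complex_conductivity
#' @return Complex scalar, F/m.
#' @export
complex_permittivity <- function(material, omega) {
  stopifnot(inherits(material, "dielectric_material"))
  if (!is.numeric(omega) || any(omega <= 0))
    abort("`omega` must be > 0.")
  eps0 <- physical_constants()$eps0
  complex(real = eps0 * material$rel_permittivity,
          imaginary = -material$conductivity / omega)
}

#' Clausius--Mossotti factor of a homogeneous sphere (or cylinder)
#'
#' Frequency-dependent effective polarizability contrast between a particle
#' and its suspending medium,
#' \deqn{K(\omega) = \frac{\varepsilon_c^* - \varepsilon_m^*}
#'                       {\varepsilon_c^* + 2\varepsilon_m^*}}
#' for a sphere; for the in-plane response of a 2D (cylindrical) cross-section
#' the depolarization changes the denominator to
#' \eqn{\varepsilon_c^* + \varepsilon_m^*}. The cell is treated as a
#' homogeneous dielectric sphere (no membrane shell). `Re[K]` is bounded in
#' `[-0.5, 1]` for the sphere and `[-1, 1]` for the cylinder.
#'
#' @param cell A [cell_dielectric()].
#' @param medium A [dielectric_material()].
#' @param omega Angular frequency in rad/s (> 0); may be a vector.
#' @param geometry `"sphere"` (default, the physical cell model) or
#'   `"cylinder"` (in-plane response of a 2D disc; used to cross-check the
#'   Maxwell-stress integration in the planar chip model).
#' @return A list of class `cm_result` with `value` (complex, same length as
#'   `omega`) and `real_part`.
#' @export
#' @examples
#' clausius_mossotti(cell_dielectric(), dep_medium(), 2 * pi * 1e6)$real_part
clausius_mossotti <- function(cell, medium, omega,
                              geometry = c("sphere", "cylinder")) {
  stopifnot(inherits(cell, "cell_dielectric"),
            inherits(medium, "dielectric_material"))
  geometry <- match.arg(geometry)
  if (!is.numeric(omega) || any(omega <= 0)) abort("`omega` must be > 0.")
  ec <- complex_permittivity(cell$cytoplasm, omega)
  em <- complex_permittivity(medium, omega)
  depol <- if (geometry == "sphere") 2 else 1
  den <- ec + depol * em
  if (any(Mod(den) == 0))
    abort("Degenerate denominator in Clausius-Mossotti factor.")
  K <- (ec - em) / den
  structure(list(value = K, real_part = Re(K), geometry = geometry),
            class = "cm_result")
}

#' @export
print.cm_result <- function(x, ...) {
  cat(sprintf("<cm_result> (%s) Re[K] = %s\n", x$geometry,
              paste(signif(x$real_part, 4), collapse = ", ")))
  invisible(x)
}

#' Clausius--Mossotti spectrum over a frequency grid
#'
#' Tidy evaluation of `Re[K]` and `Im[K]` over frequencies, for spectra and
#' crossover plots.
#'
#' @inheritParams clausius_mossotti
#' @param frequencies Frequencies in Hz.
#' @return A tibble with columns `frequency`, `re_k`, `im_k`.
#' @export
cm_spectrum <- function(cell, medium, frequencies,
                        geometry = c("sphere", "cylinder")) {
  geometry <- match.arg(geometry)
  K <- clausius_mossotti(cell, medium, 2 * pi * frequencies, geometry)$value
  tibble(frequency = frequencies, re_k = Re(K), im_k = Im(K))
}

#' Crossover frequency between positive and negative DEP
#'
#' Finds the frequency at which `Re[K]` changes sign within `[f_lo, f_hi]`
#' (the pDEP/nDEP switch), by bisection after bracketing on a log-spaced scan.
#' Returns `NULL` when `Re[K]` does not change sign over the bracket, which is
#' a valid physical outcome (e.g. a homogeneous cell with cytoplasm
#' conductivity above the medium's is pDEP at all low frequencies).
#'
#' @inheritParams clausius_mossotti
#' @param f_lo,f_hi Bracket in Hz, `f_lo < f_hi`.
#' @param tol Tolerance on `|Re[K]|` at the returned root, default `1e-6`.
#' @param n_scan Number of log-spaced scan points used to locate a sign
#'   change, default 256.
#' @return Crossover frequency in Hz, or `NULL` if there is no sign change.
#' @export
#' @examples
#' # a low-conductivity, high-permittivity particle: conduction-dominated
#' # nDEP at low frequency, dielectric pDEP at high frequency
#' p <- cell_dielectric(cytoplasm = dielectric_material(100, 1e-4))
#' crossover_frequency(p, dep_medium(), 1e3, 5e7)
crossover_frequency <- function(cell, medium, f_lo, f_hi,
                                tol = 1e-6, n_scan = 256) {
  stopifnot(f_lo > 0, f_lo < f_hi)
  rek <- function(f) clausius_mossotti(cell, medium, 2 * pi * f)$real_part
  fs <- exp(seq(log(f_lo), log(f_hi), length.out = n_scan))
  vals <- rek(fs)
  sgn <- sign(vals)
  flip <- which(sgn[-1] * sgn[-n_scan] < 0)
  if (length(flip) == 0) return(NULL)
  k <- flip[1]
  root <- uniroot(rek, lower = fs[k], upper = fs[k + 1],
                  tol = .Machine$double.eps^0.5)$root
  # polish until |Re[K]| < tol
  if (abs(rek(root)) >= tol) {
    root <- uniroot(rek, lower = fs[k], upper = fs[k + 1],
                    tol = .Machine$double.eps)$root
  }
  root
}
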