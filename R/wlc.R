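#' Contour length of a coarse-grained actin filament
#'
#' Relates the filament contour length to the crosslink density R, the
#' F-actin diameter and the F-actin concentration:
#' \deqn{L_c = \kappa\,\frac{R^{0.2} d_{Actin}}{2}\sqrt{\pi/C_{AF}}.}
#' The inputs mix units (nm, uM); `lc_scale` (\eqn{\kappa}, default 100) is
#' the single documented conversion constant that maps the raw nm-scale
#' quotient to micrometres so that physiological parameter scales
#' (C_AF around 15 uM, d_Actin = 7 nm, R in 1--100) give contour lengths in
#' the 0.1--3 um range typical of crosslinked cortical actin.
#'
#' @param r_crosslink Crosslink density R (dimensionless, > 0).
#' @param d_actin F-actin diameter in nm (> 0), default 7.
#' @param c_af F-actin concentration in uM (> 0).
#' @param lc_scale Conversion constant \eqn{\kappa}, default 100.
#' @return Contour length in um.
#' @export
#' @examples
#' contour_length(2, 7, 15)
contour_length <- function(r_crosslink, d_actin = 7, c_af, lc_scale = 100) {
  if (any(c(r_crosslink, d_actin, c_af, lc_scale) <= 0))
    abort("All contour-length inputs must be > 0.")
  lc_scale * (r_crosslink^0.2 * d_actin / 2) * sqrt(pi / c_af) * 1e-3
}

#' Worm-like-chain filament force
#'
#' MacKintosh-style force-extension law of a semiflexible filament,
#' \deqn{f_a = \frac{81 k_B T L_p^2 L_c^2 (\Delta r + \delta r_0)}
#'   {(L_c^2 - 6L_p\Delta r - 6L_p\delta r_0)^2
#'    (L_c^2 + 3L_p\Delta r + 3L_p\delta r_0)},}
#' with \eqn{\Delta r} the extension beyond the rest end-to-end distance and
#' \eqn{\delta r_0} the built-in pre-extension from cytoskeletal prestress.
#' The force is zero at \eqn{\Delta r + \delta r_0 = 0}, strictly increasing,
#' and diverges as the total extension approaches the finite limit
#' \eqn{L_c^2/(6 L_p) - \delta r_0} (see [wlc_extension_limit()]).
#'
#' @param delta_r Extension in um (may be a vector; negative = compression).
#' @param delta_r0 Pre-extension in um, default 0.
#' @param l_p Persistence length in um.
#' @param l_c Contour length in um.
#' @param temperature Absolute temperature in K, default 300.
#' @return Force in N (positive = tension).
#' @export
#' @examples
#' wlc_force(1e-4, 0, l_p = 10, l_c = 0.3)
wlc_force <- function(delta_r, delta_r0 = 0, l_p, l_c, temperature = 300) {
  stopifnot(l_p > 0, l_c > 0, temperature > 0)
  kBT <- physical_constants()$kB * temperature
  lp <- l_p * 1e-6; lc <- l_c * 1e-6
  x <- (delta_r + delta_r0) * 1e-6
  lc2 <- lc^2
  d1 <- lc2 - 6 * lp * x
  d2 <- lc2 + 3 * lp * x
  if (any(d1 <= 0) || any(d2 <= 0))
    abort(sprintf(
      "WLC extension at/beyond its divergence; the extension limit is %g um.",
      wlc_extension_limit(l_p, l_c, delta_r0)),
      class = "cytostretch_domain_error")
  81 * kBT * lp^2 * lc2 * x / (d1^2 * d2)
}

#' Extension limit of the WLC law
#'
#' The finite extension \eqn{L_c^2/(6L_p) - \delta r_0} at which the filament
#' force diverges.
#'
#' @inheritParams wlc_force
#' @return Limit in um.
#' @export
wlc_extension_limit <- function(l_p, l_c, delta_r0 = 0) {
  l_c^2 / (6 * l_p) - delta_r0
}

#' Hookean crosslinker (ABP) force
#'
#' Actin-binding proteins are modeled as linear springs of stiffness `k_c`.
#'
#' @param extension Spring extension in um (signed).
#' @param k_c Spring stiffness in N/m.
#' @return Force in N (signed; positive = tension).
#' @export
#' @examples
#' abp_force(0.1, 1e-5)
abp_force <- function(extension, k_c) {
  stopifnot(is.numeric(extension), is.numeric(k_c), all(k_c >= 0))
  k_c * extension * 1e-6
}
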