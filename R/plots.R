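#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_errorbar
#'   geom_raster geom_segment scale_fill_viridis_c coord_equal labs
#'   theme_minimal .data
#' @export
ggplot2::autoplot

#' Plot a strain-force curve
#'
#' Mean strain against applied force (in nN) with standard-error bars when
#' present.
#'
#' @param object A [strain_force_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strain_force_curve <- function(object, ...) {
  df <- as_tibble(object)
  df$force_nN <- df$force_N * 1e9
  p <- ggplot(df, aes(x = .data$force_nN, y = .data$strain_mean)) +
    geom_line(color = "grey50") +
    geom_point() +
    labs(x = "Force (nN)", y = "Strain",
         title = attr(object, "label") %||% NULL) +
    theme_minimal()
  if (has_se(object)) {
    p <- p + geom_errorbar(aes(ymin = .data$strain_mean - .data$strain_se,
                               ymax = .data$strain_mean + .data$strain_se),
                           width = 0)
  }
  p
}

#' Plot the field magnitude of a solved chip
#'
#' Raster of `|E|` over the 2D cross-section (um axes).
#'
#' @param object A [solve_potential()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.field_solution <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$x_m * 1e6, y = .data$y_m * 1e6,
                 fill = .data$e_mag)) +
    geom_raster() +
    scale_fill_viridis_c(name = "|E| (V/m)") +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
}

#' Plot an actin network projection
#'
#' x-y projection of filament (dark) and ABP (light) edges, with pole-cap
#' vertices highlighted.
#'
#' @param object An [build_network()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.actin_network <- function(object, ...) {
  v <- object$vertices
  seg <- function(edges, kind) {
    tibble(x = v[edges$a, 1], y = v[edges$a, 2],
           xend = v[edges$b, 1], yend = v[edges$b, 2], kind = kind)
  }
  edges <- bind_rows(seg(object$fil_edges, "filament"),
                     seg(object$abp_edges, "ABP"))
  poles <- tidy(object)
  poles <- filter(poles, .data$pole != "none")
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, color = .data$kind),
                 linewidth = 0.2, alpha = 0.5) +
    geom_point(data = poles, aes(x = .data$x, y = .data$y), size = 0.6) +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)", color = NULL) +
    theme_minimal()
}

#' Plot a Clausius--Mossotti spectrum
#'
#' `Re[K]` against frequency on a log axis, with the pDEP/nDEP boundary.
#'
#' @param cell A [cell_dielectric()].
#' @param medium A [dielectric_material()].
#' @param f_lo,f_hi Frequency range in Hz.
#' @param n Number of points, default 400.
#' @return A ggplot.
#' @export
plot_cm_spectrum <- function(cell, medium, f_lo = 1e2, f_hi = 1e8, n = 400) {
  df <- cm_spectrum(cell, medium, exp(seq(log(f_lo), log(f_hi),
                                          length.out = n)))
  ggplot(df, aes(x = .data$frequency, y = .data$re_k)) +
    geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey40") +
    ggplot2::scale_x_log10() +
    labs(x = "Frequency (Hz)", y = "Re[K]") +
    theme_minimal()
}
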