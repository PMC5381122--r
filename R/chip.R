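#' Microfluidic chip model (2D side-view cross-section)
#'
#' Geometry and drive of the electro-deformation chip, modeled as a 2D
#' side-view rectangle of the microchannel: height 50 um (the channel
#' height), a truncated 100 um width around the electrode pair (the full
#' 5000 um channel adds nothing near the gap), and zero-thickness planar
#' electrodes patterned on the bottom wall separated by a gap `d`. One
#' electrode is driven at the voltage amplitude, the other grounded; all
#' remaining boundaries are electrically insulated.
#'
#' @param domain_width Domain width in m, default `100e-6`.
#' @param domain_height Channel height in m, default `50e-6`.
#' @param gap Electrode gap d in m, default `20e-6`.
#' @param electrode_length Length of each electrode segment in m, default
#'   `30e-6`.
#' @param driven_potential Voltage amplitude U on the driven electrode in V,
#'   default 2.
#' @param grid_spacing Cell size of the uniform Cartesian grid in m, default
#'   `0.25e-6`.
#' @param out_of_plane_thickness Constant thickness used to turn 2D contour
#'   integrals into 3D forces, in m; default `14e-6` (one cell diameter).
#' @param electrodes Optional explicit electrode list overriding the
#'   tip-to-tip layout; a list of `list(side, x0, x1, potential)` entries
#'   with `side` in `"bottom"`/`"top"` and `potential` either the driven
#'   amplitude or 0.
#' @return An object of class `chip_model`.
#' @export
#' @examples
#' chip_model()
#' fixture_chip("parallel_plate")
chip_model <- function(domain_width = 100e-6,
                       domain_height = 50e-6,
                       gap = 20e-6,
                       electrode_length = 30e-6,
                       driven_potential = 2,
                       grid_spacing = 0.25e-6,
                       out_of_plane_thickness = 14e-6,
                       electrodes = NULL) {
  stopifnot(domain_width > 0, domain_height > 0, grid_spacing > 0,
            out_of_plane_thickness > 0)
  if (gap <= 0) abort("`gap` must be > 0.")
  gap_x <- c((domain_width - gap) / 2, (domain_width + gap) / 2)
  if (is.null(electrodes)) {
    if (gap_x[1] - electrode_length < 0)
      abort("Electrodes do not fit in the domain; widen `domain_width`.")
    electrodes <- list(
      list(side = "bottom", x0 = gap_x[1] - electrode_length, x1 = gap_x[1],
           potential = driven_potential),
      list(side = "bottom", x0 = gap_x[2], x1 = gap_x[2] + electrode_length,
           potential = 0)
    )
  }
  for (e in electrodes) {
    if (!e$side %in% c("bottom", "top")) abort("Electrode side must be bottom/top.")
    if (e$x0 >= e$x1 || e$x0 < -1e-12 || e$x1 > domain_width + 1e-12)
      abort("Electrode segment outside the domain boundary.")
  }
  # overlap check on same side
  for (side in c("bottom", "top")) {
    segs <- Filter(function(e) e$side == side, electrodes)
    if (length(segs) > 1) {
      ord <- order(vapply(segs, `[[`, 0, "x0"))
      segs <- segs[ord]
      for (k in seq_len(length(segs) - 1))
        if (segs[[k]]$x1 > segs[[k + 1]]$x0 + 1e-15)
          abort("Electrode segments overlap.")
    }
  }
  nx <- round(domain_width / grid_spacing)
  ny <- round(domain_height / grid_spacing)
  if (abs(nx * grid_spacing - domain_width) > 1e-12 ||
      abs(ny * grid_spacing - domain_height) > 1e-12)
    abort("`grid_spacing` must divide the domain dimensions.")
  structure(list(domain_width = domain_width, domain_height = domain_height,
                 gap = gap, gap_x = gap_x,
                 electrode_length = electrode_length,
                 driven_potential = driven_potential,
                 grid_spacing = grid_spacing,
                 out_of_plane_thickness = out_of_plane_thickness,
                 electrodes = electrodes, nx = nx, ny = ny),
            class = "chip_model")
}

#' @export
print.chip_model <- function(x, ...) {
  cat(sprintf(paste0("<chip_model> %g x %g um, gap %g um, U = %g V, ",
                     "h = %g um (%d x %d cells)\n"),
              x$domain_width * 1e6, x$domain_height * 1e6, x$gap * 1e6,
              x$driven_potential, x$grid_spacing * 1e6, x$nx, x$ny))
  invisible(x)
}

#' Dielectric particle inclusion
#'
#' A circular (disc, in the 2D cross-section) dielectric particle placed in
#' the chip, representing the captured cell in the field model.
#'
#' @param center Numeric length-2, particle center (x, y) in m.
#' @param radius Particle radius in m.
#' @param material A [dielectric_material()] for the particle interior.
#' @return An object of class `particle_inclusion`.
#' @export
particle_inclusion <- function(center, radius,
                               material = dielectric_material(60, 0.2)) {
  stopifnot(is.numeric(center), length(center) == 2, radius > 0,
            inherits(material, "dielectric_material"))
  structure(list(center = center, radius = radius, material = material),
            class = "particle_inclusion")
}

#' Default captured-cell particle for a chip
#'
#' Places the cell where stretching happens: laterally at the inner edge of
#' the driven electrode (the gap edge where cells are captured by pDEP),
#' vertically resting near the bottom wall at height radius + standoff. The
#' small standoff keeps the Maxwell-stress integration contour strictly
#' inside the solution domain.
#'
#' @param chip A [chip_model()].
#' @param cell A [cell_dielectric()].
#' @param standoff Clearance between particle bottom and the wall in m,
#'   default `1e-6`.
#' @return A [particle_inclusion()] with the cell's cytoplasm material.
#' @export
chip_particle <- function(chip, cell = cell_dielectric(), standoff = 1e-6) {
  stopifnot(inherits(chip, "chip_model"), inherits(cell, "cell_dielectric"))
  particle_inclusion(center = c(chip$gap_x[1], cell$radius + standoff),
                     radius = cell$radius, material = cell$cytoplasm)
}

#' Fixture chip geometries
#'
#' Ready-made chip models used throughout the tests and examples:
#' `"tip_to_tip"` is the default electro-deformation layout (coplanar
#' electrodes on the bottom wall, 20 um gap); `"parallel_plate"` covers the
#' full bottom and top walls with the two electrodes, which admits the exact
#' analytic solution `|E| = U/d` with `d = domain_height`.
#'
#' @param kind `"tip_to_tip"` or `"parallel_plate"`.
#' @param ... Passed on to [chip_model()] (e.g. `grid_spacing`,
#'   `driven_potential`).
#' @return A [chip_model()].
#' @export
fixture_chip <- function(kind = c("tip_to_tip", "parallel_plate"), ...) {
  kind <- match.arg(kind)
  if (kind == "tip_to_tip") return(chip_model(...))
  args <- list(...)
  w <- args$domain_width %||% 100e-6
  h <- args$domain_height %||% 50e-6
  u <- args$driven_potential %||% 2
  args$gap <- h
  args$electrodes <- list(
    list(side = "bottom", x0 = 0, x1 = w, potential = u),
    list(side = "top", x0 = 0, x1 = w, potential = 0)
  )
  do.call(chip_model, args)
}
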