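#' DEP force by all three estimators across a drive protocol
#'
#' Computes, for each drive level, the simplified parallel-field estimate,
#' the equivalent-dipole (EDM) estimate (CM factor x gradient of the
#' squared RMS field from the particle-free solution, probed at the cell
#' center), and the Maxwell-stress-tensor (MST) force on the captured-cell
#' particle. The field problem is linear in the drive voltage, so the two
#' field solutions are computed once at 1 V and the quadratic scaling
#' \eqn{F \propto U^2} gives every level exactly.
#'
#' @param drives List of [drive()] objects (all at one frequency), default
#'   [dep_drive_protocol()].
#' @param chip A [chip_model()]; its `driven_potential` is overridden per
#'   drive level.
#' @param cell A [cell_dielectric()].
#' @param medium A [dielectric_material()].
#' @param standoff Particle standoff above the wall, see [chip_particle()].
#' @return A tibble with columns `voltage_V`, `edm_nN`, `mst_nN`,
#'   `simplified_nN` (force magnitudes in nN).
#' @export
#' @examples
#' \donttest{
#' dep_force_table(chip = chip_model(grid_spacing = 1e-6))
#' }
dep_force_table <- function(drives = dep_drive_protocol(),
                            chip = chip_model(),
                            cell = cell_dielectric(),
                            medium = dep_medium(),
                            standoff = 1e-6) {
  stopifnot(length(drives) >= 1)
  freqs <- vapply(drives, `[[`, 0, "frequency")
  if (diff(range(freqs)) > 1e-9 * freqs[1])
    abort("All drives must share one frequency (the solve is per frequency).")
  omega <- 2 * pi * freqs[1]
  volts <- vapply(drives, `[[`, 0, "voltage_amplitude")

  chip1 <- chip
  chip1$driven_potential <- 1
  chip1$electrodes <- lapply(chip1$electrodes, function(e) {
    if (e$potential != 0) e$potential <- 1
    e
  })
  particle <- chip_particle(chip1, cell, standoff)
  sol0 <- solve_potential(chip1, medium, omega)
  solp <- solve_potential(chip1, medium, omega, particle)

  re_k <- clausius_mossotti(cell, medium, omega)$real_part
  g1 <- grad_e2_at(sol0, particle$center, rms = TRUE)
  f_edm1 <- sqrt(sum(dep_force_edm(cell, medium, re_k, g1)^2))
  f_mst1 <- sqrt(sum(integrate_mst(solp)^2))

  tibble(
    voltage_V = volts,
    edm_nN = f_edm1 * volts^2 * 1e9,
    mst_nN = f_mst1 * volts^2 * 1e9,
    simplified_nN = vapply(drives, function(d)
      dep_force_simplified(d, chip$gap, cell, medium), 0) * 1e9
  )
}
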