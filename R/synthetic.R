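#' Observation-noise model for synthetic strain data
#'
#' Per-cell additive Gaussian noise on the measured strain, plus the number
#' of cells examined per force level. The default cell count mirrors the
#' replication of the electro-deformation experiments (more than 50 cells
#' per group).
#'
#' @param strain_sd Per-cell strain observation noise (dimensionless,
#'   >= 0), default 0.03.
#' @param n_cells Cells per level (>= 1), default 50.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(strain_sd = 0.03, n_cells = 50) {
  if (strain_sd < 0) abort("`strain_sd` must be >= 0.")
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  structure(list(strain_sd = strain_sd, n_cells = as.integer(n_cells)),
            class = "noise_model")
}

#' Generate a noisy synthetic strain-force dataset
#'
#' Emulates a mean +/- SE strain-force dataset: for each force level,
#' `n_cells` networks are simulated (distinct seeds, one per cell), each
#' cell's strain receives zero-mean Gaussian observation noise of sd
#' `strain_sd`, and the per-level mean, standard error (`sd/sqrt(n_cells)`)
#' and count are reported. Deterministic for a fixed seed.
#'
#' @param true_params A [network_params()] describing the cells.
#' @param forces Non-negative increasing force levels in N.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param config Relaxation protocol, as in [simulate_stretch_curve()].
#' @param label Optional curve label (e.g. `"control"`).
#' @return A [strain_force_curve()].
#' @export
#' @examples
#' \donttest{
#' generate_strain_force_data(network_params(n_af = 150), c(1e-9, 2e-9),
#'                            noise_model(0.02, 5), seed = 1)
#' }
generate_strain_force_data <- function(true_params, forces,
                                       noise = noise_model(), seed = 1,
                                       config = relax_config(max_iterations = 2000),
                                       label = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  strains <- stretch_strain_matrix(true_params, forces, noise$n_cells,
                                   seed, config)
  eps <- withr::with_seed(as.integer(seed) + 1L,
                          matrix(rnorm(length(strains), 0, noise$strain_sd),
                                 nrow(strains), ncol(strains)))
  obs <- strains + eps
  strain_force_curve(tibble(
    force_N = forces,
    strain_mean = rowMeans(obs),
    strain_se = if (noise$n_cells > 1) {
      apply(obs, 1, sd) / sqrt(noise$n_cells)
    } else {
      rep(0, length(forces))
    },
    n = noise$n_cells
  ), label = label)
}

#' The stepped voltage protocol of the stretching experiments
#'
#' The six drive levels used for the force-estimation comparison:
#' amplitudes 1.5 to 4 V in 0.5 V steps (3 to 8 V peak-to-peak) at the
#' 1 MHz operating frequency chosen to maximize the CM factor while
#' limiting Joule heating.
#'
#' @return A list of six [drive()] objects.
#' @export
#' @examples
#' vapply(dep_drive_protocol(), function(d) d$voltage_amplitude, 0)
dep_drive_protocol <- function() {
  lapply(seq(1.5, 4, by = 0.5), drive, frequency = 1e6)
}
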