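#' Read a strain-force curve from CSV
#'
#' Parses the curve format written by [write_curve()]: comment lines
#' starting with `#`, then a header `force_N,strain_mean[,strain_se,n]`.
#' Column invariants (strictly increasing forces, non-negative SE) are
#' validated; a missing `strain_se` column simply leaves the curve
#' unweighted in fits.
#'
#' @param path File path.
#' @param label Optional label attached to the curve.
#' @return A [strain_force_curve()].
#' @export
#' @examples
#' demo <- system.file("extdata", "demo_curve_synthetic.csv",
#'                     package = "cytostretch")
#' read_curve(demo, label = "synthetic demo")
read_curve <- function(path, label = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) abort(sprintf("Cannot parse %s: %s", path,
                                      conditionMessage(e)), parent = e))
  probs <- readr::problems(df)
  if (nrow(probs) > 0)
    abort(sprintf("Malformed curve CSV %s (first problem at line %d: %s).",
                  path, probs$row[1], probs$expected[1]),
          class = "cytostretch_parse_error")
  if (!all(c("force_N", "strain_mean") %in% names(df)))
    abort(sprintf("Curve CSV %s must have columns force_N,strain_mean.", path),
          class = "cytostretch_parse_error")
  strain_force_curve(df, label = label)
}

#' Write a strain-force curve to CSV
#'
#' Writes a commented header (seed and configuration hash when supplied,
#' so every artifact records how to regenerate it) followed by the curve
#' columns in fixed order. Floats are serialized with 9 significant
#' digits; the byte output is deterministic for fixed input.
#'
#' @param curve A [strain_force_curve()].
#' @param path Output path.
#' @param seed Optional integer recorded in the header.
#' @param config_hash Optional configuration hash recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_curve <- function(curve, path, seed = NULL, config_hash = NULL) {
  curve <- strain_force_curve(curve, label = attr(curve, "label"))
  cols <- intersect(c("force_N", "strain_mean", "strain_se", "n"),
                    names(curve))
  header <- c("# cytostretch strain-force curve",
              if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
              if (!is.null(config_hash)) sprintf("# config_hash: %s",
                                                 config_hash))
  fmt <- function(x) {
    if (is.numeric(x) && !all(x == round(x))) sprintf("%.9g", x)
    else as.character(x)
  }
  body <- vapply(seq_len(nrow(curve)), function(i)
    paste(vapply(cols, function(cn) fmt(curve[[cn]][i]), ""), collapse = ","),
    "")
  out <- tryCatch(
    writeLines(c(header, paste(cols, collapse = ","), body), path),
    error = function(e) abort(sprintf("Cannot write %s: %s", path,
                                      conditionMessage(e)), parent = e))
  invisible(path)
}

#' Read a YAML or JSON configuration file
#'
#' Dispatches on the file extension (`.yaml`/`.yml` via yaml, `.json` via
#' jsonlite); used by the command-line interface for chip, network and
#' bounds configuration.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort(sprintf("Unsupported config extension '.%s' (use yaml or json).",
                  ext))
  }
}

# canonical parameter names from field-style aliases (Table-2 symbols)
canonical_param_names <- function(x) {
  alias <- c(R_E = "r_e", R_I = "r_i", C_AF = "c_af", N_AF = "n_af",
             R = "r_crosslink", delta_r0 = "delta_r0", L_p = "l_p",
             d_Actin = "d_actin", k_c = "k_c", T = "temperature",
             eta = "eta")
  nm <- names(x)
  hit <- nm %in% names(alias)
  nm[hit] <- alias[nm[hit]]
  names(x) <- nm
  x
}

#' Build network parameters from a configuration list
#'
#' Accepts either the package's argument names (`c_af`, `r_e`, ...) or the
#' field's symbols (`C_AF`, `R_E`, `R`, ...).
#'
#' @param cfg Named list.
#' @return A [network_params()].
#' @export
params_from_config <- function(cfg) {
  cfg <- canonical_param_names(cfg)
  known <- names(formals(network_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    abort(sprintf("Unknown network parameter(s): %s.",
                  paste(unknown, collapse = ", ")))
  do.call(network_params, cfg)
}

#' Build a chip model from a configuration list
#'
#' @param cfg Named list of [chip_model()] arguments.
#' @return A [chip_model()].
#' @export
chip_from_config <- function(cfg) {
  known <- names(formals(chip_model))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    abort(sprintf("Unknown chip parameter(s): %s.",
                  paste(unknown, collapse = ", ")))
  do.call(chip_model, cfg)
}

#' Export a field solution as CSV
#'
#' Writes the potential (real and imaginary parts) and field magnitude on
#' the cell-centered grid in long format (`x_m,y_m,phi_re,phi_im,e_mag`).
#'
#' @param solution A [solve_potential()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_field_csv <- function(solution, path) {
  stopifnot(inherits(solution, "field_solution"))
  grid <- tidyr::expand_grid(y_m = solution$y, x_m = solution$x)
  grid <- grid[, c("x_m", "y_m")]
  df <- mutate(grid,
               phi_re = as.vector(Re(solution$phi)),
               phi_im = as.vector(Im(solution$phi)),
               e_mag = as.vector(sqrt(solution$e2)))
  readr::write_csv(df, path)
  invisible(path)
}
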