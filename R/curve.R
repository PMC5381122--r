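#' Strain-force curve
#'
#' The tabular result type shared by simulation, synthetic data generation
#' and fitting: one row per force level with the mean strain, its standard
#' error and the replicate count. A `strain_force_curve` is a tibble with
#' columns `force_N`, `strain_mean`, and optionally `strain_se` and `n`,
#' plus a `label` attribute (e.g. the cell group).
#'
#' @param x A data frame with at least `force_N` and `strain_mean`.
#' @param label Optional text label carried in the `label` attribute.
#' @return A `strain_force_curve` tibble.
#' @export
#' @examples
#' strain_force_curve(tibble::tibble(force_N = c(1e-9, 2e-9),
#'                                   strain_mean = c(0.05, 0.11)))
strain_force_curve <- function(x, label = NULL) {
  x <- as_tibble(x)
  if (!all(c("force_N", "strain_mean") %in% names(x)))
    abort("Curve needs columns `force_N` and `strain_mean`.")
  if (nrow(x) == 0) abort("Curve has no rows.")
  if (any(!is.finite(x$force_N)) || any(!is.finite(x$strain_mean)))
    abort("Non-finite values in curve.")
  if (is.unsorted(x$force_N, strictly = TRUE))
    abort("`force_N` must be strictly increasing.",
          class = "cytostretch_validation_error")
  if ("strain_se" %in% names(x) && any(x$strain_se < 0, na.rm = TRUE))
    abort("`strain_se` must be >= 0.")
  if ("n" %in% names(x) && any(x$n < 1, na.rm = TRUE))
    abort("`n` must be >= 1.")
  keep <- intersect(c("force_N", "strain_mean", "strain_se", "n"), names(x))
  x <- x[keep]
  class(x) <- c("strain_force_curve", class(x))
  attr(x, "label") <- label
  x
}

#' @export
print.strain_force_curve <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf("# strain-force curve%s (%d levels)\n",
              if (is.null(lbl)) "" else paste0(" [", lbl, "]"), nrow(x)))
  NextMethod()
}

has_se <- function(curve) {
  "strain_se" %in% names(curve) && !all(is.na(curve$strain_se))
}
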