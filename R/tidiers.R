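#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parameter fit
#'
#' One row per free parameter with its estimate.
#'
#' @param x A `cyto_fit` from [fit_parameters()].
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `estimate`.
#' @export
tidy.cyto_fit <- function(x, ...) {
  tibble(parameter = names(x$theta), estimate = unname(x$theta))
}

#' @rdname tidy.cyto_fit
#' @return For `glance`: a one-row tibble with `loss`, `n_evaluations`,
#'   `converged`.
#' @export
glance.cyto_fit <- function(x, ...) {
  tibble(loss = x$loss, n_evaluations = x$n_evaluations,
         converged = x$converged)
}

#' Tidy a modulus fit
#'
#' @param x A `modulus_fit` from [estimate_modulus()].
#' @param ... Unused.
#' @return A tibble with `term`/`estimate` rows (the modulus slope).
#' @export
tidy.modulus_fit <- function(x, ...) {
  tibble(term = "modulus_Pa", estimate = x$modulus)
}

#' @rdname tidy.modulus_fit
#' @return For `glance`: one row with `modulus`, `r_squared`,
#'   `area_convention`, `n_levels`.
#' @export
glance.modulus_fit <- function(x, ...) {
  tibble(modulus = x$modulus, r_squared = x$r_squared,
         area_convention = x$area_convention, n_levels = x$n_levels)
}

#' Tidy an actin network
#'
#' @param x An `actin_network`.
#' @param ... Unused.
#' @return A tibble of vertices (`vertex`, `x`, `y`, `z`, `pole`).
#' @export
tidy.actin_network <- function(x, ...) {
  pole <- rep("none", nrow(x$vertices))
  pole[x$pole_plus] <- "plus"
  pole[x$pole_minus] <- "minus"
  v <- x$vertices
  tibble(vertex = seq_len(nrow(v)),
         x = v[, 1], y = v[, 2], z = v[, 3], pole = pole)
}

#' Tidy a field solution
#'
#' @param x A `field_solution`.
#' @param ... Unused.
#' @return A long tibble (`x_m`, `y_m`, `phi_re`, `phi_im`, `e_mag`).
#' @export
tidy.field_solution <- function(x, ...) {
  grid <- tidyr::expand_grid(y_m = x$y, x_m = x$x)[, c("x_m", "y_m")]
  mutate(grid,
         phi_re = as.vector(Re(x$phi)),
         phi_im = as.vector(Im(x$phi)),
         e_mag = as.vector(sqrt(x$e2)))
}
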