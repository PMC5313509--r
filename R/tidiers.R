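#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted decoder into one row per voxel
#'
#' @param x a `decoder_fit`.
#' @param nonzero_only keep only nonzero coefficients.
#' @param ... unused.
#' @return Tibble with columns `voxel`, `x`, `y`, `z`, `beta`.
#' @export
tidy.decoder_fit <- function(x, nonzero_only = FALSE, ...) {
  coords <- x$grid$coords # grab everything before the `x` column masks `x`
  beta <- x$beta
  out <- tibble::tibble(
    voxel = seq_len(nrow(coords)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    beta = beta)
  if (nonzero_only) out <- dplyr::filter(out, .data$beta != 0)
  out
}

#' One-row summary of a fitted decoder
#'
#' @param x a `decoder_fit`.
#' @param fraction l1-mass fraction used to report sparsity.
#' @param ... unused.
#' @return Tibble: family, hyperparameters (as a packed label), objective,
#'   iterations, convergence flag, sparsity.
#' @export
glance.decoder_fit <- function(x, fraction = 1e-4, ...) {
  hp <- x$spec[setdiff(names(x$spec), "family")]
  sp <- support_and_sparsity(threshold_coefficients(x$beta, fraction),
                             x$grid$p)
  tibble::tibble(
    family = x$spec$family,
    hyperparameters = paste(sprintf("%s=%g", names(hp), unlist(hp)),
                            collapse = ", "),
    objective = x$objective, iterations = x$iterations,
    converged = isTRUE(x$converged), sparsity = sp$sparsity)
}

#' Tidy a stability summary into one row per signature pair
#'
#' @param x a [stability_summary()].
#' @param ... unused.
#' @return Tibble with `s`, `s_prime`, `overlap`, `corrected`,
#'   `correlation`, `expected` for each ordered off-diagonal pair.
#' @export
tidy.stability_summary <- function(x, ...) {
  n <- x$n
  pairs <- which(row(x$overlap) != col(x$overlap), arr.ind = TRUE)
  tibble::tibble(
    s = pairs[, 1], s_prime = pairs[, 2],
    overlap = x$overlap[pairs], corrected = x$corrected[pairs],
    correlation = x$correlation[pairs], expected = x$expected[pairs])
}

#' @export
glance.stability_summary <- function(x, ...) {
  tibble::tibble(n = x$n, o_bar = x$o_bar, oc_bar = x$oc_bar,
                 c_bar = x$c_bar, sparsity_mean = mean(x$sparsity),
                 sparsity_sd = stats::sd(x$sparsity))
}

#' Tidy a nested-LOSO selection result
#'
#' One row per criterion and external fold: the chosen hyperparameters,
#' the held-out subject's accuracy, and the signature sparsity.
#'
#' @param x a `selection_result`.
#' @param ... unused.
#' @export
tidy.selection_result <- function(x, ...) {
  x$folds
}

#' One row per criterion, in the style of a method-performance table
#'
#' @param x a `selection_result`.
#' @param ... unused.
#' @export
glance.selection_result <- function(x, ...) {
  x$summary
}
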