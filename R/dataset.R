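#' Decoding dataset: feature matrix, labels, subjects, grid
#'
#' Bundles the design matrix of in-mask voxel features (one row per scan),
#' binary labels in `{-1, +1}`, per-scan subject identifiers, and the
#' [voxel_grid()] the columns live on. Leave-one-subject-out schemes and the
#' per-subject (macro) accuracy require every subject to contribute at least
#' one example of each class.
#'
#' @param X numeric matrix, `m x p` with `p = grid$p`.
#' @param y labels; coerced to `-1/+1` (accepts `-1/1`, `0/1` or a
#'   two-level factor mapped by level order to `-1, +1`).
#' @param subject vector of length `m` of subject identifiers.
#' @param grid a [voxel_grid()].
#' @return An object of class `decode_dataset` with fields `X`, `y`,
#'   `subject` (character), `grid`, `m`, `p`.
#' @export
decode_dataset <- function(X, y, subject, grid) {
  if (!is_voxel_grid(grid)) stop("`grid` must be a voxel_grid.", call. = FALSE)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L) stop("`X` has no rows.", call. = FALSE)
  if (ncol(X) != grid$p) {
    stop(sprintf("`X` has %d columns but grid$p = %d.", ncol(X), grid$p),
         call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("`X` contains NA/NaN/Inf values.", call. = FALSE)
  }
  y <- coerce_labels(y)
  if (length(y) != nrow(X)) stop("`y` length must match nrow(X).", call. = FALSE)
  subject <- as.character(subject)
  if (length(subject) != nrow(X)) {
    stop("`subject` length must match nrow(X).", call. = FALSE)
  }
  tab <- table(subject, y)
  if (any(tab == 0L)) {
    bad <- rownames(tab)[apply(tab == 0L, 1L, any)]
    stop("every subject needs at least one example of each class; violated by: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(X = X, y = y, subject = subject, grid = grid,
         m = nrow(X), p = ncol(X)),
    class = "decode_dataset"
  )
}

coerce_labels <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("label factor must have exactly 2 levels.",
                               call. = FALSE)
    return(ifelse(as.integer(y) == 1L, -1, 1))
  }
  y <- as.numeric(y)
  if (anyNA(y)) stop("labels must not contain NA.", call. = FALSE)
  u <- sort(unique(y))
  if (identical(u, c(-1, 1))) return(y)
  if (identical(u, c(0, 1))) return(2 * y - 1)
  if (identical(u, -1) || identical(u, 1) || identical(u, 0)) {
    stop("labels contain a single class; two classes are required.",
         call. = FALSE)
  }
  stop("labels must be binary (-1/+1, 0/1, or a two-level factor).",
       call. = FALSE)
}

#' @export
print.decode_dataset <- function(x, ...) {
  cat(sprintf("<decode_dataset> m = %d scans, p = %d voxels, %d subjects\n",
              x$m, x$p, length(unique(x$subject))))
  invisible(x)
}

#' Subset a dataset by row index
#'
#' @param data a [decode_dataset()].
#' @param idx integer row indices to keep.
#' @return A `decode_dataset` on the same grid.
#' @keywords internal
dataset_rows <- function(data, idx) {
  decode_dataset(data$X[idx, , drop = FALSE], data$y[idx],
                 data$subject[idx], data$grid)
}

#' Mean squared-error data-fit term
#'
#' `E(beta) = (1/m) * ||X beta - y||_2^2`, the square loss used by all six
#' decoder families.
#'
#' @param beta numeric vector of length `p`.
#' @param data a [decode_dataset()].
#' @return Nonnegative scalar.
#' @examples
#' g <- voxel_grid(array(TRUE, c(2, 1, 1)))
#' d <- decode_dataset(diag(2), c(1, -1), c("a", "a"), g)
#' data_fit(c(1, -1), d)  # exact interpolation: 0
#' @export
data_fit <- function(beta, data) {
  stopifnot(inherits(data, "decode_dataset"))
  beta <- check_beta(beta, data$grid)
  r <- data$X %*% beta - data$y
  sum(r^2) / data$m
}
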