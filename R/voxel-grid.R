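#' Masked 3D voxel grid
#'
#' A `voxel_grid` records the geometry shared by all structured penalties: a
#' 3D bounding box, a logical mask selecting the `p` voxels that carry
#' coefficients (e.g. gray matter), and the index maps between the linear
#' in-mask index `1..p` and grid coordinates `(i, j, k)`. Neighborhood is
#' face adjacency (6-connectivity), matching the three axis-aligned backward
#' differences used by the total-variation and Laplacian penalties; voxels
#' excluded by the mask behave exactly like the grid boundary.
#'
#' @param mask A logical (or 0/1 numeric) 3D array. 1D/2D inputs are
#'   promoted to 3D by appending singleton dimensions, so line and slab
#'   geometries can be used directly in tests and examples.
#' @return An object of class `voxel_grid` with components
#'   \describe{
#'     \item{shape}{integer triple `(nx, ny, nz)`.}
#'     \item{mask}{the logical 3D mask.}
#'     \item{p}{number of in-mask voxels.}
#'     \item{coords}{`p x 3` integer matrix of 1-based grid coordinates of
#'       each in-mask voxel, in linear (column-major) mask order.}
#'     \item{vox_of}{integer array of the mask's shape: 0 off-mask,
#'       otherwise the in-mask index.}
#'     \item{nbr_back}{`p x 3` integer matrix; entry `(v, l)` is the in-mask
#'       index of the backward face neighbor of voxel `v` along axis `l`,
#'       or 0 when that neighbor is outside the grid or off-mask.}
#'   }
#' @examples
#' g <- voxel_grid(array(TRUE, c(3, 3, 3)))
#' g$p
#' @export
voxel_grid <- function(mask) {
  if (is.logical(mask) || is.numeric(mask)) {
    mask <- as.array(mask)
  } else {
    stop("`mask` must be a logical or 0/1 numeric array.", call. = FALSE)
  }
  d <- dim(mask)
  if (is.null(d)) d <- length(mask)
  if (length(d) > 3L) stop("`mask` must have at most 3 dimensions.", call. = FALSE)
  d <- c(d, rep(1L, 3L - length(d)))
  mask <- array(as.logical(mask), dim = d)
  if (anyNA(mask)) stop("`mask` must not contain NA.", call. = FALSE)
  p <- sum(mask)
  if (p == 0L) stop("`mask` selects no voxels.", call. = FALSE)

  vox_of <- array(0L, dim = d)
  vox_of[mask] <- seq_len(p)
  coords <- which(mask, arr.ind = TRUE)
  dimnames(coords) <- NULL
  storage.mode(coords) <- "integer"

  nbr_back <- matrix(0L, nrow = p, ncol = 3L)
  for (l in 1:3) {
    back <- coords
    back[, l] <- back[, l] - 1L
    ok <- back[, l] >= 1L
    if (any(ok)) {
      nbr_back[ok, l] <- vox_of[back[ok, , drop = FALSE]]
    }
  }

  structure(
    list(shape = as.integer(d), mask = mask, p = as.integer(p),
         coords = coords, vox_of = vox_of, nbr_back = nbr_back),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, p = %d in-mask voxels (%.1f%%)\n",
              x$shape[1], x$shape[2], x$shape[3], x$p,
              100 * x$p / prod(x$shape)))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

check_beta <- function(beta, grid, arg = "beta") {
  if (!is.numeric(beta) || length(beta) != grid$p) {
    stop(sprintf("`%s` must be a numeric vector of length grid$p = %d (got %d).",
                 arg, grid$p, length(beta)), call. = FALSE)
  }
  as.double(beta)
}

#' Embed an in-mask coefficient vector into the full 3D grid
#'
#' Off-mask voxels are exactly zero.
#'
#' @param beta numeric vector of length `grid$p`.
#' @param grid a [voxel_grid()].
#' @return A numeric 3D array of the grid's shape.
#' @export
unmask <- function(beta, grid) {
  beta <- check_beta(beta, grid)
  vol <- array(0, dim = grid$shape)
  vol[grid$mask] <- beta
  vol
}

#' Extract the in-mask voxels of a 3D volume
#'
#' @param vol numeric array of the grid's shape.
#' @param grid a [voxel_grid()].
#' @return Numeric vector of length `grid$p`, in linear in-mask order.
#' @export
mask_values <- function(vol, grid) {
  vol <- as.array(vol)
  d <- dim(vol)
  d <- c(d, rep(1L, 3L - length(d)))
  if (!all(d == grid$shape)) {
    stop("`vol` shape does not match the grid.", call. = FALSE)
  }
  as.double(array(vol, dim = grid$shape)[grid$mask])
}
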