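#' Discrete spatial gradient on a masked grid
#'
#' Backward first differences along the three grid axes,
#' `(grad beta)^l_v = beta_v - beta_b(v,l)` where `b(v, l)` is the backward
#' face neighbor along axis `l`. Components are zero wherever that neighbor
#' is outside the grid or off-mask, so the operator never differences across
#' the mask boundary.
#'
#' @param beta numeric vector of length `grid$p`.
#' @param grid a [voxel_grid()].
#' @return A `p x 3` numeric matrix of class `gradient_field`; column `l`
#'   holds the axis-`l` component at each in-mask voxel.
#' @seealso [gradient_adjoint()] for the exact adjoint (negative divergence).
#' @examples
#' g <- voxel_grid(array(TRUE, c(2, 1, 1)))
#' discrete_gradient(c(3, 5), g)
#' @export
discrete_gradient <- function(beta, grid) {
  beta <- check_beta(beta, grid)
  field <- matrix(0, nrow = grid$p, ncol = 3L)
  for (l in 1:3) {
    has <- grid$nbr_back[, l] > 0L
    field[has, l] <- beta[has] - beta[grid$nbr_back[has, l]]
  }
  class(field) <- c("gradient_field", class(field))
  field
}

#' Adjoint of the discrete gradient (masked negative divergence)
#'
#' Exact linear adjoint of [discrete_gradient()] under the Euclidean inner
#' product: `<grad beta, u> == <beta, gradient_adjoint(u)>` for every `beta`
#' and field `u`. Needed by the dual solvers of the total-variation proximal
#' map and to form the graph Laplacian as `t(G) %*% G`.
#'
#' @param field `p x 3` numeric matrix (a gradient field on `grid`).
#' @param grid a [voxel_grid()].
#' @return Numeric vector of length `grid$p`.
#' @export
gradient_adjoint <- function(field, grid) {
  if (!is.matrix(field) || nrow(field) != grid$p || ncol(field) != 3L) {
    stop(sprintf("`field` must be a %d x 3 matrix.", grid$p), call. = FALSE)
  }
  out <- numeric(grid$p)
  for (l in 1:3) {
    has <- which(grid$nbr_back[, l] > 0L)
    if (!length(has)) next
    u <- field[has, l]
    out[has] <- out[has] + u
    b <- grid$nbr_back[has, l]
    # backward neighbors can repeat across axes but not within one axis
    out[b] <- out[b] - u
  }
  out
}

#' Graph Laplacian of the in-mask 6-neighbor graph
#'
#' `L = D - A` over the face-adjacency graph of in-mask voxels (`D` degree,
#' `A` adjacency). `L` is symmetric positive semidefinite with zero row sums
#' and satisfies `t(beta) %*% L %*% beta = sum over unordered neighbor pairs
#' of (beta_i - beta_j)^2`, which is how the Laplacian penalty is evaluated.
#'
#' @param grid a [voxel_grid()].
#' @return A sparse symmetric `p x p` matrix (class `dgCMatrix`).
#' @export
graph_laplacian <- function(grid) {
  edges <- grid_edges(grid)
  p <- grid$p
  if (nrow(edges) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = double(),
                                dims = c(p, p)))
  }
  i <- c(edges[, 1], edges[, 2])
  j <- c(edges[, 2], edges[, 1])
  A <- Matrix::sparseMatrix(i = i, j = j, x = rep(-1, length(i)), dims = c(p, p))
  deg <- tabulate(i, nbins = p)
  A + Matrix::Diagonal(p, deg)
}

#' Unordered in-mask edges (face adjacency)
#'
#' @param grid a [voxel_grid()].
#' @return Two-column integer matrix; each row one unordered neighbor pair
#'   `(backward, forward)` of in-mask indices.
#' @keywords internal
grid_edges <- function(grid) {
  lst <- lapply(1:3, function(l) {
    has <- which(grid$nbr_back[, l] > 0L)
    cbind(grid$nbr_back[has, l], has)
  })
  out <- do.call(rbind, lst)
  storage.mode(out) <- "integer"
  out
}

#' Explicit sparse matrix of the discrete gradient
#'
#' Stacks the three axis blocks, giving a `3p x p` sparse matrix `G` with
#' `G %*% beta == as.vector(discrete_gradient(beta, grid))`. Intended for
#' testing and export; the solvers apply the operator matrix-free.
#'
#' @param grid a [voxel_grid()].
#' @return A `3p x p` sparse matrix.
#' @export
gradient_matrix <- function(grid) {
  p <- grid$p
  rows <- integer(0); cols <- integer(0); vals <- double(0)
  for (l in 1:3) {
    has <- which(grid$nbr_back[, l] > 0L)
    if (!length(has)) next
    off <- (l - 1L) * p
    rows <- c(rows, off + has, off + has)
    cols <- c(cols, has, grid$nbr_back[has, l])
    vals <- c(vals, rep(1, length(has)), rep(-1, length(has)))
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(3L * p, p))
}
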