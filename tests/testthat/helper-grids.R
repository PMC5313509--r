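# Random masked grid with at least `p_min` in-mask voxels.
random_masked_grid <- function(shape = c(4, 4, 3), fill = 0.7, p_min = 2L) {
  repeat {
    mask <- array(stats::runif(prod(shape)) < fill, dim = shape)
    if (sum(mask) >= p_min) return(voxel_grid(mask))
  }
}

# Dense 3p x p gradient matrix built directly from the mask geometry
# (independent of the package's nbr_back bookkeeping): row block l holds
# beta(i,j,k) - beta(i-1,j,k) etc., zero at boundaries and across the mask.
dense_gradient_oracle <- function(grid) {
  p <- grid$p
  G <- matrix(0, 3 * p, p)
  for (v in seq_len(p)) {
    co <- grid$coords[v, ]
    for (l in 1:3) {
      back <- co
      back[l] <- back[l] - 1L
      if (back[l] >= 1L && grid$mask[back[1], back[2], back[3]]) {
        b <- grid$vox_of[back[1], back[2], back[3]]
        G[(l - 1L) * p + v, v] <- 1
        G[(l - 1L) * p + v, b] <- -1
      }
    }
  }
  G
}

# Enumerate all unordered in-mask face-neighbor pairs straight from
# coordinates (edge-sum oracle for the Laplacian quadratic form).
edge_pairs_oracle <- function(grid) {
  out <- NULL
  for (v in seq_len(grid$p)) {
    co <- grid$coords[v, ]
    for (l in 1:3) {
      fwd <- co
      fwd[l] <- fwd[l] + 1L
      if (fwd[l] <= grid$shape[l] && grid$mask[fwd[1], fwd[2], fwd[3]]) {
        out <- rbind(out, c(v, grid$vox_of[fwd[1], fwd[2], fwd[3]]))
      }
    }
  }
  out
}

# A small multi-subject dataset with a planted separable direction.
tiny_dataset <- function(n_subjects = 3, n_per_class = 4, p_shape = c(3, 3, 1),
                         signal = 1, noise = 0.5, seed = 42) {
  set.seed(seed)
  grid <- voxel_grid(array(TRUE, p_shape))
  w <- numeric(grid$p)
  w[1:2] <- 1
  m <- n_subjects * 2 * n_per_class
  y <- rep(rep(c(1, -1), each = n_per_class), n_subjects)
  subject <- rep(sprintf("S%d", seq_len(n_subjects)), each = 2 * n_per_class)
  X <- outer(y, signal * w) + matrix(rnorm(m * grid$p, sd = noise), m, grid$p)
  decode_dataset(X, y, subject, grid)
}
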