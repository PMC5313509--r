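# Random small decoding problems on masked 1D/3D grids for solver
# validation sweeps.
random_problem <- function(p_max = 30, m_max = 40) {
  if (runif(1) < 0.4) {
    n <- sample(4:p_max, 1)
    grid <- voxel_grid(array(TRUE, c(n, 1, 1)))
  } else {
    grid <- random_masked_grid(shape = sample(2:4, 3, replace = TRUE),
                               fill = 0.85, p_min = 4)
    while (grid$p > p_max) {
      grid <- random_masked_grid(shape = sample(2:4, 3, replace = TRUE),
                                 fill = 0.85, p_min = 4)
    }
  }
  m <- sample(6:m_max, 1)
  m <- m + m %% 2
  X <- matrix(rnorm(m * grid$p), m, grid$p)
  y <- rep(c(1, -1), m / 2)
  list(data = decode_dataset(X, y, rep("a", m), grid), grid = grid)
}

random_spec <- function(family) {
  switch(family,
    lasso = penalty("lasso", lambda1 = runif(1, 0.05, 0.6)),
    enet = penalty("enet", lambda1 = runif(1, 0.05, 0.6),
                   lambda2 = runif(1, 0.01, 0.5)),
    tv = penalty("tv", lambda = runif(1, 0.05, 0.5)),
    stv = penalty("stv", lambda = runif(1, 0.05, 0.5)),
    lap = penalty("lap", lambda = runif(1, 0.05, 0.8)),
    slap = penalty("slap", lambda = runif(1, 0.05, 0.8),
                   alpha = runif(1, 0.1, 0.9)))
}
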