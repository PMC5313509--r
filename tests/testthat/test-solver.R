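test_that("data_fit is the (1/m)-scaled squared error", {
  g <- voxel_grid(array(TRUE, c(2, 1, 1)))
  d <- decode_dataset(diag(2), c(1, -1), c("a", "a"), g)
  expect_equal(data_fit(c(0, 0), d), 1) # (1/m) sum y_i^2
  expect_equal(data_fit(c(1, -1), d), 0)
  d2 <- decode_dataset(matrix(c(1, 0, 0, 2), 2, byrow = TRUE), c(1, -1),
                       c("a", "a"), g)
  expect_equal(data_fit(c(1, -1), d2), 0.5) # residuals (0, 1): (1/2)(0+1)

})

test_that("ridge fits match the normal equations", {
  set.seed(41)
  g <- voxel_grid(array(TRUE, c(6, 1, 1)))
  for (lam2 in c(0.1, 1, 5)) {
    X <- matrix(rnorm(60), 10, 6)
    y <- rep(c(1, -1), 5)
    d <- decode_dataset(X, y, rep("a", 10), g)
    fit <- fit_model(d, penalty("enet", lambda1 = 0, lambda2 = lam2),
                     solver_options(tol = 1e-11, max_iter = 50000))
    closed <- solve(crossprod(X) / 10 + lam2 * diag(6),
                    crossprod(X, y) / 10)
    expect_equal(fit$beta, drop(closed), tolerance = 1e-5)
  }
  # the 2x2 identity case
  d <- decode_dataset(diag(2), c(1, -1), c("a", "a"),
                      voxel_grid(array(TRUE, c(2, 1, 1))))
  f <- fit_model(d, penalty("enet", lambda1 = 0, lambda2 = 0.5))
  expect_equal(f$beta, c(0.5, -0.5), tolerance = 1e-6)
})

test_that("identity-design LASSO soft-thresholds the labels", {
  g <- voxel_grid(array(TRUE, c(2, 1, 1)))
  d <- decode_dataset(diag(2), c(1, -1), c("a", "a"), g)
  f <- fit_model(d, penalty("lasso", lambda1 = 0.5))
  expect_equal(f$beta, c(0.5, -0.5), tolerance = 1e-5)
  # above the critical regularization the solution is exactly zero
  f0 <- fit_model(d, penalty("lasso", lambda1 = lambda_max_l1(d)))
  expect_equal(f0$beta, c(0, 0))
})

test_that("lasso/enet fits agree with glmnet on random problems", {
  skip_if_not_installed("glmnet")
  set.seed(43)
  g <- voxel_grid(array(TRUE, c(8, 1, 1)))
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- rep(c(1, -1), 10)
    d <- decode_dataset(X, y, rep("a", 20), g)
    lam1 <- runif(1, 0.05, 0.5)
    lam2 <- if (rep %% 2 == 0) runif(1, 0.05, 0.5) else 0
    fit <- fit_model(d, penalty("enet", lambda1 = lam1, lambda2 = lam2),
                     solver_options(tol = 1e-11, max_iter = 50000))
    # our objective is 2x glmnet's gaussian objective, so
    # glmnet lambda*alpha = lam1/2, glmnet lambda*(1-alpha) = lam2
    a <- lam1 / 2; b <- lam2
    gl <- glmnet::glmnet(X, y, alpha = a / (a + b), lambda = a + b,
                         standardize = FALSE, intercept = FALSE,
                         thresh = 1e-12)
    expect_equal(fit$beta, as.vector(gl$beta), tolerance = 1e-4)
  }
})

test_that("fitting is deterministic with a monotone objective trace", {
  d <- tiny_dataset()
  sp <- penalty("stv", lambda = 0.2)
  f1 <- fit_model(d, sp)
  f2 <- fit_model(d, sp)
  expect_identical(f1$beta, f2$beta)
  expect_true(all(diff(f1$trace) <= 0))
  f3 <- fit_model(d, penalty("lasso", lambda1 = 0.1))
  expect_true(all(diff(f3$trace) <= 0))
})

test_that("degenerate-family identities hold at the solver level", {
  d <- tiny_dataset(seed = 77)
  f_lap <- fit_model(d, penalty("lap", lambda = 0.3))
  f_slap0 <- fit_model(d, penalty("slap", lambda = 0.3, alpha = 0))
  expect_equal(f_slap0$beta, f_lap$beta, tolerance = 1e-5)
  f_lasso <- fit_model(d, penalty("lasso", lambda1 = 0.2))
  f_enet0 <- fit_model(d, penalty("enet", lambda1 = 0.2, lambda2 = 0))
  expect_equal(f_enet0$beta, f_lasso$beta, tolerance = 1e-5)
})

test_that("the lasso l1 norm shrinks as regularization grows", {
  set.seed(47)
  d <- tiny_dataset(n_per_class = 6, seed = 47)
  lams <- lambda_max_l1(d) * c(0.9, 0.5, 0.2, 0.1, 0.02)
  norms <- vapply(lams, function(l) {
    sum(abs(fit_model(d, penalty("lasso", lambda1 = l))$beta))
  }, 1.0)
  expect_true(all(diff(norms) >= -1e-8)) # increasing as lambda decreases
})

test_that("prediction uses sign(x' beta) with sign(0) -> +1", {
  expect_equal(predict_labels(c(1, 0), matrix(c(3, 7), 1)), 1)
  expect_equal(predict_labels(c(0, 0), matrix(c(3, 7), 1)), 1)
  expect_equal(predict_labels(c(1, -1), rbind(c(2, 1), c(1, 2))), c(1, -1))
  d <- tiny_dataset()
  f <- fit_model(d, penalty("lasso", lambda1 = 0.05))
  expect_setequal(unique(predict(f, d)), c(-1, 1))
  expect_error(predict(f, matrix(0, 2, 3)), "column")
})

test_that("invalid data are rejected before fitting", {
  g <- voxel_grid(array(TRUE, c(2, 1, 1)))
  expect_error(decode_dataset(matrix(c(1, NA, 0, 1), 2), c(1, -1),
                              c("a", "a"), g), "NA")
  expect_error(decode_dataset(diag(2), c(1, 2), c("a", "a"), g), "binary")
  expect_error(decode_dataset(diag(2), c(1, -1), c("a", "b"), g),
               "each class")
  expect_error(decode_dataset(matrix(0, 2, 3), c(1, -1), c("a", "a"), g),
               "columns")
})

test_that("FISTA objective is near the independent oracle on random small problems", {
  # one quick spot check per family here; the full sweep lives with the
  # acceptance tests
  set.seed(53)
  specs <- list(penalty("lasso", lambda1 = 0.2),
                penalty("enet", lambda1 = 0.15, lambda2 = 0.1),
                penalty("tv", lambda = 0.2),
                penalty("stv", lambda = 0.15),
                penalty("lap", lambda = 0.3),
                penalty("slap", lambda = 0.3, alpha = 0.5))
  g <- random_masked_grid(c(3, 3, 2), fill = 0.85, p_min = 10)
  X <- matrix(rnorm(20 * g$p), 20, g$p)
  y <- rep(c(1, -1), 10)
  d <- decode_dataset(X, y, rep("a", 20), g)
  for (sp in specs) {
    fit <- fit_model(d, sp, solver_options(tol = 1e-9, max_iter = 20000,
                                           tv_tol = 1e-10,
                                           tv_max_iter = 2000))
    w <- stabdecode:::penalty_weights(sp)
    orc <- stabdecode:::prox_subgrad_oracle_cpp(
      X, y, w[["w1"]], w[["w2"]], w[["wtv"]], w[["wlap"]],
      g$nbr_back, 20000L)
    expect_lte(fit$objective,
               orc$objective + 1e-6 * max(1, abs(orc$objective)))
  }
})
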