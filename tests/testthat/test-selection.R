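test_that("loso_folds holds out whole subjects, one fold each", {
  subject <- c("A", "A", "B", "B", "C", "C")
  folds <- loso_folds(subject)
  expect_equal(nrow(folds), 3)
  fa <- folds[folds$test_subject == "A", ]
  expect_setequal(fa$train[[1]], 3:6)
  expect_setequal(fa$test[[1]], 1:2)
  # test sets partition the rows
  expect_setequal(unlist(folds$test), seq_along(subject))
  # nesting: the internal loop of fold A runs over B and C only
  inner <- loso_folds(subject[folds$train[[1]]])
  expect_setequal(inner$test_subject, c("B", "C"))
  # 16 subjects: 16 external folds with 15 internal folds each
  subs16 <- rep(sprintf("S%02d", 1:16), each = 2)
  f16 <- loso_folds(subs16)
  expect_equal(nrow(f16), 16)
  expect_equal(nrow(loso_folds(subs16[f16$train[[1]]])), 15)
  expect_error(loso_folds(rep("A", 3)), "2 distinct")
})

test_that("default grids span lambda_max downwards, strongest first", {
  d <- tiny_dataset()
  g <- default_hyper_grid(d, "lasso", n_lambda = 7)
  expect_equal(nrow(g), 7)
  expect_equal(g$lambda1[1], lambda_max_l1(d))
  expect_equal(g$lambda1[7], lambda_max_l1(d) * 1e-4, tolerance = 1e-10)
  expect_true(all(diff(g$lambda1) < 0))
  # the top grid point zeroes the lasso
  f <- fit_model(d, penalty("lasso", lambda1 = g$lambda1[1]))
  expect_equal(f$beta, numeric(d$p))
  ge <- default_hyper_grid(d, "enet", n_lambda = 3)
  expect_equal(nrow(ge), 15) # 3 lambda1 x 5 lambda2
  gs <- default_hyper_grid(d, "slap", n_lambda = 3)
  expect_equal(nrow(gs), 15) # 3 lambda x 5 alpha
  expect_error(default_hyper_grid(d, "nope"), "unknown")
})

test_that("hyper_grid validates and orders combinations", {
  g <- hyper_grid("slap", lambda = c(0.1, 1), alpha = c(0.2, 0.8))
  expect_equal(nrow(g), 4)
  expect_equal(g$lambda[1], 1)
  expect_equal(g$alpha[1], 0.8)
  expect_error(hyper_grid("slap", lambda = 0.1, alpha = 2), "0, 1")
  expect_error(hyper_grid("lasso", lambda1 = numeric(0)), "empty")
})

test_that("select_hyperparameters implements the three criteria", {
  pts <- tibble::tibble(lambda1 = c(0.2, 0.1),
                        accuracy = c(0.9, 0.8), oc = c(0.5, 0.9),
                        corr = c(0.5, 0.9), ok = TRUE)
  # distances: sqrt(.01+.25) = .5099 vs sqrt(.04+.01) = .2236
  ch <- select_hyperparameters(pts, "acc_oc", family = "lasso")
  expect_equal(ch$lambda1, 0.1)
  expect_equal(ch$distance, sqrt(0.04 + 0.01))
  expect_equal(select_hyperparameters(pts, "acc", family = "lasso")$lambda1,
               0.2)
  # a point at (1, 1) always wins the distance criteria
  pts2 <- dplyr::bind_rows(pts, tibble::tibble(lambda1 = 0.05, accuracy = 1,
                                               oc = 1, corr = 1, ok = TRUE))
  expect_equal(select_hyperparameters(pts2, "acc_oc",
                                      family = "lasso")$lambda1, 0.05)
  # corrected-overlap criterion is refused for dense families
  expect_error(select_hyperparameters(pts, "acc_oc", family = "tv"), "sparse")
  expect_error(select_hyperparameters(pts, "acc_oc", family = "lap"),
               "sparse")
  # ties break toward stronger regularization
  tie <- tibble::tibble(lambda1 = c(0.1, 0.3), accuracy = 0.8, oc = 0.8,
                        corr = 0.8, ok = TRUE)
  expect_equal(select_hyperparameters(tie, "acc", family = "lasso")$lambda1,
               0.3)
  # flagged points are excluded
  pts$ok[1] <- FALSE
  expect_equal(select_hyperparameters(pts, "acc", family = "lasso")$lambda1,
               0.1)
})

test_that("internal_evaluate reproduces a manual internal LOSO assessment", {
  d <- tiny_dataset(n_subjects = 3, n_per_class = 5, seed = 91)
  lam <- 0.3 * lambda_max_l1(d)
  grid <- hyper_grid("lasso", lambda1 = lam)
  pts <- internal_evaluate(d, grid)
  expect_equal(nrow(pts), 1)

  folds <- loso_folds(d$subject)
  accs <- vapply(seq_len(nrow(folds)), function(fi) {
    tr <- dataset_rows(d, folds$train[[fi]])
    f <- fit_model(tr, penalty("lasso", lambda1 = lam))
    mean(predict_labels(f$beta, d$X[folds$test[[fi]], , drop = FALSE]) ==
           d$y[folds$test[[fi]]])
  }, 1.0)
  expect_equal(pts$accuracy, mean(accs))

  # over-regularized: empty signatures, chance accuracy, zero overlap
  grid0 <- hyper_grid("lasso", lambda1 = 2 * lambda_max_l1(d))
  pts0 <- internal_evaluate(d, grid0)
  expect_equal(pts0$oc, 0)
  expect_equal(pts0$accuracy, 0.5, tolerance = 0.2)
})

test_that("nested_loso_run is deterministic and reduces to plain LOSO for one grid point", {
  d <- tiny_dataset(n_subjects = 4, n_per_class = 4, seed = 97)
  lam <- 0.2 * lambda_max_l1(d)
  grid <- hyper_grid("lasso", lambda1 = lam)
  r1 <- nested_loso_run(d, grid, criteria = c("acc", "acc_oc"))
  r2 <- nested_loso_run(d, grid, criteria = c("acc", "acc_oc"))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$signatures, r2$signatures)

  # selection is vacuous: external metrics equal a hand-rolled LOSO run
  folds <- loso_folds(d$subject)
  accs <- vapply(seq_len(nrow(folds)), function(fi) {
    tr <- dataset_rows(d, folds$train[[fi]])
    f <- fit_model(tr, penalty("lasso", lambda1 = lam))
    bt <- threshold_coefficients(f$beta)
    mean(predict_labels(bt, d$X[folds$test[[fi]], , drop = FALSE]) ==
           d$y[folds$test[[fi]]])
  }, 1.0)
  acc_row <- r1$summary[r1$summary$criterion == "acc", ]
  expect_equal(acc_row$accuracy, mean(accs))
  # both criteria choose the only combination, so externals coincide
  expect_equal(acc_row$accuracy,
               r1$summary$accuracy[r1$summary$criterion == "acc_oc"])
  expect_equal(nrow(r1$folds), 2 * nrow(folds))
})

test_that("aggregated stability equals a recomputation from the stored signatures", {
  d <- tiny_dataset(n_subjects = 4, n_per_class = 4, seed = 101)
  grid <- default_hyper_grid(d, "lasso", n_lambda = 4)
  res <- nested_loso_run(d, grid, criteria = "acc")
  st <- suppressWarnings(
    stability_summary(res$raw_signatures[["acc"]], p = d$p))
  expect_equal(res$summary$oc, st$oc_bar)
  expect_equal(res$summary$overlap, st$o_bar)
  expect_equal(res$summary$correlation, st$c_bar)
  sp <- vapply(res$signatures[["acc"]], function(b) mean(b != 0), 1.0)
  expect_equal(res$summary$sparsity, mean(sp))
  expect_equal(res$summary$sparsity_sd, sd(sp))
})

test_that("the acc_oc choice is at least as internally stable as the acc choice", {
  d <- tiny_dataset(n_subjects = 4, n_per_class = 6, noise = 1.2, seed = 103)
  grid <- default_hyper_grid(d, "lasso", n_lambda = 6)
  pts <- internal_evaluate(d, grid)
  attr(pts, "family") <- "lasso"
  ch_acc <- select_hyperparameters(pts, "acc")
  ch_oc <- select_hyperparameters(pts, "acc_oc")
  expect_gte(ch_oc$oc, ch_acc$oc - 1e-12)
})

test_that("pair-cached internal evaluation matches the direct computation", {
  d <- tiny_dataset(n_subjects = 4, n_per_class = 4, seed = 107)
  grid <- default_hyper_grid(d, "lasso", n_lambda = 3)
  res <- nested_loso_run(d, grid, criteria = "acc")
  # recompute one external fold's points directly
  folds <- loso_folds(d$subject)
  tr <- dataset_rows(d, folds$train[[2]])
  pts <- internal_evaluate(tr, grid)
  got <- res$diagrams[res$diagrams$test_subject == folds$test_subject[2],
                      names(pts)]
  expect_equal(as.data.frame(got), as.data.frame(pts), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("held-out data cannot leak into an external fold's fit", {
  d <- tiny_dataset(n_subjects = 3, n_per_class = 4, seed = 109)
  grid <- default_hyper_grid(d, "lasso", n_lambda = 3)
  res <- nested_loso_run(d, grid, criteria = "acc")
  # corrupt every label and scan of subject S1, leaving the rest untouched
  idx <- which(d$subject == "S1")
  X2 <- d$X
  X2[idx, ] <- -5 * X2[idx, ] + 3
  y2 <- d$y
  y2[idx] <- -y2[idx]
  d2 <- decode_dataset(X2, y2, d$subject, d$grid)
  res2 <- nested_loso_run(d2, grid, criteria = "acc")
  i1 <- which(res$folds$test_subject == "S1")
  expect_identical(res$signatures[["acc"]][[i1]],
                   res2$signatures[["acc"]][[i1]])
  expect_identical(res$folds$lambda1[i1], res2$folds$lambda1[i1])
})
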