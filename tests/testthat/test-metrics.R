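test_that("thresholding keeps the minimal prefix holding 1 - fraction of the l1 mass", {
  expect_equal(threshold_coefficients(c(5, 4, 1e-5)), c(5, 4, 0))
  expect_equal(threshold_coefficients(c(1, 1, 1, 1)), c(1, 1, 1, 1))
  expect_equal(threshold_coefficients(numeric(3)), numeric(3))
  expect_error(threshold_coefficients(c(1, 2), fraction = 1), "0, 1")
  expect_error(threshold_coefficients(c(1, Inf)), "finite")

  set.seed(61)
  for (rep in 1:50) {
    beta <- rnorm(sample(5:80, 1)) * 10^(rnorm(1))
    beta[sample(length(beta), length(beta) %/% 3)] <- 0
    thr <- threshold_coefficients(beta, 1e-4)
    kept <- which(thr != 0)
    expect_gte(sum(abs(thr)), (1 - 1e-4) * sum(abs(beta)))
    # minimality: dropping the smallest retained coefficient breaks the bound
    if (length(kept)) {
      smallest <- kept[which.min(abs(beta[kept]))]
      expect_lt(sum(abs(beta[setdiff(kept, smallest)])),
                (1 - 1e-4) * sum(abs(beta)))
    }
    # zeroed entries are a subset of the original plus discarded ones
    expect_true(all(thr[thr != 0] == beta[thr != 0]))
  }
})

test_that("ties at the threshold cut are broken deterministically by index", {
  beta <- c(1e-6, 2, 2, 1e-6)
  t1 <- threshold_coefficients(beta, 1e-4)
  t2 <- threshold_coefficients(beta, 1e-4)
  expect_identical(t1, t2)
  expect_equal(which(t1 != 0), c(2, 3))
})

test_that("support and sparsity count nonzero coefficients", {
  s <- support_and_sparsity(c(0, 2, 0, -1), 4)
  expect_equal(s$support, c(2, 4))
  expect_equal(s$sparsity, 0.5)
  s0 <- support_and_sparsity(numeric(4))
  expect_equal(s0$support, integer(0))
  expect_equal(s0$sparsity, 0)
  # thresholding then supporting equals supporting then keeping retained set
  set.seed(67)
  beta <- rnorm(50)
  thr <- threshold_coefficients(beta, 1e-2)
  expect_setequal(support_and_sparsity(thr)$support,
                  intersect(which(beta != 0), which(thr != 0)))
})

test_that("pairwise overlap is the intersection over the larger support", {
  expect_equal(pairwise_overlap(1:3, 1:3), 1)
  expect_equal(pairwise_overlap(1:3, 4:6), 0)
  expect_equal(pairwise_overlap(1:3, 2:5), 0.5)
  expect_warning(o <- pairwise_overlap(integer(0), integer(0)), "empty")
  expect_equal(o, 0)
  # symmetry
  expect_equal(pairwise_overlap(1:4, 3:10), pairwise_overlap(3:10, 1:4))
})

test_that("corrected overlap subtracts the chance-level intersection", {
  expect_equal(corrected_overlap(1:3, 2:5, 10), (2 - 1.2) / 4)
  # dense models are pulled to zero, the correction's purpose
  expect_equal(corrected_overlap(1:10, 1:10, 10), 0)
  expect_warning(oc <- corrected_overlap(integer(0), integer(0), 5), "empty")
  expect_equal(oc, 0)
  expect_error(corrected_overlap(1:2, 1:2, 0), "positive")
  expect_error(corrected_overlap(1:5, 1:2, 4), "larger")
  # Oc <= O always, equality when E = 0
  set.seed(71)
  for (rep in 1:50) {
    p <- sample(10:60, 1)
    I <- sample(p, sample(p, 1))
    J <- sample(p, sample(p, 1))
    expect_lte(corrected_overlap(I, J, p), pairwise_overlap(I, J))
    expect_equal(corrected_overlap(I, J, p),
                 pairwise_overlap(I, J) - length(I) * length(J) / p /
                   max(length(I), length(J)))
  }
})

test_that("chance overlap of random supports matches E = p S S'", {
  set.seed(73)
  p <- 200
  nI <- 30
  nJ <- 50
  E <- nI * nJ / p
  inters <- replicate(10000, length(intersect(sample(p, nI), sample(p, nJ))))
  # Monte-Carlo check of the expectation formula
  expect_lt(abs(mean(inters) - E), 4 * sd(inters) / sqrt(10000))
  # and the mean corrected overlap of random supports is near zero
  oc <- (inters - E) / max(nI, nJ)
  expect_lt(abs(mean(oc)), 4 * sd(oc) / sqrt(10000))
})

test_that("pairwise correlation uses all coefficients, zeros included", {
  beta <- c(1, 0, 3, 0)
  expect_equal(pairwise_correlation(beta, 2 * beta), 1)
  expect_equal(pairwise_correlation(beta, -beta), -1)
  expect_equal(pairwise_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_warning(r <- pairwise_correlation(c(1, 1), c(1, 2)), "constant")
  expect_equal(r, 0)
  expect_error(pairwise_correlation(1, 1), "length")
})

test_that("stability_summary averages pairwise measures over ordered pairs", {
  # all identical signatures
  sig <- c(1, 0, 2, 0, 0)
  s <- stability_summary(list(sig, sig, sig))
  expect_equal(s$o_bar, 1)
  expect_equal(s$c_bar, 1)
  # N = 2: means equal the single pairwise value
  b1 <- c(1, 2, 0, 0)
  b2 <- c(0, 1, 2, 0)
  s2 <- stability_summary(list(b1, b2))
  expect_equal(s2$o_bar, pairwise_overlap(c(1, 2), c(2, 3)))
  expect_equal(s2$c_bar, cor(b1, b2))
  expect_equal(s2$oc_bar, corrected_overlap(c(1, 2), c(2, 3), 4))
  expect_error(stability_summary(list(b1)), "at least 2")

  # three hand-built supports on p = 10: means match hand-averaged values
  v1 <- v2 <- v3 <- numeric(10)
  v1[c(1, 2, 3)] <- 1
  v2[c(2, 3, 4, 5)] <- c(1, -1, 2, 1)
  v3[c(3, 9)] <- 1
  s3 <- stability_summary(list(v1, v2, v3), p = 10)
  hand_o <- mean(c(pairwise_overlap(1:3, 2:5), pairwise_overlap(1:3, c(3, 9)),
                   pairwise_overlap(2:5, c(3, 9))))
  hand_oc <- mean(c(corrected_overlap(1:3, 2:5, 10),
                    corrected_overlap(1:3, c(3, 9), 10),
                    corrected_overlap(2:5, c(3, 9), 10)))
  expect_equal(s3$o_bar, hand_o)
  expect_equal(s3$oc_bar, hand_oc)
  expect_equal(s3$c_bar, mean(c(cor(v1, v2), cor(v1, v3), cor(v2, v3))))

  # permutation invariance of the means
  s3p <- stability_summary(list(v3, v1, v2), p = 10)
  expect_equal(s3p$o_bar, s3$o_bar)
  expect_equal(s3p$oc_bar, s3$oc_bar)
  expect_equal(s3p$c_bar, s3$c_bar)

  # matrices symmetric with unit diagonal for overlap/correlation
  expect_equal(s3$overlap, t(s3$overlap))
  expect_equal(diag(s3$overlap), rep(1, 3))
  expect_equal(diag(s3$correlation), rep(1, 3))
})

test_that("accuracy is macro-averaged over subjects, not pooled", {
  res <- macro_accuracy(c(1, 1, 1, -1, 1, -1), c(1, 1, 1, 1, -1, -1),
                        c("A", "A", "A", "A", "B", "B"))
  expect_equal(res$accuracy, 0.625) # pooled would be 4/6
  expect_equal(res$per_subject$accuracy, c(0.75, 0.5))
  expect_equal(macro_accuracy(c(1, -1), c(1, -1), c("A", "B"))$accuracy, 1)
  # random predictions on balanced labels sit near chance
  set.seed(79)
  n <- 4000
  truth <- rep(c(1, -1), n / 2)
  preds <- sample(c(1, -1), n, replace = TRUE)
  acc <- macro_accuracy(preds, truth, rep(c("A", "B"), each = n / 2))$accuracy
  expect_lt(abs(acc - 0.5), 0.05)
  expect_error(macro_accuracy(1, c(1, -1), c("A", "B")), "aligned")
})
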