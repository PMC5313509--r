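#' Threshold near-zero coefficients by l1-mass
#'
#' Numerical optimization leaves coefficients that should be zero at tiny
#' nonzero values. This heuristic zeroes the smallest components that
#' together contribute at most `fraction` of `||beta||_1`: order the
#' magnitudes decreasingly, keep the smallest prefix `r` whose cumulative l1
#' mass reaches `(1 - fraction) * ||beta||_1`, zero the rest. Ties in
#' magnitude are broken by original index (stable sort), and `r` is minimal,
#' so the output is deterministic.
#'
#' @param beta numeric vector (finite).
#' @param fraction tolerated l1-mass loss, in `[0, 1)`; default `1e-4`,
#'   i.e. the retained coefficients carry at least 99.99% of the mass.
#' @return `beta` with the discarded components set to exactly zero.
#' @examples
#' threshold_coefficients(c(5, 4, 1e-5))
#' @export
threshold_coefficients <- function(beta, fraction = 1e-4) {
  if (!is.numeric(beta) || anyNA(beta) || any(!is.finite(beta))) {
    stop("`beta` must be finite numeric.", call. = FALSE)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1) {
    stop("`fraction` must lie in [0, 1).", call. = FALSE)
  }
  total <- sum(abs(beta))
  if (total == 0) return(beta)
  ord <- order(abs(beta), decreasing = TRUE) # stable: ties keep index order
  cum <- cumsum(abs(beta)[ord])
  r <- which(cum >= (1 - fraction) * total)[1]
  out <- numeric(length(beta))
  keep <- ord[seq_len(r)]
  out[keep] <- beta[keep]
  out
}

#' Support and sparsity of a coefficient vector
#'
#' @param beta numeric vector of length `p` (usually thresholded first).
#' @param p number of voxels; defaults to `length(beta)`.
#' @return List with `support` (integer indices of nonzeros) and `sparsity`
#'   (`|support| / p`).
#' @export
support_and_sparsity <- function(beta, p = length(beta)) {
  if (length(beta) != p) stop("`beta` length must equal `p`.", call. = FALSE)
  support <- which(beta != 0)
  list(support = support, sparsity = length(support) / p)
}

#' Pairwise relative overlap of two supports
#'
#' `|I intersect I'| / max(|I|, |I'|)`. When both supports are empty the
#' overlap is defined as 0 with a warning: an empty model carries no
#' reproducible pattern.
#'
#' @param I,I_prime integer index vectors over a common voxel space.
#' @return Scalar in `[0, 1]`.
#' @export
pairwise_overlap <- function(I, I_prime) {
  nI <- length(I); nJ <- length(I_prime)
  if (nI == 0L && nJ == 0L) {
    warning("both supports are empty; overlap defined as 0.")
    return(0)
  }
  length(intersect(I, I_prime)) / max(nI, nJ)
}

#' Chance-corrected pairwise overlap
#'
#' Subtracts the expected intersection of two random supports of the same
#' sizes, `E = p * S * S' = |I| * |I'| / p`, before normalizing:
#' `(|I intersect I'| - E) / max(|I|, |I'|)`. Dense models overlapping by
#' construction are thereby pulled to zero; the value can be slightly
#' negative for below-chance overlap.
#'
#' @param I,I_prime integer index vectors.
#' @param p total number of voxels.
#' @return Scalar `<= 1`; 0 (with a warning) when both supports are empty.
#' @export
corrected_overlap <- function(I, I_prime, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0) {
    stop("`p` must be a positive count.", call. = FALSE)
  }
  nI <- length(I); nJ <- length(I_prime)
  if (nI > p || nJ > p) stop("support larger than `p`.", call. = FALSE)
  if (nI == 0L && nJ == 0L) {
    warning("both supports are empty; corrected overlap defined as 0.")
    return(0)
  }
  E <- nI * nJ / p
  (length(intersect(I, I_prime)) - E) / max(nI, nJ)
}

#' Pearson correlation between two coefficient vectors
#'
#' Sample correlation over all `p` coefficients, zeros included (supports
#' are not intersected). A constant vector has undefined correlation; 0 is
#' returned with a warning.
#'
#' @param beta,beta_prime numeric vectors of equal length `>= 2`.
#' @return Scalar in `[-1, 1]`.
#' @export
pairwise_correlation <- function(beta, beta_prime) {
  if (length(beta) != length(beta_prime) || length(beta) < 2L) {
    stop("vectors must have equal length >= 2.", call. = FALSE)
  }
  if (stats::sd(beta) == 0 || stats::sd(beta_prime) == 0) {
    warning("constant coefficient vector; correlation undefined, returning 0.")
    return(0)
  }
  stats::cor(beta, beta_prime)
}

#' Stability summary across cross-validation signatures
#'
#' For `N >= 2` signatures (the coefficient vectors fitted with one subject
#' held out each), computes all pairwise overlaps, chance-corrected
#' overlaps and Pearson correlations, and their means over the `N(N-1)`
#' ordered off-diagonal pairs (each unordered pair counted twice, which
#' equals the unordered mean). Supports are taken from the thresholded
#' coefficients; correlations use the raw coefficients.
#'
#' @param signatures list of numeric coefficient vectors of a common length
#'   `p`, or a list of `decoder_fit` objects.
#' @param p voxel count; inferred from the signatures when missing.
#' @param fraction l1-mass fraction for [threshold_coefficients()].
#' @return Object of class `stability_summary`: pairwise matrices
#'   `overlap`, `corrected`, `correlation`, `expected` (the chance term per
#'   pair), off-diagonal means `o_bar`, `oc_bar`, `c_bar`, and `n`.
#' @export
stability_summary <- function(signatures, p = NULL, fraction = 1e-4) {
  betas <- lapply(signatures, function(s) {
    if (inherits(s, "decoder_fit")) s$beta else as.numeric(s)
  })
  n <- length(betas)
  if (n < 2L) stop("need at least 2 signatures.", call. = FALSE)
  lens <- lengths(betas)
  if (length(unique(lens)) != 1L) {
    stop("signatures must share a common length.", call. = FALSE)
  }
  if (is.null(p)) p <- lens[1]
  supports <- lapply(betas, function(b) {
    support_and_sparsity(threshold_coefficients(b, fraction), p)$support
  })
  O <- Oc <- E <- Cm <- matrix(NA_real_, n, n)
  diag(O) <- 1; diag(Cm) <- 1
  for (s in seq_len(n)) {
    diag(E)[s] <- length(supports[[s]])^2 / p
    diag(Oc)[s] <- if (length(supports[[s]])) {
      (length(supports[[s]]) - diag(E)[s]) / length(supports[[s]])
    } else 0
  }
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      O[s, t] <- O[t, s] <- pairwise_overlap(supports[[s]], supports[[t]])
      Oc[s, t] <- Oc[t, s] <- corrected_overlap(supports[[s]], supports[[t]], p)
      E[s, t] <- E[t, s] <- length(supports[[s]]) * length(supports[[t]]) / p
      Cm[s, t] <- Cm[t, s] <- pairwise_correlation(betas[[s]], betas[[t]])
    }
  }
  off <- upper.tri(O) | lower.tri(O)
  structure(
    list(overlap = O, corrected = Oc, correlation = Cm, expected = E,
         o_bar = mean(O[off]), oc_bar = mean(Oc[off]), c_bar = mean(Cm[off]),
         n = n, p = p,
         sparsity = vapply(supports, length, 1L) / p),
    class = "stability_summary"
  )
}

#' @export
print.stability_summary <- function(x, ...) {
  cat(sprintf(
    "<stability_summary> N = %d signatures: O = %.3f, Oc = %.3f, C = %.3f\n",
    x$n, x$o_bar, x$oc_bar, x$c_bar))
  invisible(x)
}

#' Per-subject (macro) classification accuracy
#'
#' Fraction correct per subject, then the unweighted mean over subjects —
#' not the pooled fraction over examples, so every subject carries the same
#' weight regardless of scan count.
#'
#' @param predictions,truth label vectors in `{-1, +1}` (aligned).
#' @param subject subject identifier per example.
#' @return List with `accuracy` (macro mean) and `per_subject` (tibble with
#'   columns `subject`, `n`, `accuracy`).
#' @examples
#' macro_accuracy(c(1, 1, 1, -1, 1, -1), c(1, 1, 1, 1, -1, -1),
#'                c("A", "A", "A", "A", "B", "B"))$accuracy  # 0.625
#' @export
macro_accuracy <- function(predictions, truth, subject) {
  if (length(predictions) != length(truth) ||
      length(truth) != length(subject)) {
    stop("`predictions`, `truth` and `subject` must be aligned.", call. = FALSE)
  }
  if (length(truth) == 0L) stop("no examples.", call. = FALSE)
  tb <- tibble::tibble(subject = as.character(subject),
                       correct = as.numeric(predictions == truth))
  per <- dplyr::summarise(dplyr::group_by(tb, .data$subject),
                          n = dplyr::n(), accuracy = mean(.data$correct),
                          .groups = "drop")
  list(accuracy = mean(per$accuracy), per_subject = per)
}
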