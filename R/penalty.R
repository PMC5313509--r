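#' Penalty specification for the six decoder families
#'
#' Constructs the penalty `Omega(beta)` of one of the six regularized
#' least-squares decoders:
#' \describe{
#'   \item{`"lasso"`}{`lambda1 * ||beta||_1` (set via `lambda1`).}
#'   \item{`"enet"`}{`lambda1 * ||beta||_1 + lambda2 * ||beta||_2^2`.}
#'   \item{`"tv"`}{`lambda * ||grad beta||_1`, the anisotropic total
#'     variation: the l1 norm over all `3p` backward-difference components.}
#'   \item{`"stv"`}{`lambda * (||grad beta||_1 + ||beta||_1)`, sparse total
#'     variation (a 3D fused lasso).}
#'   \item{`"lap"`}{`(lambda / 2) * sum over ordered neighbor pairs of
#'     (beta_i - beta_j)^2 = lambda * t(beta) L beta` with `L` the grid-graph
#'     Laplacian.}
#'   \item{`"slap"`}{`lambda * (1 - alpha) * t(beta) L beta +
#'     lambda * alpha * ||beta||_1`, the sparse Laplacian (GraphNET with
#'     `lambda1 = lambda * alpha`, `lambda_G = lambda * (1 - alpha)`).}
#' }
#' The neighbor sum is taken over ordered pairs, so that its half equals the
#' Laplacian quadratic form exactly.
#'
#' @param family one of `"lasso"`, `"enet"`, `"tv"`, `"stv"`, `"lap"`,
#'   `"slap"` (case-insensitive).
#' @param lambda nonnegative scalar; the single regularization parameter of
#'   the TV, STV, LAP and SLAP families.
#' @param lambda1,lambda2 nonnegative scalars; l1 and squared-l2 weights of
#'   LASSO (`lambda1`) and Elastic Net.
#' @param alpha mixing weight in `[0, 1]` for SLAP; `alpha = 0` reduces to
#'   LAP, `alpha = 1` to LASSO.
#' @return An object of class `penalty_spec`.
#' @examples
#' penalty("enet", lambda1 = 0.1, lambda2 = 0.05)
#' penalty("stv", lambda = 0.2)
#' @export
penalty <- function(family, lambda = NULL, lambda1 = NULL, lambda2 = NULL,
                    alpha = NULL) {
  family <- tolower(family)
  families <- c("lasso", "enet", "tv", "stv", "lap", "slap")
  if (length(family) != 1L || !family %in% families) {
    stop("`family` must be one of: ", paste(families, collapse = ", "),
         call. = FALSE)
  }
  num1 <- function(x, name, default = NULL) {
    if (is.null(x)) {
      if (is.null(default)) {
        stop(sprintf("family '%s' requires `%s`.", family, name), call. = FALSE)
      }
      return(default)
    }
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
      stop(sprintf("`%s` must be a single nonnegative number.", name),
           call. = FALSE)
    }
    as.double(x)
  }
  spec <- switch(family,
    lasso = list(lambda1 = num1(lambda1, "lambda1")),
    enet  = list(lambda1 = num1(lambda1, "lambda1"),
                 lambda2 = num1(lambda2, "lambda2")),
    tv    = list(lambda = num1(lambda, "lambda")),
    stv   = list(lambda = num1(lambda, "lambda")),
    lap   = list(lambda = num1(lambda, "lambda")),
    slap  = {
      a <- num1(alpha, "alpha")
      if (a > 1) stop("`alpha` must lie in [0, 1].", call. = FALSE)
      list(lambda = num1(lambda, "lambda"), alpha = a)
    })
  structure(c(list(family = family), spec), class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  hp <- x[setdiff(names(x), "family")]
  cat(sprintf("<penalty_spec> %s (%s)\n", toupper(x$family),
              paste(sprintf("%s = %g", names(hp), unlist(hp)), collapse = ", ")))
  invisible(x)
}

# Map a penalty_spec to the four elementary weights the solver understands:
#   Omega(beta) = w1*||beta||_1 + w2*||beta||_2^2
#               + wtv*||grad beta||_1 + wlap*t(beta) L beta
penalty_weights <- function(spec) {
  stopifnot(inherits(spec, "penalty_spec"))
  w <- c(w1 = 0, w2 = 0, wtv = 0, wlap = 0)
  switch(spec$family,
    lasso = { w["w1"] <- spec$lambda1 },
    enet  = { w["w1"] <- spec$lambda1; w["w2"] <- spec$lambda2 },
    tv    = { w["wtv"] <- spec$lambda },
    stv   = { w["wtv"] <- spec$lambda; w["w1"] <- spec$lambda },
    lap   = { w["wlap"] <- spec$lambda },
    slap  = { w["wlap"] <- spec$lambda * (1 - spec$alpha)
              w["w1"]   <- spec$lambda * spec$alpha })
  w
}

#' Penalty value Omega(beta)
#'
#' @param beta numeric vector of length `grid$p`.
#' @param spec a [penalty()] specification.
#' @param grid a [voxel_grid()].
#' @return Nonnegative scalar.
#' @examples
#' g <- voxel_grid(array(TRUE, c(2, 1, 1)))
#' penalty_value(c(3, 5), penalty("tv", lambda = 1), g)
#' @export
penalty_value <- function(beta, spec, grid) {
  beta <- check_beta(beta, grid)
  w <- penalty_weights(spec)
  val <- 0
  if (w["w1"] > 0) val <- val + w["w1"] * sum(abs(beta))
  if (w["w2"] > 0) val <- val + w["w2"] * sum(beta^2)
  if (w["wtv"] > 0 || w["wlap"] > 0) {
    gmat <- discrete_gradient(beta, grid)
    if (w["wtv"] > 0) val <- val + w["wtv"] * sum(abs(gmat))
    if (w["wlap"] > 0) val <- val + w["wlap"] * sum(gmat^2)
  }
  unname(val)
}

#' Proximal map of the nonsmooth part of a penalty
#'
#' Computes `argmin_z 0.5 * ||z - v||^2 + step * Omega_ns(z)` where
#' `Omega_ns` is the nonsmooth part of the penalty: the l1 term for
#' LASSO/ENET/SLAP (exact soft-thresholding), the total-variation term for
#' TV (solved on the dual by accelerated projected gradient), and TV + l1
#' for STV (soft-thresholding composed after the TV prox, the fused-lasso
#' composition identity). Quadratic terms (squared l2, Laplacian) are
#' handled by the smooth gradient in [fit_model()], not here, and contribute
#' nothing to this map.
#'
#' @param v numeric vector of length `grid$p`.
#' @param spec a [penalty()] specification.
#' @param step positive step size multiplying the penalty.
#' @param grid a [voxel_grid()].
#' @param tv_tol,tv_max_iter tolerance (max-norm change of the dual
#'   variable) and iteration cap of the inner TV dual solver.
#' @param warm optional warm start for the TV dual variable
#'   (`p x 3` matrix, as returned in the `dual` attribute).
#' @return The prox output vector. For TV-bearing families it carries
#'   attributes `dual` (final dual variable), `iterations` and `converged`;
#'   non-convergence within `tv_max_iter` raises a warning and returns the
#'   best iterate.
#' @export
proximal_map <- function(v, spec, step, grid, tv_tol = 1e-8,
                         tv_max_iter = 500L, warm = NULL) {
  v <- check_beta(v, grid, arg = "v")
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("`step` must be a positive scalar.", call. = FALSE)
  }
  w <- penalty_weights(spec)
  if (w["wtv"] > 0) {
    u0 <- if (is.null(warm)) matrix(0, grid$p, 3L) else warm
    res <- tv_prox_cpp(v, step * w[["wtv"]], grid$nbr_back, u0,
                       tv_tol, as.integer(tv_max_iter))
    z <- drop(res$z)
    if (!res$converged) {
      warning(sprintf(
        "TV prox did not reach tol %.1e within %d dual iterations; returning best iterate.",
        tv_tol, tv_max_iter))
    }
    if (w["w1"] > 0) z <- soft_threshold(z, step * w[["w1"]])
    attr(z, "dual") <- res$u
    attr(z, "iterations") <- res$iterations
    attr(z, "converged") <- as.logical(res$converged)
    z
  } else if (w["w1"] > 0) {
    soft_threshold(v, step * w[["w1"]])
  } else {
    v
  }
}

#' Soft-thresholding operator
#'
#' `sign(v) * pmax(|v| - t, 0)`, the exact proximal map of `t * ||.||_1`.
#'
#' @param v numeric vector.
#' @param t nonnegative threshold.
#' @return Numeric vector of the same length.
#' @export
soft_threshold <- function(v, t) {
  sign(v) * pmax(abs(v) - t, 0)
}
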