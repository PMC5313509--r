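#' Solver options for the accelerated proximal gradient method
#'
#' @param tol relative objective-change tolerance; the solver stops after
#'   three consecutive accepted iterations whose relative decrease falls
#'   below it.
#' @param max_iter outer iteration cap.
#' @param tv_tol,tv_max_iter tolerance and cap of the inner dual solver of
#'   the TV proximal map (max-norm change of the dual variable).
#' @param center subtract the column means of the training features before
#'   fitting (off by default: the decision function is `sign(x' beta)` with
#'   no intercept and classes are balanced by design).
#' @param gram_limit use the precomputed Gram matrix `X'X` when
#'   `p <= gram_limit` (cheap re-fits along a hyperparameter path); above it
#'   the solver multiplies by `X` directly.
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(tol = 1e-6, max_iter = 5000L, tv_tol = 1e-8,
                           tv_max_iter = 500L, center = FALSE,
                           gram_limit = 2048L) {
  stopifnot(tol > 0, max_iter >= 1, tv_tol > 0, tv_max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter), tv_tol = tv_tol,
                 tv_max_iter = as.integer(tv_max_iter),
                 center = isTRUE(center), gram_limit = as.integer(gram_limit)),
            class = "solver_options")
}

# Smooth-part Lipschitz constant: 2/m * eigmax(X'X) + 2*w2 + 2*wlap*eigmax(L),
# with eigmax(L) bounded by 2 * max degree = 12 on a 3D grid. eig_xx is
# eigmax(X'X) (estimated once per design matrix and reused along the path).
smooth_lipschitz <- function(eig_xx, m, w) {
  2 * eig_xx * 1.01 / m + 2 * w[["w2"]] + 24 * w[["wlap"]] + 1e-12
}

# Largest eigenvalue of X'X via power iteration on the Gram (p x p) or on
# X directly.
eigmax_xtx <- function(G = NULL, X = NULL, iter = 100L, seed_vec = NULL) {
  p <- if (!is.null(G)) ncol(G) else ncol(X)
  v <- if (is.null(seed_vec)) rep(1, p) else seed_vec
  v <- v / sqrt(sum(v^2))
  eig <- 0
  for (k in seq_len(iter)) {
    w <- if (!is.null(G)) as.vector(G %*% v) else as.vector(crossprod(X, X %*% v))
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    conv <- abs(nw - eig) <= 1e-10 * max(1, nw)
    eig <- nw
    v <- w / nw
    if (conv && k > 5) break
  }
  eig
}

#' Fit a penalized least-squares decoder
#'
#' Minimizes `E(beta) + Omega(beta)` with `E(beta) = (1/m)||X beta - y||^2`
#' by monotone FISTA: the squared-l2 and Laplacian penalty terms join the
#' smooth gradient (step size from a power-iteration Lipschitz estimate),
#' the l1 and TV terms are handled by their proximal maps (exact
#' soft-thresholding; accelerated dual projected gradient for TV, with the
#' STV prox as soft-thresholding composed after the TV prox).
#' Initialization is at `beta = 0`, so the fit is deterministic.
#'
#' @param data a [decode_dataset()].
#' @param spec a [penalty()] specification.
#' @param options a [solver_options()] list.
#' @param init optional warm-start coefficient vector (default zero).
#' @param gram,Xty,eig_xx optional precomputed `X'X`, `X'y` and
#'   `eigmax(X'X)` for the training design; used by the cross-validation
#'   driver to share work across a hyperparameter path.
#' @param tv_warm optional warm start for the TV dual variable.
#' @return An object of class `decoder_fit` with elements `beta`,
#'   `objective`, `iterations`, `converged`, `spec`, `grid`, plus solver
#'   diagnostics (`trace`, `tv_iterations`, `tv_all_converged`) and, when
#'   `center = TRUE`, the column means used.
#' @examples
#' g <- voxel_grid(array(TRUE, c(2, 1, 1)))
#' d <- decode_dataset(diag(2), c(1, -1), c("a", "a"), g)
#' fit <- fit_model(d, penalty("enet", lambda1 = 0, lambda2 = 0.5))
#' round(fit$beta, 6)
#' @export
fit_model <- function(data, spec, options = solver_options(), init = NULL,
                      gram = NULL, Xty = NULL, eig_xx = NULL, tv_warm = NULL) {
  stopifnot(inherits(data, "decode_dataset"), inherits(spec, "penalty_spec"))
  if (!inherits(options, "solver_options")) {
    stop("`options` must come from solver_options().", call. = FALSE)
  }
  X <- data$X
  centers <- NULL
  if (options$center) {
    centers <- colMeans(X)
    X <- sweep(X, 2L, centers)
    gram <- Xty <- eig_xx <- NULL # precomputations refer to uncentered X
  }
  p <- data$p
  # the Gram path wins only when p is small relative to m (each iteration
  # costs p^2 instead of 2mp) or a cached Gram is already available
  use_gram <- !is.null(gram) || p <= min(options$gram_limit, data$m)
  if (use_gram && is.null(gram)) gram <- crossprod(X)
  if (is.null(Xty) || !is.null(centers)) Xty <- as.vector(crossprod(X, data$y))
  if (is.null(eig_xx)) {
    eig_xx <- if (use_gram) eigmax_xtx(G = gram) else eigmax_xtx(X = X)
  }
  w <- penalty_weights(spec)
  lips <- smooth_lipschitz(eig_xx, data$m, w)
  beta0 <- if (is.null(init)) numeric(p) else check_beta(init, data$grid, "init")
  u0 <- if (is.null(tv_warm)) matrix(0, p, 3L) else tv_warm

  res <- fista_fit_cpp(
    use_gram,
    if (use_gram) gram else matrix(0, 0L, 0L),
    if (use_gram) matrix(0, 0L, 0L) else X,
    Xty, data$y, sum(data$y^2), data$m,
    w[["w1"]], w[["w2"]], w[["wtv"]], w[["wlap"]],
    data$grid$nbr_back, lips, beta0, u0,
    options$tol, options$max_iter, options$tv_tol, options$tv_max_iter
  )
  structure(
    list(beta = drop(res$beta), objective = res$objective,
         iterations = res$iterations, converged = res$converged,
         trace = drop(res$trace), tv_iterations = res$tv_iterations,
         tv_all_converged = res$tv_all_converged, tv_dual = res$u,
         spec = spec, grid = data$grid, m = data$m, centers = centers),
    class = "decoder_fit"
  )
}

#' @export
print.decoder_fit <- function(x, ...) {
  cat(sprintf("<decoder_fit> %s: objective %.6g after %d iterations (%s)\n",
              toupper(x$spec$family), x$objective, x$iterations,
              if (isTRUE(x$converged)) "converged" else "max_iter reached"))
  invisible(x)
}

#' Predict class labels from a fitted decoder
#'
#' The decision function is `sign(x' beta)`, with `sign(0)` mapped to `+1`
#' (fixed convention, so predictions are always in `{-1, +1}`).
#'
#' @param object a `decoder_fit`.
#' @param newdata a numeric matrix (`n x p`) or a [decode_dataset()].
#' @param ... unused.
#' @return Numeric vector of labels in `{-1, +1}`.
#' @export
predict.decoder_fit <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "decode_dataset")) newdata$X else as.matrix(newdata)
  if (ncol(X) != length(object$beta)) {
    stop("`newdata` column count does not match the fitted coefficients.",
         call. = FALSE)
  }
  if (!is.null(object$centers)) X <- sweep(X, 2L, object$centers)
  predict_labels(object$beta, X)
}

#' Linear decision rule sign(x' beta)
#'
#' @param beta coefficient vector.
#' @param X matrix with scans as rows.
#' @return Labels in `{-1, +1}`; `sign(0)` maps to `+1`.
#' @export
predict_labels <- function(beta, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(beta)) stop("dimension mismatch.", call. = FALSE)
  scores <- as.vector(X %*% beta)
  ifelse(scores >= 0, 1, -1)
}

#' Critical l1 regularization that zeroes the LASSO solution
#'
#' For the `(1/m)` square loss the LASSO estimate is identically zero
#' exactly when `lambda1 >= 2 * max|X'y| / m`; hyperparameter grids are laid
#' out downward from this value.
#'
#' @param data a [decode_dataset()].
#' @return Positive scalar.
#' @export
lambda_max_l1 <- function(data) {
  stopifnot(inherits(data, "decode_dataset"))
  2 * max(abs(crossprod(data$X, data$y))) / data$m
}
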