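#' Leave-one-subject-out folds
#'
#' One fold per distinct subject; all examples of the held-out subject leave
#' together (this is never leave-one-example-out).
#'
#' @param subject vector of per-example subject identifiers.
#' @return Tibble with columns `test_subject`, `train` and `test`
#'   (list-columns of row indices).
#' @export
loso_folds <- function(subject) {
  subject <- as.character(subject)
  subs <- unique(subject)
  if (length(subs) < 2L) stop("need at least 2 distinct subjects.", call. = FALSE)
  tibble::tibble(
    test_subject = subs,
    train = lapply(subs, function(s) which(subject != s)),
    test = lapply(subs, function(s) which(subject == s))
  )
}

#' Default hyperparameter grid for a penalty family
#'
#' Regularization strengths are laid out on a log scale downward from the
#' critical value `lambda_max` that zeroes the LASSO solution on the given
#' data (the natural scale for all six families, since every penalty
#' competes against the same `(1/m)` square loss). Single-parameter families
#' (LASSO, TV, STV, LAP) get `n_lambda` values; ENET crosses the l1 grid
#' with a 5-point `lambda2` grid; SLAP crosses `lambda` with
#' `alpha in {0.1, 0.25, 0.5, 0.75, 0.9}`.
#'
#' @param data a [decode_dataset()] (used only for `lambda_max`).
#' @param family penalty family name.
#' @param n_lambda number of log-spaced regularization values.
#' @param lambda_min_ratio smallest value as a fraction of `lambda_max`.
#' @param alphas SLAP mixing grid.
#' @param lambda2s ENET quadratic weights; default spans
#'   `lambda_max * c(1e-3, 1e-2, 0.1, 1, 10)`.
#' @return Tibble of hyperparameter combinations with attribute `family`,
#'   ordered from strongest to weakest regularization (the warm-start
#'   order used by the cross-validation driver).
#' @export
default_hyper_grid <- function(data, family, n_lambda = 15L,
                               lambda_min_ratio = 1e-4,
                               alphas = c(0.1, 0.25, 0.5, 0.75, 0.9),
                               lambda2s = NULL) {
  family <- tolower(family)
  lmax <- lambda_max_l1(data)
  lams <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  grid <- switch(family,
    lasso = tibble::tibble(lambda1 = lams),
    enet = {
      if (is.null(lambda2s)) lambda2s <- lmax * c(1e-3, 1e-2, 0.1, 1, 10)
      tidyr::expand_grid(lambda1 = lams, lambda2 = sort(lambda2s,
                                                        decreasing = TRUE))
    },
    tv = tibble::tibble(lambda = lams),
    stv = tibble::tibble(lambda = lams),
    lap = tibble::tibble(lambda = lams),
    slap = tidyr::expand_grid(lambda = lams,
                              alpha = sort(alphas, decreasing = TRUE)),
    stop("unknown family: ", family, call. = FALSE))
  attr(grid, "family") <- family
  grid
}

grid_family <- function(grid) {
  fam <- attr(grid, "family", exact = TRUE)
  if (is.null(fam)) stop("grid lacks a 'family' attribute; build it with default_hyper_grid() or hyper_grid().", call. = FALSE)
  fam
}

#' Assemble a hyperparameter grid from explicit values
#'
#' @param family penalty family.
#' @param ... named hyperparameter vectors (`lambda`, `lambda1`, `lambda2`,
#'   `alpha` as the family requires); crossed with [tidyr::expand_grid()].
#' @return Tibble with attribute `family`, in strongest-first order.
#' @export
hyper_grid <- function(family, ...) {
  family <- tolower(family)
  grid <- tidyr::expand_grid(...)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid.", call. = FALSE)
  # strongest regularization first (warm-start and tie-break order)
  ord_cols <- intersect(c("lambda", "lambda1", "lambda2", "alpha"), names(grid))
  grid <- dplyr::arrange(grid, dplyr::across(dplyr::all_of(ord_cols),
                                             dplyr::desc))
  # validate by constructing each penalty once
  for (i in seq_len(nrow(grid))) row_penalty(grid[i, ], family)
  attr(grid, "family") <- family
  grid
}

row_penalty <- function(row, family) {
  penalty(family,
          lambda = row[["lambda"]], lambda1 = row[["lambda1"]],
          lambda2 = row[["lambda2"]], alpha = row[["alpha"]])
}

sparse_families <- c("lasso", "enet", "stv", "slap")

# Precompute per-subject Gram blocks and X'y pieces so every LOSO fold's
# Gram is a sum over its own training subjects' blocks. Summing (rather
# than downdating a full-data total) keeps each fold's quantities an exact
# function of that fold's training data alone — held-out scans must not
# influence a fit even at floating-point level.
gram_cache <- function(data, options) {
  if (data$p > options$gram_limit || data$p > data$m) return(NULL)
  subs <- unique(data$subject)
  by_sub <- lapply(subs, function(s) {
    idx <- which(data$subject == s)
    Xs <- data$X[idx, , drop = FALSE]
    list(G = crossprod(Xs), xty = as.vector(crossprod(Xs, data$y[idx])))
  })
  names(by_sub) <- subs
  list(by_subject = by_sub)
}

cache_sum <- function(cache, keep_subjects) {
  blocks <- cache$by_subject[keep_subjects]
  list(G = Reduce(`+`, lapply(blocks, `[[`, "G")),
       xty = Reduce(`+`, lapply(blocks, `[[`, "xty")))
}

# Fit every grid point on one training set. Coefficients always start from
# zero: with m < p the minimizer need not be unique at weak regularization,
# and a coefficient warm start would make the returned signature depend on
# the visiting order, biasing the stability measures computed from them.
# The TV dual variable, by contrast, solves a strongly convex subproblem
# with a unique solution, so carrying it along the path is pure
# acceleration and is kept. Returns a list of decoder_fit objects (NULL
# where fitting failed).
fit_grid_path <- function(train_data, grid, family, options, gram = NULL,
                          Xty = NULL, eig_xx = NULL) {
  fits <- vector("list", nrow(grid))
  u_warm <- NULL
  for (gi in seq_len(nrow(grid))) {
    spec <- row_penalty(grid[gi, ], family)
    fits[[gi]] <- tryCatch(
      {
        f <- fit_model(train_data, spec, options,
                       gram = gram, Xty = Xty, eig_xx = eig_xx,
                       tv_warm = u_warm)
        u_warm <- f$tv_dual
        f
      },
      error = function(e) {
        warning(sprintf("fit failed for grid point %d (%s): %s", gi,
                        toupper(family), conditionMessage(e)))
        NULL
      })
  }
  fits
}

#' Evaluate a hyperparameter grid on the internal LOSO loop
#'
#' For every hyperparameter combination, fits one model per internal fold
#' (each subject of `train_data` held out in turn), then computes the mean
#' internal macro accuracy over the left-out subjects and the mean pairwise
#' stability of the internal signatures: chance-corrected overlap on the
#' thresholded supports and Pearson correlation on the raw coefficients.
#'
#' @param train_data a [decode_dataset()] with at least 2 subjects.
#' @param grid hyperparameter tibble (with `family` attribute).
#' @param options a [solver_options()].
#' @param fraction l1-mass fraction for [threshold_coefficients()].
#' @param stability which stability summaries to compute
#'   (`"both"`, `"corrected_overlap"`, `"correlation"`, `"none"`).
#' @param cache internal Gram cache (built automatically when `NULL`).
#' @return Tibble of criterion points: hyperparameter columns plus
#'   `accuracy`, `oc`, `corr`, `ok` (FALSE where any internal fit failed;
#'   such points are excluded from selection).
#' @export
internal_evaluate <- function(train_data, grid, options = solver_options(),
                              fraction = 1e-4, stability = "both",
                              cache = NULL) {
  stability <- match.arg(stability,
                         c("both", "corrected_overlap", "correlation", "none"))
  family <- grid_family(grid)
  folds <- loso_folds(train_data$subject)
  n_folds <- nrow(folds)
  if (is.null(cache)) cache <- gram_cache(train_data, options)

  # fits[[fold]][[grid_point]]. Every fit starts from zero (no warm starts
  # across folds or grid points), so each signature depends on its training
  # data alone and the stability measures compare independent solutions.
  # Each fold's Gram and spectral bound come from its own training rows
  # only — nothing of the left-out subject enters the fit.
  fits <- vector("list", n_folds)
  for (fi in seq_len(n_folds)) {
    tr <- dataset_rows(train_data, folds$train[[fi]])
    if (!is.null(cache)) {
      gx <- cache_sum(cache, setdiff(folds$test_subject, folds$test_subject[fi]))
      fits[[fi]] <- fit_grid_path(tr, grid, family, options,
                                  gram = gx$G, Xty = gx$xty,
                                  eig_xx = eigmax_xtx(G = gx$G))
    } else {
      fits[[fi]] <- fit_grid_path(tr, grid, family, options,
                                  eig_xx = eigmax_xtx(X = tr$X))
    }
  }
  points_from_fits(fits, folds, train_data, grid, fraction, stability)
}

# Assemble the criterion-point table from per-fold, per-grid-point fits.
points_from_fits <- function(fits, folds, train_data, grid, fraction,
                             stability) {
  n_folds <- nrow(folds)
  purrr::map_dfr(seq_len(nrow(grid)), function(gi) {
    point_fits <- lapply(fits, `[[`, gi)
    ok <- !any(vapply(point_fits, is.null, TRUE))
    acc <- oc <- corr <- NA_real_
    if (ok) {
      per_sub_acc <- vapply(seq_len(n_folds), function(fi) {
        te <- folds$test[[fi]]
        preds <- predict_labels(point_fits[[fi]]$beta,
                                train_data$X[te, , drop = FALSE])
        mean(preds == train_data$y[te])
      }, 1.0)
      acc <- mean(per_sub_acc) # macro over internal left-out subjects
      if (stability != "none") {
        betas <- lapply(point_fits, `[[`, "beta")
        ss <- suppressWarnings(
          stability_summary(betas, p = train_data$p, fraction = fraction))
        if (stability %in% c("both", "corrected_overlap")) oc <- ss$oc_bar
        if (stability %in% c("both", "correlation")) corr <- ss$c_bar
      }
    }
    dplyr::bind_cols(grid[gi, ],
                     tibble::tibble(accuracy = acc, oc = oc, corr = corr,
                                    ok = ok))
  })
}

#' Pick hyperparameters from internal criterion points
#'
#' Three criteria:
#' \describe{
#'   \item{`"acc"`}{maximize mean internal accuracy.}
#'   \item{`"acc_oc"`}{minimize the Euclidean distance to the ideal point
#'     `(1, 1)` in the accuracy vs corrected-overlap diagram. Only defined
#'     for the sparse families (LASSO, ENET, STV, SLAP); dense TV and LAP
#'     supports make corrected overlap meaningless.}
#'   \item{`"acc_corr"`}{same distance rule in the accuracy vs correlation
#'     diagram (all families).}
#' }
#' Accuracy enters the distance on its natural `[0, 1]` scale; corrected
#' overlap is used raw (it may be slightly negative) so the distance stays
#' well-defined. Ties break toward stronger regularization: larger
#' `lambda`/`lambda1`, then larger `lambda2`/`alpha`.
#'
#' @param points tibble from [internal_evaluate()].
#' @param criterion `"acc"`, `"acc_oc"` or `"acc_corr"`.
#' @param family penalty family of the points (taken from the attribute if
#'   present).
#' @return The chosen row of `points`, with a `distance` column for the
#'   distance-based criteria.
#' @export
select_hyperparameters <- function(points, criterion, family = NULL) {
  criterion <- match.arg(criterion, c("acc", "acc_oc", "acc_corr"))
  if (is.null(family)) family <- attr(points, "family", exact = TRUE)
  valid <- dplyr::filter(points, .data$ok, is.finite(.data$accuracy))
  if (nrow(valid) == 0L) stop("no valid criterion points.", call. = FALSE)
  if (criterion == "acc_oc") {
    if (!is.null(family) && !family %in% sparse_families) {
      stop("criterion 'acc_oc' applies only to sparse families (lasso, enet, stv, slap).",
           call. = FALSE)
    }
    valid$distance <- sqrt((1 - valid$accuracy)^2 + (1 - valid$oc)^2)
  } else if (criterion == "acc_corr") {
    valid$distance <- sqrt((1 - valid$accuracy)^2 + (1 - valid$corr)^2)
  }
  ord_cols <- intersect(c("lambda", "lambda1", "lambda2", "alpha"),
                        names(valid))
  valid <- dplyr::arrange(valid, dplyr::across(dplyr::all_of(ord_cols),
                                               dplyr::desc))
  if (criterion == "acc") {
    best <- which.max(valid$accuracy) # first max = strongest regularization
  } else {
    best <- which.min(valid$distance)
  }
  valid[best, ]
}

#' Nested leave-one-subject-out run
#'
#' The external loop assesses; the internal loop selects. For each external
#' fold (one subject held out): evaluate the whole hyperparameter grid on
#' the internal LOSO folds of the remaining subjects, choose hyperparameters
#' under each requested criterion, refit on all training subjects with the
#' winner, threshold the coefficients, and classify the held-out subject.
#' Across the N external signatures of each criterion, the run reports
#' macro accuracy, sparsity mean and SD, and the mean pairwise overlap,
#' corrected overlap and correlation.
#'
#' The internal fits are shared between criteria (the criteria differ only
#' in how they read the same accuracy-vs-stability points), and refits are
#' cached when two criteria choose the same combination. All fits are
#' deterministic, so the result is reproducible from the inputs alone.
#'
#' @param data a [decode_dataset()] with at least 3 subjects.
#' @param grid hyperparameter tibble with `family` attribute (see
#'   [default_hyper_grid()], [hyper_grid()]).
#' @param criteria subset of `c("acc", "acc_oc", "acc_corr")`.
#' @param options a [solver_options()].
#' @param fraction l1-mass fraction for thresholding.
#' @param keep_signatures keep the external coefficient vectors in the
#'   result (needed for maps and recomputing stability; default TRUE).
#' @return Object of class `selection_result`: `summary` (one row per
#'   criterion: accuracy, correlation, sparsity, overlap, corrected
#'   overlap, with SDs), `folds` (per criterion x external fold: chosen
#'   hyperparameters, test accuracy, sparsity), `diagrams` (internal
#'   criterion points per external fold), `signatures` (per criterion, list
#'   of thresholded external coefficient vectors), `stability` (per
#'   criterion, the external [stability_summary()]), plus `family`, `grid`,
#'   `criteria`.
#' @export
nested_loso_run <- function(data, grid, criteria = c("acc", "acc_oc"),
                            options = solver_options(), fraction = 1e-4,
                            keep_signatures = TRUE) {
  stopifnot(inherits(data, "decode_dataset"))
  family <- grid_family(grid)
  criteria <- match.arg(criteria, c("acc", "acc_oc", "acc_corr"),
                        several.ok = TRUE)
  if ("acc_oc" %in% criteria && !family %in% sparse_families) {
    stop("criterion 'acc_oc' is not applicable to family '", family,
         "' (dense supports).", call. = FALSE)
  }
  subs <- unique(data$subject)
  if (length(subs) < 3L) {
    stop("nested LOSO needs >= 3 subjects (>= 2 internal folds).",
         call. = FALSE)
  }
  folds <- loso_folds(data$subject)
  cache <- gram_cache(data, options)

  # The internal training set of external fold i, internal fold j excludes
  # exactly subjects {i, j} — the same set as external j, internal i — so
  # grid-path fits are computed once per unordered subject pair and reused.
  # Every fold-level quantity (Gram, X'y, spectral bound) is built from the
  # fold's own training subjects only, so held-out data cannot influence a
  # fit even through the step size.
  pair_fits <- new.env(parent = emptyenv())
  pair_path <- function(s_i, s_j) {
    key <- paste(sort(c(s_i, s_j)), collapse = "\r")
    got <- get0(key, envir = pair_fits)
    if (!is.null(got)) return(got)
    idx <- which(!data$subject %in% c(s_i, s_j))
    tr <- dataset_rows(data, idx)
    f <- if (!is.null(cache)) {
      gx <- cache_sum(cache, setdiff(folds$test_subject, c(s_i, s_j)))
      fit_grid_path(tr, grid, family, options, gram = gx$G, Xty = gx$xty,
                    eig_xx = eigmax_xtx(G = gx$G))
    } else {
      fit_grid_path(tr, grid, family, options, eig_xx = eigmax_xtx(X = tr$X))
    }
    assign(key, f, envir = pair_fits)
    f
  }

  per_fold <- vector("list", nrow(folds))
  diagrams <- vector("list", nrow(folds))
  for (fi in seq_len(nrow(folds))) {
    tr_idx <- folds$train[[fi]]
    te_idx <- folds$test[[fi]]
    train_data <- dataset_rows(data, tr_idx)
    ext_gram <- NULL; ext_xty <- NULL
    if (!is.null(cache)) {
      gx <- cache_sum(cache, setdiff(folds$test_subject,
                                     folds$test_subject[fi]))
      ext_gram <- gx$G; ext_xty <- gx$xty
      eig_ext <- eigmax_xtx(G = ext_gram)
    } else {
      eig_ext <- eigmax_xtx(X = train_data$X)
    }
    int_folds <- loso_folds(train_data$subject)
    int_fits <- lapply(int_folds$test_subject, function(s_j) {
      pair_path(folds$test_subject[fi], s_j)
    })
    points <- points_from_fits(int_fits, int_folds, train_data, grid,
                               fraction, stability = "both")
    attr(points, "family") <- family
    diagrams[[fi]] <- dplyr::bind_cols(
      tibble::tibble(test_subject = folds$test_subject[fi]), points)

    refit_cache <- list()
    per_fold[[fi]] <- lapply(criteria, function(cr) {
      chosen <- select_hyperparameters(points, cr, family = family)
      key <- paste(vapply(
        chosen[intersect(c("lambda", "lambda1", "lambda2", "alpha"),
                         names(chosen))],
        function(v) sprintf("%.17g", v), ""), collapse = "|")
      if (is.null(refit_cache[[key]])) {
        spec <- row_penalty(chosen, family)
        refit_cache[[key]] <<- fit_model(train_data, spec, options,
                                         gram = ext_gram, Xty = ext_xty,
                                         eig_xx = eig_ext)
      }
      fit <- refit_cache[[key]]
      beta_thr <- threshold_coefficients(fit$beta, fraction)
      sp <- support_and_sparsity(beta_thr, data$p)
      preds <- predict_labels(beta_thr, data$X[te_idx, , drop = FALSE])
      list(criterion = cr, test_subject = folds$test_subject[fi],
           chosen = chosen, beta = beta_thr, beta_raw = fit$beta,
           sparsity = sp$sparsity,
           test_accuracy = mean(preds == data$y[te_idx]))
    })
  }

  hyp_cols <- intersect(c("lambda", "lambda1", "lambda2", "alpha"),
                        names(grid))
  fold_tbl <- purrr::map_dfr(seq_along(criteria), function(ci) {
    purrr::map_dfr(per_fold, function(pf) {
      r <- pf[[ci]]
      dplyr::bind_cols(
        tibble::tibble(criterion = r$criterion, test_subject = r$test_subject,
                       test_accuracy = r$test_accuracy, sparsity = r$sparsity),
        r$chosen[hyp_cols])
    })
  })

  signatures <- stats::setNames(lapply(seq_along(criteria), function(ci) {
    lapply(per_fold, function(pf) pf[[ci]]$beta)
  }), criteria)
  raw_signatures <- stats::setNames(lapply(seq_along(criteria), function(ci) {
    lapply(per_fold, function(pf) pf[[ci]]$beta_raw)
  }), criteria)

  stability <- lapply(criteria, function(cr) {
    betas <- raw_signatures[[cr]]
    suppressWarnings(stability_summary(betas, p = data$p, fraction = fraction))
  })
  names(stability) <- criteria

  summary_tbl <- purrr::map_dfr(criteria, function(cr) {
    rows <- fold_tbl[fold_tbl$criterion == cr, ]
    st <- stability[[cr]]
    off <- upper.tri(st$overlap) | lower.tri(st$overlap)
    tibble::tibble(
      family = family, criterion = cr,
      accuracy = mean(rows$test_accuracy),
      accuracy_sd = stats::sd(rows$test_accuracy),
      correlation = st$c_bar,
      correlation_sd = stats::sd(st$correlation[off]),
      sparsity = mean(rows$sparsity),
      sparsity_sd = stats::sd(rows$sparsity),
      overlap = st$o_bar, overlap_sd = stats::sd(st$overlap[off]),
      oc = st$oc_bar, oc_sd = stats::sd(st$corrected[off])
    )
  })

  structure(
    list(summary = summary_tbl, folds = fold_tbl,
         diagrams = dplyr::bind_rows(diagrams),
         signatures = if (keep_signatures) signatures else NULL,
         raw_signatures = if (keep_signatures) raw_signatures else NULL,
         stability = stability, family = family, grid = grid,
         criteria = criteria, n_subjects = length(subs), p = data$p),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s, %d subjects, %d grid points\n",
              toupper(x$family), x$n_subjects, nrow(x$grid)))
  print(x$summary)
  invisible(x)
}
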