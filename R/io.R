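#' Read a masked decoding dataset from NIfTI volumes and a labels table
#'
#' The mask defines the voxel grid; each volume (one scan) is masked and
#' becomes one row of the design matrix, in the order of the labels table.
#' The labels CSV must have columns `volume` (file name or path of the
#' scan), `label` (two values, coerced to `-1/+1`) and `subject`.
#'
#' @param mask_path NIfTI file of the binary mask.
#' @param volumes_dir directory resolving relative `volume` entries; a 4D
#'   NIfTI file may instead be given via `volumes_4d`.
#' @param labels_csv path of the labels table.
#' @param volumes_4d optional 4D NIfTI whose 4th dimension indexes scans;
#'   then `volume` must hold 1-based scan indices.
#' @return A [decode_dataset()].
#' @export
read_dataset <- function(mask_path, labels_csv, volumes_dir = ".",
                         volumes_4d = NULL) {
  mask_img <- RNifti::readNifti(mask_path)
  grid <- voxel_grid(array(as.logical(mask_img != 0), dim = dim(mask_img)))
  labels <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  needed <- c("volume", "label", "subject")
  missing_cols <- setdiff(needed, names(labels))
  if (length(missing_cols)) {
    stop("labels table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- nrow(labels)
  X <- matrix(NA_real_, m, grid$p)
  if (!is.null(volumes_4d)) {
    img4 <- RNifti::readNifti(volumes_4d)
    if (length(dim(img4)) != 4L || !all(dim(img4)[1:3] == grid$shape)) {
      stop("4D volume shape does not match the mask.", call. = FALSE)
    }
    idx <- as.integer(labels$volume)
    if (anyNA(idx) || any(idx < 1L) || any(idx > dim(img4)[4])) {
      stop("`volume` must index scans of the 4D file.", call. = FALSE)
    }
    for (i in seq_len(m)) X[i, ] <- mask_values(img4[, , , idx[i]], grid)
  } else {
    for (i in seq_len(m)) {
      f <- labels$volume[i]
      if (!file.exists(f)) f <- file.path(volumes_dir, labels$volume[i])
      vol <- RNifti::readNifti(f)
      if (!all(dim(vol)[1:3] == grid$shape)) {
        stop("volume '", labels$volume[i], "' shape does not match the mask.",
             call. = FALSE)
      }
      X[i, ] <- mask_values(vol, grid)
    }
  }
  decode_dataset(X, labels$label, labels$subject, grid)
}

#' Write a decoding dataset as NIfTI volumes plus a labels CSV
#'
#' Inverse of [read_dataset()]: writes the mask, one 4D NIfTI of scans and
#' the labels table (with `volume` holding scan indices). Off-mask voxels
#' are zero.
#'
#' @param data a [decode_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (`mask`, `volumes`, `labels`).
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "decode_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(mask = file.path(dir, "mask.nii.gz"),
                volumes = file.path(dir, "scans.nii.gz"),
                labels = file.path(dir, "labels.csv"))
  RNifti::writeNifti(array(as.numeric(data$grid$mask), dim = data$grid$shape),
                     paths$mask)
  arr <- array(0, dim = c(data$grid$shape, data$m))
  for (i in seq_len(data$m)) arr[, , , i] <- unmask(data$X[i, ], data$grid)
  RNifti::writeNifti(arr, paths$volumes)
  utils::write.csv(
    data.frame(volume = seq_len(data$m), label = data$y,
               subject = data$subject),
    paths$labels, row.names = FALSE)
  invisible(paths)
}

#' Write a fitted signature as a NIfTI coefficient map with JSON sidecar
#'
#' The coefficient vector is embedded into the 3D grid (zeros off-mask) and
#' written as NIfTI; the sidecar records the penalty family,
#' hyperparameters, solver diagnostics, sparsity and an optional fold
#' label.
#'
#' @param fit a `decoder_fit` (or a bare numeric vector plus `spec`).
#' @param path output NIfTI path; the sidecar replaces the extension with
#'   `.json`.
#' @param grid the [voxel_grid()]; taken from the fit when missing.
#' @param fold_id optional identifier of the left-out subject.
#' @param fraction l1-mass fraction used to report sparsity.
#' @return Invisibly, a list with the two paths.
#' @export
write_signature <- function(fit, path, grid = NULL, fold_id = NULL,
                            fraction = 1e-4) {
  if (inherits(fit, "decoder_fit")) {
    beta <- fit$beta
    if (is.null(grid)) grid <- fit$grid
    spec <- fit$spec
    diag <- list(objective = fit$objective, iterations = fit$iterations,
                 converged = isTRUE(fit$converged))
  } else {
    stop("`fit` must be a decoder_fit.", call. = FALSE)
  }
  RNifti::writeNifti(unmask(beta, grid), path)
  sp <- support_and_sparsity(threshold_coefficients(beta, fraction), grid$p)
  side <- list(
    family = spec$family,
    hyperparameters = spec[setdiff(names(spec), "family")],
    sparsity = sp$sparsity, support_size = length(sp$support),
    threshold_fraction = fraction, fold_id = fold_id, solver = diag)
  json_path <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(map = path, sidecar = json_path))
}

#' Read a coefficient map written by [write_signature()]
#'
#' @param path NIfTI path.
#' @param grid the [voxel_grid()] to re-mask with.
#' @return Numeric vector of length `grid$p`.
#' @export
read_signature <- function(path, grid) {
  vol <- RNifti::readNifti(path)
  mask_values(vol, grid)
}

#' Connected-component cluster table of a thresholded signature
#'
#' Face-connected (6-connectivity, matching the penalty neighborhood)
#' components of the support, sorted by extent: per cluster its voxel
#' count, the grid coordinate of the peak |coefficient| and the peak value.
#'
#' @param beta thresholded coefficient vector (or a `decoder_fit`, which is
#'   thresholded first).
#' @param grid the [voxel_grid()]; taken from the fit when missing.
#' @param fraction l1-mass fraction used when `beta` is a fit.
#' @return Tibble with columns `cluster`, `size`, `peak_x`, `peak_y`,
#'   `peak_z`, `peak_value`; zero rows for an empty support.
#' @export
cluster_report <- function(beta, grid = NULL, fraction = 1e-4) {
  if (inherits(beta, "decoder_fit")) {
    if (is.null(grid)) grid <- beta$grid
    beta <- threshold_coefficients(beta$beta, fraction)
  }
  if (is.null(grid)) stop("`grid` is required.", call. = FALSE)
  beta <- check_beta(beta, grid)
  support <- which(beta != 0)
  if (!length(support)) {
    return(tibble::tibble(cluster = integer(), size = integer(),
                          peak_x = integer(), peak_y = integer(),
                          peak_z = integer(), peak_value = double()))
  }
  comp <- support_components(support, grid)
  rows <- lapply(seq_along(comp), function(ci) {
    vox <- comp[[ci]]
    pk <- vox[which.max(abs(beta[vox]))]
    tibble::tibble(size = length(vox),
                   peak_x = grid$coords[pk, 1], peak_y = grid$coords[pk, 2],
                   peak_z = grid$coords[pk, 3], peak_value = beta[pk])
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$size))
  dplyr::bind_cols(tibble::tibble(cluster = seq_len(nrow(out))), out)
}

# breadth-first connected components of a voxel subset under face adjacency
support_components <- function(support, grid) {
  in_set <- logical(grid$p)
  in_set[support] <- TRUE
  visited <- logical(grid$p)
  comps <- list()
  # forward-neighbor lists derived once from the backward map
  fwd_idx <- lapply(1:3, function(l) {
    has <- which(grid$nbr_back[, l] > 0L)
    split(has, grid$nbr_back[has, l])
  })
  neighbor_list <- function(v) {
    b <- grid$nbr_back[v, ]
    out <- b[b > 0L]
    for (l in 1:3) {
      f <- fwd_idx[[l]][[as.character(v)]]
      if (!is.null(f)) out <- c(out, f)
    }
    out
  }
  for (s in support) {
    if (visited[s]) next
    queue <- s
    visited[s] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, v)
      nb <- neighbor_list(v)
      nb <- nb[in_set[nb] & !visited[nb]]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}
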