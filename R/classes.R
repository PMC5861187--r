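#' Gray-matter density stack
#'
#' Subjects x volume container for modulated, smoothed gray-matter density
#' maps plus the total-brain-value (TBV) covariate used by the voxelwise
#' regressions.
#'
#' @param subjects character vector of subject ids.
#' @param data 4-D array, subjects x nx x ny x nz, finite and >= 0 densities.
#' @param voxel_mm isotropic voxel size.
#' @param affine 4 x 4 invertible matrix mapping 0-based voxel indices to
#'   world (MNI-convention RAS) millimeter coordinates.
#' @param tbv per-subject total brain value; computed as
#'   `sum(map) * voxel_volume` when not supplied.
#' @param parcellation optional integer-labeled atlas array on the same grid.
#' @param focus_voxels bookkeeping from the synthetic generator (or NULL).
#' @return object of class `gm_stack`.
#' @export
gm_stack <- function(subjects, data, voxel_mm, affine, tbv = NULL,
                     parcellation = NULL, focus_voxels = NULL) {
  stopifnot(length(dim(data)) == 4L, dim(data)[1L] == length(subjects))
  if (!all(is.finite(data))) stop("densities must be finite")
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  vv <- voxel_mm^3
  internal_tbv <- apply(data, 1L, sum) * vv
  if (is.null(tbv)) {
    tbv <- internal_tbv
  } else if (max(abs(tbv - internal_tbv) / pmax(abs(internal_tbv), 1)) > 1e-6) {
    stop("tbv inconsistent with map sums (relative tolerance 1e-6)")
  }
  structure(list(subjects = subjects, data = data, voxel_mm = voxel_mm,
                 affine = affine, tbv = tbv, parcellation = parcellation,
                 focus_voxels = focus_voxels),
            class = "gm_stack")
}

#' @export
print.gm_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("gm_stack: %d subjects, %dx%dx%d grid at %g mm\n",
              d[1L], d[2L], d[3L], d[4L], x$voxel_mm))
  invisible(x)
}

# world coordinates (mm) of 1-based voxel index rows
voxel_to_world <- function(affine, voxel) {
  voxel <- matrix(voxel, ncol = 3L)
  t(affine %*% rbind(t(voxel) - 1, 1))[, 1:3, drop = FALSE]
}

#' Construct an ROI set
#'
#' Ordered table of spherical regions of interest. Ordering follows the
#' parameter list order, then within-parameter peak discovery order; ids are
#' 1-based in that order.
#'
#' @param df data.frame with columns `x`, `y`, `z` (world mm), `radius_mm`,
#'   `peak_t`, `parameter`, `parcel`.
#' @return data.frame of class `roi_set` with a leading `id` column.
#' @export
roi_set <- function(df) {
  need <- c("x", "y", "z", "radius_mm", "peak_t", "parameter", "parcel")
  stopifnot(all(need %in% names(df)))
  if (any(df$radius_mm <= 0)) stop("ROI radius must be > 0")
  df <- df[, need]
  df <- cbind(id = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  class(df) <- c("roi_set", "data.frame")
  df
}

#' Per-subject ROI correlation matrices
#'
#' @param subjects character vector of subject ids.
#' @param matrices 3-D array, subjects x R x R, of Pearson correlations.
#' @param roi_ids integer ids matching an `roi_set`.
#' @return object of class `connectivity_stack`.
#' @export
connectivity_stack <- function(subjects, matrices, roi_ids) {
  stopifnot(length(dim(matrices)) == 3L,
            dim(matrices)[1L] == length(subjects),
            dim(matrices)[2L] == dim(matrices)[3L],
            dim(matrices)[2L] == length(roi_ids))
  for (s in seq_len(dim(matrices)[1L])) {
    m <- matrices[s, , ]
    if (max(abs(m - t(m))) > 1e-8 || max(abs(diag(m) - 1)) > 1e-8)
      stop("matrix for subject ", subjects[s], " is not a unit-diagonal correlation matrix")
  }
  if (any(matrices < -1 - 1e-12 | matrices > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]")
  structure(list(subjects = subjects, matrices = matrices,
                 roi_ids = as.integer(roi_ids)),
            class = "connectivity_stack")
}

#' @export
print.connectivity_stack <- function(x, ...) {
  cat(sprintf("connectivity_stack: %d subjects, %d ROIs\n",
              length(x$subjects), length(x$roi_ids)))
  invisible(x)
}

# subjects x edges matrix of upper-triangle correlations
edge_matrix <- function(stack) {
  p <- edge_pairs(length(stack$roi_ids))
  n <- length(stack$subjects)
  out <- matrix(NA_real_, n, nrow(p))
  for (s in seq_len(n)) out[s, ] <- stack$matrices[s, , ][cbind(p[, 1L], p[, 2L])]
  out
}
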