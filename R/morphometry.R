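#' Voxelwise regression of gray-matter density on a psychometric score
#'
#' Fits, at every voxel, `density ~ intercept + score + tbv` across subjects
#' and returns the t-statistic (and two-sided p) of the score slope with
#' n - 3 degrees of freedom. Subjects with a missing score are dropped.
#' Voxels fit exactly (zero residual variance) get `t = +/-Inf`, `p = 0`,
#' and are flagged in `perfect_fit`.
#'
#' @param stack a [gm_stack()].
#' @param scores numeric score vector aligned with `stack$subjects`.
#' @param covariate nuisance covariate; defaults to the stack's TBV.
#' @return list of class `vox_reg`: 3-D arrays `t` and `p`, `df`,
#'   `n_effective`, logical array `perfect_fit`.
#' @export
voxelwise_regression <- function(stack, scores, covariate = stack$tbv) {
  n_all <- length(stack$subjects)
  stopifnot(length(scores) == n_all, length(covariate) == n_all)
  keep <- is.finite(scores)
  if (sum(keep) <= 3L)
    stop("insufficient data: voxelwise regression needs > 3 subjects with observed scores")
  if (stats::var(scores[keep]) == 0)
    stop("degenerate design: score column is constant")
  dims <- dim(stack$data)[-1L]
  Y <- matrix(stack$data[keep, , , ], nrow = sum(keep))  # subjects x voxels
  fit <- score_slope_t(Y, scores[keep], covariate[keep])
  structure(list(t = array(fit$t, dims), p = array(fit$p, dims),
                 df = fit$df, n_effective = sum(keep),
                 perfect_fit = array(fit$perfect, dims)),
            class = "vox_reg")
}

# score-slope t statistics for Y (n x V) on [1, score, cov]; vectorized over
# voxels through one QR decomposition of the design
score_slope_t <- function(Y, score, covariate) {
  n <- length(score)
  X <- cbind(1, score, covariate)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("degenerate design: score and covariate are collinear")
  coefs <- qr.coef(qx, Y)                  # 3 x V
  res <- Y - X %*% coefs
  df <- n - ncol(X)
  rss <- colSums(res^2)
  xtx_inv_22 <- chol2inv(qr.R(qx))[2L, 2L]
  sigma2 <- rss / df
  se <- sqrt(sigma2 * xtx_inv_22)
  tol <- 1e-10 * pmax(colSums(Y^2), 1)
  perfect <- rss <= tol
  t <- ifelse(perfect, sign(coefs[2L, ]) * Inf, coefs[2L, ] / se)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, p = p, df = df, perfect = perfect)
}

#' Small-volume familywise-error correction within atlas parcels
#'
#' For each parcel of the atlas, the null distribution of the within-parcel
#' maximum |t| is built by permuting scores across subjects and re-running
#' the voxelwise regression. A voxel is significant iff its uncorrected
#' p <= `alpha_unc` AND its |t| exceeds the (1 - `alpha_fwe`) quantile of
#' that parcel's permutation maxima. This is a distribution-free stand-in
#' for parametric voxel-level FWE correction, valid under exchangeability of
#' subjects.
#'
#' @param reg a `vox_reg` from [voxelwise_regression()].
#' @param parcellation integer atlas array on the density grid (defaults to
#'   the stack's own).
#' @param stack,scores,covariate the inputs of the observed regression (the
#'   permutation null re-uses them).
#' @param n_perm permutations (>= 100).
#' @param alpha_fwe familywise level within a parcel.
#' @param alpha_unc primary uncorrected threshold.
#' @param seed permutation RNG seed.
#' @return list of class `svc_masks`: `masks` (named list, parcel id ->
#'   logical 3-D array), `thresholds` (per-parcel |t| cutoffs), `params`.
#'   Parcels with < 2 voxels are skipped with a warning.
#' @export
small_volume_fwe <- function(reg, parcellation = NULL, stack, scores,
                             covariate = stack$tbv, n_perm = 1000L,
                             alpha_fwe = 0.05, alpha_unc = 0.001, seed = 1L) {
  parcellation <- parcellation %||% stack$parcellation
  stopifnot(!is.null(parcellation), n_perm >= 100L)
  if (!all(dim(parcellation) == dim(reg$t)))
    stop("parcellation grid does not match the density grid")
  keep <- is.finite(scores)
  Y <- matrix(stack$data[keep, , , ], nrow = sum(keep))
  sc <- scores[keep]; cv <- covariate[keep]
  parcels <- sort(unique(as.vector(parcellation)))
  parcels <- parcels[parcels != 0]
  vox_of <- lapply(parcels, function(pc) which(parcellation == pc))
  names(vox_of) <- parcels
  small <- lengths(vox_of) < 2L
  if (any(small)) {
    warning("skipping parcels with < 2 voxels: ",
            paste(parcels[small], collapse = ", "))
    parcels <- parcels[!small]; vox_of <- vox_of[!small]
  }
  set.seed(derive_seed(seed, "svc"))
  perm_max <- matrix(NA_real_, n_perm, length(parcels),
                     dimnames = list(NULL, parcels))
  for (b in seq_len(n_perm)) {
    tb <- score_slope_t(Y, sample(sc), cv)$t
    perm_max[b, ] <- vapply(vox_of, function(v) max(abs(tb[v])), numeric(1L))
  }
  # (1 - alpha_fwe) order statistic of the permutation maxima; alpha_fwe = 1
  # disables the correction entirely
  k_ord <- ceiling((1 - alpha_fwe) * n_perm)
  thresholds <- if (k_ord < 1L) rep(-Inf, ncol(perm_max)) else
    apply(perm_max, 2L, function(v) sort(v)[k_ord])
  names(thresholds) <- colnames(perm_max)
  masks <- vector("list", length(parcels))
  names(masks) <- parcels
  for (k in seq_along(parcels)) {
    m <- array(FALSE, dim(reg$t))
    v <- vox_of[[k]]
    m[v] <- reg$p[v] <= alpha_unc & abs(reg$t[v]) > thresholds[k]
    masks[[k]] <- m
  }
  structure(list(masks = masks, thresholds = thresholds,
                 params = list(n_perm = n_perm, alpha_fwe = alpha_fwe,
                               alpha_unc = alpha_unc, seed = seed)),
            class = "svc_masks")
}

#' Define peak-sphere ROIs from significant-voxel masks
#'
#' One ROI per non-empty (parameter, parcel) mask: a sphere of diameter
#' `diameter_mm` centered on the world coordinate of the maximum-|t| voxel
#' inside the mask. Ties on |t| are broken by the smallest linear voxel
#' index (x-fastest scan order), which is deterministic and order-stable.
#'
#' @param masks an `svc_masks` (or plain named list of logical arrays).
#' @param t_volume the observed t array.
#' @param affine voxel-to-world affine of the grid.
#' @param diameter_mm sphere diameter (default 5).
#' @param parameter name recorded as the ROI's source parameter.
#' @return a [roi_set()] (pre-deduplication); zero rows if no mask voxel.
#' @export
define_rois <- function(masks, t_volume, affine, diameter_mm = 5,
                        parameter = "score") {
  if (inherits(masks, "svc_masks")) masks <- masks$masks
  rows <- list()
  for (pc in names(masks)) {
    v <- which(masks[[pc]])
    if (!length(v)) next
    peak <- v[which.max(abs(t_volume[v]))]   # which.max takes the first max
    vox <- arrayInd(peak, dim(t_volume))
    w <- voxel_to_world(affine, vox)
    rows[[length(rows) + 1L]] <- data.frame(
      x = w[1L], y = w[2L], z = w[3L], radius_mm = diameter_mm / 2,
      peak_t = t_volume[peak], parameter = parameter,
      parcel = as.integer(pc))
  }
  if (!length(rows))
    return(roi_set(data.frame(x = numeric(), y = numeric(), z = numeric(),
                              radius_mm = numeric(), peak_t = numeric(),
                              parameter = character(), parcel = integer())))
  roi_set(do.call(rbind, rows))
}

#' Remove overlapping ROIs, keeping the first in parameter-list order
#'
#' Single forward pass over the ordered ROI set: an ROI is retained iff its
#' sphere does not intersect any already-retained sphere, where two spheres
#' intersect when the distance between centers is strictly less than the sum
#' of their radii. Retained ROIs keep their relative order and are
#' renumbered 1..R. Idempotent.
#'
#' @param rois a [roi_set()] ordered by parameter list then discovery order.
#' @return deduplicated [roi_set()].
#' @export
dedup_rois <- function(rois) {
  if (nrow(rois) <= 1L) return(roi_set(rois[, -1L, drop = FALSE]))
  keep <- logical(nrow(rois))
  centers <- as.matrix(rois[, c("x", "y", "z")])
  for (k in seq_len(nrow(rois))) {
    prior <- which(keep)
    if (!length(prior)) { keep[k] <- TRUE; next }
    d <- sqrt(colSums((t(centers[prior, , drop = FALSE]) - centers[k, ])^2))
    keep[k] <- all(d >= rois$radius_mm[prior] + rois$radius_mm[k])
  }
  roi_set(rois[keep, -1L, drop = FALSE])
}

#' Discover a pooled, deduplicated ROI set over many parameters
#'
#' Runs [voxelwise_regression()] + [small_volume_fwe()] + [define_rois()]
#' for every score column of a table (in column order), concatenates the
#' per-parameter ROIs, and applies [dedup_rois()].
#'
#' @param stack a [gm_stack()] (must carry a parcellation).
#' @param table a `psych_table`.
#' @param parameters score columns to scan; default all non-subject columns.
#' @param n_perm,alpha_fwe,alpha_unc,diameter_mm,seed see the stage functions.
#' @return list: `rois` (deduplicated [roi_set()]), `n_pre_dedup`,
#'   `per_parameter` (ROI counts before dedup).
#' @export
discover_rois <- function(stack, table, parameters = setdiff(names(table), "subject"),
                          n_perm = 1000L, alpha_fwe = 0.05, alpha_unc = 0.001,
                          diameter_mm = 5, seed = 1L) {
  pieces <- list()
  counts <- integer(length(parameters)); names(counts) <- parameters
  for (p in parameters) {
    reg <- voxelwise_regression(stack, table[[p]])
    masks <- small_volume_fwe(reg, stack$parcellation, stack, table[[p]],
                              n_perm = n_perm, alpha_fwe = alpha_fwe,
                              alpha_unc = alpha_unc,
                              seed = derive_seed(seed, paste0("svc_", p)))
    r <- define_rois(masks, reg$t, stack$affine, diameter_mm, parameter = p)
    counts[p] <- nrow(r)
    if (nrow(r)) pieces[[p]] <- as.data.frame(r)[, -1L]
  }
  pre <- if (length(pieces)) roi_set(do.call(rbind, pieces)) else
    define_rois(list(), array(0, c(1, 1, 1)), diag(4))
  list(rois = dedup_rois(pre), n_pre_dedup = nrow(pre), per_parameter = counts)
}
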