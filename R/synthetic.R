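#' Ground truth for a synthetic cohort
#'
#' Bundles the planted structure that the pipeline is expected to recover:
#' gray-matter foci whose density scales with a psychometric score, and
#' connectivity edges whose correlation scales with a score.
#'
#' @param n_rois number of candidate ROIs / time-series columns.
#' @param planted_foci data.frame with columns `parcel` (integer id),
#'   `parameter` (score column the focus tracks) and `beta` (density units per
#'   score unit). May have zero rows.
#' @param planted_edges data.frame with columns `i`, `j` (ROI indices,
#'   unordered pair), `parameter`, and `beta` (correlation units per standard
#'   score unit). May have zero rows.
#' @param score_model data.frame with columns `parameter`, `mean`, `sd`, and
#'   `battery` (missingness block).
#' @param seed integer; fully determines every emitted dataset.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(n_rois, planted_foci = NULL, planted_edges = NULL,
                         score_model = example_score_model(), seed = 1L) {
  planted_foci <- planted_foci %||%
    data.frame(parcel = integer(), parameter = character(), beta = numeric())
  planted_edges <- planted_edges %||%
    data.frame(i = integer(), j = integer(), parameter = character(), beta = numeric())
  stopifnot(all(c("parcel", "parameter", "beta") %in% names(planted_foci)),
            all(c("i", "j", "parameter", "beta") %in% names(planted_edges)),
            all(c("parameter", "mean", "sd", "battery") %in% names(score_model)))
  if (nrow(planted_edges)) {
    lo <- pmin(planted_edges$i, planted_edges$j)
    hi <- pmax(planted_edges$i, planted_edges$j)
    if (any(lo == hi)) stop("planted edge connects an ROI to itself")
    if (anyDuplicated(paste(lo, hi, planted_edges$parameter)))
      stop("planted edges must be unique unordered pairs per parameter")
    planted_edges$i <- lo
    planted_edges$j <- hi
    if (any(hi > n_rois)) stop("planted edge index exceeds n_rois")
  }
  if (!all(is.finite(planted_foci$beta)) || !all(is.finite(planted_edges$beta)))
    stop("planted effect sizes must be finite")
  structure(list(n_rois = as.integer(n_rois), planted_foci = planted_foci,
                 planted_edges = planted_edges, score_model = score_model,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Example psychometric score model
#'
#' Six parameters spanning three battery blocks, with means and SDs on the
#' 0-130 questionnaire scale typical of published battery summaries. The
#' `social` battery is complete; the `iq` and `eq` batteries are missing for
#' a fraction of subjects (whole battery absent per subject), mirroring
#' cohorts where some instruments could not be administered to everyone.
#'
#' @return data.frame with columns `parameter`, `mean`, `sd`, `battery`.
#' @export
example_score_model <- function() {
  data.frame(
    parameter = c("extraversion", "cooperativeness", "self_control",
                  "fluid_iq", "verbal_iq", "empathy"),
    mean = c(58.38, 56.70, 73.22, 56.55, 56.90, 57.18),
    sd   = c(10.40, 14.66, 12.25, 20.05, 12.00, 20.34),
    battery = c("social", "social", "social", "iq", "iq", "eq"),
    stringsAsFactors = FALSE
  )
}

#' Generate a psychometric score table
#'
#' Scores are drawn per parameter from a Gaussian truncated to `score_range`
#' (inverse-CDF method), so column means and SDs converge to the requested
#' moments as the cohort grows. Missingness is block-structured: for each
#' battery, a requested fraction of subjects has the entire battery absent.
#'
#' @param n_subjects cohort size (>= 10).
#' @param moments data.frame with columns `parameter`, `mean`, `sd`,
#'   `battery` (see [example_score_model()]).
#' @param missing_blocks named numeric vector, battery -> fraction of
#'   subjects missing that battery (default none missing).
#' @param seed integer seed; the same seed yields a byte-identical table.
#' @param score_range truncation bounds of the questionnaire scale.
#' @return data.frame of class `psych_table`: `subject` plus one numeric
#'   column per parameter (NA where the battery is missing). The moments used
#'   are attached as attribute `score_model`.
#' @export
generate_scores <- function(n_subjects, moments = example_score_model(),
                            missing_blocks = NULL, seed = 1L,
                            score_range = c(0, 130)) {
  stopifnot(n_subjects >= 10)
  if (any(!is.finite(moments$sd)) || any(moments$sd <= 0))
    stop("invalid moments: every SD must be finite and > 0")
  set.seed(derive_seed(seed, "scores"))
  tab <- data.frame(subject = sprintf("s%03d", seq_len(n_subjects)))
  for (k in seq_len(nrow(moments))) {
    m <- moments$mean[k]; s <- moments$sd[k]
    a <- stats::pnorm(score_range[1L], m, s)
    b <- stats::pnorm(score_range[2L], m, s)
    u <- stats::runif(n_subjects, a, b)
    tab[[moments$parameter[k]]] <- stats::qnorm(u, m, s)
  }
  if (length(missing_blocks)) {
    for (bat in names(missing_blocks)) {
      frac <- missing_blocks[[bat]]
      stopifnot(frac >= 0, frac < 1)
      n_miss <- round(frac * n_subjects)
      if (n_miss == 0) next
      miss <- sample.int(n_subjects, n_miss)
      cols <- moments$parameter[moments$battery == bat]
      tab[miss, cols] <- NA_real_
    }
  }
  for (p in moments$parameter) {
    obs <- tab[[p]][!is.na(tab[[p]])]
    if (length(unique(obs)) < 2) stop("degenerate score column: ", p)
  }
  attr(tab, "score_model") <- moments
  class(tab) <- c("psych_table", "data.frame")
  tab
}

#' Block parcellation of a cuboid grid
#'
#' Splits the volume into `n_blocks` near-equal slabs per axis, yielding
#' `n_blocks^3` integer-labeled parcels. A stand-in for an anatomical atlas:
#' any integer-labeled volume on the same grid can be supplied instead.
#'
#' @param dim length-3 integer grid size.
#' @param n_blocks cuts per axis.
#' @return integer 3-D array of parcel labels (1-based).
#' @export
generate_parcellation <- function(dim, n_blocks = 2L) {
  stopifnot(length(dim) == 3L, all(dim >= n_blocks))
  cut1 <- function(n) as.integer(cut(seq_len(n), breaks = n_blocks, labels = FALSE))
  ix <- cut1(dim[1L]); iy <- cut1(dim[2L]); iz <- cut1(dim[3L])
  arr <- array(0L, dim)
  for (z in seq_len(dim[3L])) for (y in seq_len(dim[2L]))
    arr[, y, z] <- ix + n_blocks * (iy[y] - 1L) + n_blocks^2 * (iz[z] - 1L)
  arr
}

# Separable Gaussian smoothing of a 3-D array by shift-and-add along each
# axis; zero padding at the borders. fwhm and voxel in mm.
gaussian_smooth_3d <- function(x, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(x)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  half <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-half:half, sd = sigma)
  w <- w / sum(w)
  shift_axis <- function(a, k, axis) {
    n <- dim(a)[axis]
    src <- seq_len(n) + k
    keep <- which(src >= 1L & src <= n)
    out <- array(0, dim(a))
    if (axis == 1L) out[keep, , ] <- a[src[keep], , ]
    else if (axis == 2L) out[, keep, ] <- a[, src[keep], ]
    else out[, , keep] <- a[, , src[keep]]
    out
  }
  for (axis in 1:3) {
    acc <- array(0, dim(x))
    for (k in -half:half)
      acc <- acc + w[k + half + 1L] * shift_axis(x, k, axis)
    x <- acc
  }
  x
}

#' Generate gray-matter density maps with planted foci
#'
#' Each subject's volume is a constant baseline plus, at every planted focus
#' voxel, `beta * (score - mean(score))`, plus Gaussian-smoothed noise
#' (emulating already-smoothed, normalized density maps). The total brain
#' value (TBV) is the map sum times the voxel volume.
#'
#' @param table `psych_table` of scores.
#' @param truth `ground_truth`; each planted focus is placed at the center
#'   voxel of its parcel.
#' @param grid list with `dim` (length-3) and `voxel_mm` (scalar).
#' @param parcellation integer array on `grid`; defaults to
#'   [generate_parcellation()] with 2 blocks per axis.
#' @param noise_sd pre-smoothing noise SD in density units.
#' @param smooth_fwhm_mm smoothing kernel FWHM applied to the noise field.
#' @param baseline constant density background.
#' @return a `gm_stack` (see [gm_stack()]).
#' @export
generate_gm_maps <- function(table, truth, grid = list(dim = c(12L, 12L, 12L), voxel_mm = 3),
                             parcellation = NULL, noise_sd = 0.1,
                             smooth_fwhm_mm = 8, baseline = 0.5) {
  dims <- as.integer(grid$dim)
  parcellation <- parcellation %||% generate_parcellation(dims)
  stopifnot(all(dim(parcellation) == dims))
  n <- nrow(table)
  set.seed(derive_seed(truth$seed, "gm"))
  foci <- truth$planted_foci
  if (nrow(foci) && !all(foci$parcel %in% parcellation))
    stop("placement error: planted focus parcel not present in the grid")
  # focus voxel = center-of-mass voxel of the parcel
  focus_voxel <- function(parcel) {
    idx <- which(parcellation == parcel, arr.ind = TRUE)
    idx[which.min(rowSums(sweep(idx, 2, colMeans(idx))^2)), ]
  }
  fv <- if (nrow(foci)) t(vapply(foci$parcel, focus_voxel, numeric(3L))) else NULL
  data <- array(0, c(n, dims))
  for (s in seq_len(n)) {
    vol <- array(baseline, dims)
    if (nrow(foci)) for (k in seq_len(nrow(foci))) {
      sc <- table[[foci$parameter[k]]][s]
      if (is.na(sc)) next
      mu <- mean(table[[foci$parameter[k]]], na.rm = TRUE)
      vol[fv[k, 1L], fv[k, 2L], fv[k, 3L]] <-
        vol[fv[k, 1L], fv[k, 2L], fv[k, 3L]] + foci$beta[k] * (sc - mu)
    }
    noise <- gaussian_smooth_3d(array(stats::rnorm(prod(dims), 0, noise_sd), dims),
                                smooth_fwhm_mm, grid$voxel_mm)
    data[s, , , ] <- vol + noise
  }
  affine <- diag(c(rep(grid$voxel_mm, 3L), 1))
  affine[1:3, 4L] <- -grid$voxel_mm * (dims - 1) / 2  # world origin at volume center
  gm_stack(subjects = table$subject, data = data, voxel_mm = grid$voxel_mm,
           affine = affine, parcellation = parcellation,
           focus_voxels = if (nrow(foci)) cbind(foci, x = fv[, 1L], y = fv[, 2L], z = fv[, 3L]) else NULL)
}

#' Per-edge effect size that yields a target edge-score correlation
#'
#' The sample correlation of an edge with the score across subjects is
#' diluted by the sampling noise of the per-subject correlation estimate.
#' Bandpass filtering reduces the effective number of independent samples to
#' roughly `T * 2 * (high - low) * tr` (the retained fraction of the
#' bandwidth), so the estimate sd is `(1 - r0^2) / sqrt(T_eff - 3)`. This
#' returns the beta (per standard score unit) for which the expected
#' edge-score correlation after the standard 0.01-0.1 Hz pipeline is
#' `target_r`.
#'
#' @param target_r desired |correlation| between edge value and score.
#' @param n_timepoints samples per subject.
#' @param r0 baseline edge correlation.
#' @param band bandpass edges (Hz) the downstream pipeline will apply;
#'   `NULL` for unfiltered series.
#' @param tr_seconds sampling interval.
#' @return beta on the correlation scale per standard score unit.
#' @export
edge_effect_for_r <- function(target_r, n_timepoints = 480L, r0 = 0,
                              band = c(0.01, 0.1), tr_seconds = 1) {
  stopifnot(abs(target_r) < 1)
  frac <- if (is.null(band)) 1 else min(1, 2 * diff(band) * tr_seconds)
  t_eff <- n_timepoints * frac
  sigma <- (1 - r0^2) / sqrt(t_eff - 3)
  sigma * target_r / sqrt(1 - target_r^2)
}

# nearest positive-definite projection by eigenvalue clipping
nearest_pd <- function(mat, eps = 1e-6) {
  e <- eigen(mat, symmetric = TRUE)
  if (all(e$values > eps)) return(mat)
  v <- pmax(e$values, eps)
  m <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m))
  m / tcrossprod(d)
}

#' Generate per-subject ROI time series with planted connectivity effects
#'
#' Each subject's T x R series is multivariate normal with population
#' correlation `r0` off the diagonal, except on planted edges where it is
#' `clip(r0 + beta * zscore(score), -0.95, 0.95)`. A 24-column nuisance
#' matrix in the Friston-24 layout (6 AR(1) "motion" series, their one-sample
#' lags, and the squares of both) is emitted per subject; by default it does
#' not contaminate the series (set `confound_loading > 0` to inject it).
#'
#' @param table `psych_table` of scores.
#' @param truth `ground_truth` carrying `planted_edges`.
#' @param n_rois number of ROI columns (>= 2); defaults to `truth$n_rois`.
#' @param n_timepoints samples per subject (>= 64; default 480 at TR = 1 s).
#' @param tr_seconds repetition time.
#' @param r0 baseline off-diagonal population correlation.
#' @param confound_loading amplitude of nuisance leakage added to every ROI
#'   column (0 = clean series satisfying the correlation contract exactly).
#' @return list of class `ts_bundle`: `series` (list of T x R matrices, one
#'   per subject), `confounds` (list of T x 24 matrices), `tr`, `roi_ids`.
#' @export
generate_timeseries <- function(table, truth, n_rois = truth$n_rois,
                                n_timepoints = 480L, tr_seconds = 1,
                                r0 = 0, confound_loading = 0) {
  stopifnot(n_rois >= 2L, n_timepoints >= 64L)
  n <- nrow(table)
  set.seed(derive_seed(truth$seed, "timeseries"))
  pe <- truth$planted_edges
  zscores <- lapply(unique(pe$parameter), function(p) {
    x <- table[[p]]
    (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  })
  names(zscores) <- unique(pe$parameter)
  series <- vector("list", n)
  confounds <- vector("list", n)
  n_clipped <- 0L
  for (s in seq_len(n)) {
    R <- diag(n_rois)
    R[R == 0] <- r0
    if (nrow(pe)) for (k in seq_len(nrow(pe))) {
      z <- zscores[[pe$parameter[k]]][s]
      if (is.na(z)) z <- 0
      r <- r0 + pe$beta[k] * z
      if (abs(r) >= 1) n_clipped <- n_clipped + 1L
      r <- min(max(r, -0.95), 0.95)
      R[pe$i[k], pe$j[k]] <- R[pe$j[k], pe$i[k]] <- r
    }
    R <- nearest_pd(R)
    L <- chol(R)
    ts <- matrix(stats::rnorm(n_timepoints * n_rois), n_timepoints) %*% L
    # Friston-24-shaped nuisance block: 6 AR(1) series, lags, squares of both
    mot <- vapply(1:6, function(i) {
      as.numeric(stats::arima.sim(list(ar = 0.9), n_timepoints, sd = 0.1))
    }, numeric(n_timepoints))
    lag1 <- rbind(0, mot[-n_timepoints, , drop = FALSE])
    conf <- cbind(mot, lag1, mot^2, lag1^2)
    colnames(conf) <- c(paste0("mot", 1:6), paste0("mot", 1:6, "_lag"),
                        paste0("mot", 1:6, "_sq"), paste0("mot", 1:6, "_lagsq"))
    if (confound_loading > 0)
      ts <- ts + confound_loading * (scale(mot) %*% matrix(stats::rnorm(6 * n_rois, 0, 0.5), 6))
    series[[s]] <- ts
    confounds[[s]] <- conf
  }
  if (n_clipped > 0L)
    warning(n_clipped, " requested edge correlation(s) outside (-1,1); clipped")
  structure(list(series = series, confounds = confounds, tr = tr_seconds,
                 roi_ids = seq_len(n_rois), subjects = table$subject),
            class = "ts_bundle")
}
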