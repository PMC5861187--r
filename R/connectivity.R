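#' Regress nuisance confounds out of ROI time series
#'
#' Each ROI column is replaced by its residual on `[intercept | confounds]`.
#' Residuals are orthogonal to every confound column. The confound matrix
#' (with intercept appended) must be full column rank; offending columns are
#' named otherwise. Callers may append extra nuisance columns (e.g. a CSF
#' signal) beyond the motion set.
#'
#' @param ts T x R numeric matrix of ROI time series.
#' @param confounds T x Q nuisance matrix (Q = 24 for the Friston-24 layout).
#' @return T x R residual matrix.
#' @export
regress_confounds <- function(ts, confounds) {
  ts <- as.matrix(ts); confounds <- as.matrix(confounds)
  stopifnot(nrow(ts) == nrow(confounds))
  X <- cbind(intercept = 1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("collinear confounds: matrix is rank deficient (columns: ",
         paste(bad, collapse = ", "), ")")
  }
  qr.resid(qx, ts)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies the squared magnitude response of a 4th-order Butterworth
#' bandpass — the frequency response of a forward-backward (zero-phase)
#' pass — in the frequency domain, so inter-regional correlation structure
#' is not shifted in time. The series is mirror-extended to twice its length
#' before the FFT, which removes the wrap-around discontinuity and its
#' spectral leakage. The default 0.01-0.1 Hz band is the standard
#' resting-state BOLD fluctuation band.
#'
#' @param ts T x R matrix.
#' @param low_hz,high_hz band edges; must satisfy 0 < low < high < Nyquist.
#' @param tr_seconds sampling interval.
#' @param order filter order per band edge.
#' @return filtered T x R matrix (column means ~ 0: DC lies below the band).
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.1, tr_seconds = 1,
                            order = 4L) {
  ts <- as.matrix(ts)
  nyq <- 0.5 / tr_seconds
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf("band [%g, %g] Hz must lie strictly inside (0, %g) Hz (Nyquist)",
                 low_hz, high_hz, nyq))
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  n0 <- nrow(ts)
  xp <- rbind(ts, ts[n0:1, , drop = FALSE])        # even (mirror) extension
  n <- nrow(xp)
  w <- 2 * pi * (seq_len(n) - 1) / n               # rad/sample on the FFT grid
  ek <- exp(-1i * outer(w, seq_along(bf$b) - 1))
  H <- as.vector(ek %*% bf$b) / as.vector(ek %*% bf$a)
  gain2 <- Mod(H)^2                                # |H|^2 = forward-backward
  out <- Re(stats::mvfft(stats::mvfft(xp) * gain2, inverse = TRUE)) / n
  out[seq_len(n0), , drop = FALSE]
}

#' Pearson correlation matrix of ROI time series
#'
#' @param ts T x R matrix; every column must be non-constant.
#' @return R x R symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate series: constant ROI column(s) ",
         paste(which(sds == 0), collapse = ", "))
  m <- stats::cor(ts)
  diag(m) <- 1
  (m + t(m)) / 2
}

#' Build per-subject connectivity matrices from raw time series
#'
#' Applies the stages in the fixed order confound regression -> bandpass ->
#' correlation for every subject and stacks the resulting R x R matrices.
#'
#' @param bundle a `ts_bundle` from [generate_timeseries()] (or a compatible
#'   list with `series`, `confounds`, `tr`, `roi_ids`, `subjects`).
#' @param low_hz,high_hz bandpass edges.
#' @return a [connectivity_stack()].
#' @export
build_connectivity <- function(bundle, low_hz = 0.01, high_hz = 0.1) {
  n <- length(bundle$series)
  R <- ncol(bundle$series[[1L]])
  mats <- array(NA_real_, c(n, R, R))
  for (s in seq_len(n)) {
    x <- regress_confounds(bundle$series[[s]], bundle$confounds[[s]])
    x <- bandpass_filter(x, low_hz, high_hz, bundle$tr)
    mats[s, , ] <- correlation_matrix(x)
  }
  connectivity_stack(bundle$subjects, mats, bundle$roi_ids)
}
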