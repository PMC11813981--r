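# Resting-state denoising chain: initial-volume discard, motion QC, linear
# detrending, 0.01-0.08 Hz band-pass, nuisance regression. Every stage is a
# linear operator on each time series, so the pipeline obeys superposition;
# stage order is fixed (discard -> detrend -> filter -> regress) and
# recorded in the cleaning log attribute. Whole-brain global-signal
# regression and spatial smoothing are deliberately absent.

#' Default cleaning configuration
#'
#' @param discard Initial frames to drop (steady-state magnetisation).
#' @param low,high Band-pass limits in Hz.
#' @param motion_threshold_mm Exclusion threshold on absolute translation.
#' @return Named list of cleaning parameters.
#' @export
clean_config <- function(discard = 5L, low = 0.01, high = 0.08,
                         motion_threshold_mm = 3.0) {
  list(discard = as.integer(discard), low = low, high = high,
       motion_threshold_mm = motion_threshold_mm)
}

#' Discard initial volumes
#'
#' @param vol A [volume4d].
#' @param n Number of leading frames to drop (default 5).
#' @return A [volume4d] with `t - n` frames.
#' @export
discard_initial <- function(vol, n = 5L) {
  n <- as.integer(n)
  tdim <- dim(vol$data)[4]
  if (tdim <= n)
    stop("cannot discard ", n, " frames from a ", tdim, "-frame volume")
  if (n == 0L) return(vol)
  new_volume4d(vol$data[, , , (n + 1L):tdim, drop = FALSE], vol$affine, vol$tr)
}

#' Motion quality control
#'
#' Fails a subject when any absolute translation strictly exceeds the
#' threshold. Columns 1-3 are translations (mm), columns 4-6 rotations
#' (radians); rotations are reported but not thresholded because the
#' exclusion criterion is stated in millimetres only.
#'
#' @param motion T x 6 numeric matrix of rigid-body motion parameters.
#' @param threshold_mm Translation threshold (strict inequality; default 3).
#' @return List with `pass` (logical), `max_translation_mm`,
#'   `max_rotation` (max absolute rotation, informational).
#' @export
motion_qc <- function(motion, threshold_mm = 3.0) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion matrix must have 6 columns, got ", ncol(motion))
  max_t <- max(abs(motion[, 1:3]))
  max_r <- max(abs(motion[, 4:6]))
  list(pass = !(max_t > threshold_mm),
       max_translation_mm = max_t, max_rotation = max_r)
}

#' Read a 6-column motion-parameter file
#'
#' Whitespace-delimited text, one row per retained frame.
#' @param path File path.
#' @return T x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop("motion file must have 6 columns, got ", ncol(m), ": ", path)
  dimnames(m) <- NULL
  m
}

#' Linear detrending
#'
#' Removes the least-squares fit on an intercept plus linear term from
#' each column.
#'
#' @param ts T x K numeric matrix (time by series).
#' @return Matrix of residuals: zero mean, zero linear slope per column.
#' @export
detrend_linear <- function(ts) {
  ts <- as.matrix(ts)
  T_ <- nrow(ts)
  if (T_ < 3L) stop("detrending needs at least 3 timepoints")
  X <- cbind(1, seq_len(T_))
  ts - X %*% qr.solve(X, ts)
}

#' Zero-phase band-pass filter
#'
#' FFT realization: each series is transformed, frequency bins outside
#' `[low, high]` Hz (including DC) are zeroed, and the series is inverse
#' transformed. Exactly linear and zero-phase; pass-band amplitude
#' retention > 90% and stop-band leakage < 10% are the normative contracts.
#'
#' @param ts T x K matrix.
#' @param tr Sampling interval (repetition time), seconds.
#' @param low,high Band limits in Hz; `high` must be below Nyquist.
#' @return Filtered matrix.
#' @export
bandpass <- function(ts, tr, low = 0.01, high = 0.08) {
  ts <- as.matrix(ts)
  T_ <- nrow(ts)
  if (T_ < 3L) stop("band-pass needs at least 3 timepoints")
  nyq <- 1 / (2 * tr)
  if (high >= nyq)
    stop("high cutoff ", high, " Hz must be below Nyquist ", nyq, " Hz")
  if (low >= high) stop("low cutoff must be below high cutoff")
  freq <- (seq_len(T_) - 1) / (T_ * tr)
  freq <- pmin(freq, 1 / tr - freq)          # two-sided -> physical frequency
  keep <- freq >= low & freq <= high
  F <- stats::mvfft(ts)
  F[!keep, ] <- 0
  Re(stats::mvfft(F, inverse = TRUE)) / T_
}

#' Nuisance regression
#'
#' Projects out the confound columns (plus an always-added intercept) from
#' each series by ordinary least squares.
#'
#' @param ts T x K matrix.
#' @param confounds T x C numeric matrix (motion parameters, WM, CSF, ...).
#' @return Residual matrix, orthogonal to every confound column.
#' @export
regress_nuisance <- function(ts, confounds) {
  ts <- as.matrix(ts); confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(ts))
    stop("confound rows (", nrow(confounds), ") != timepoints (",
         nrow(ts), ")")
  X <- cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    nm <- colnames(X)[bad]
    nm[is.na(nm) | nm == ""] <- paste0("col", bad[is.na(nm) | nm == ""])
    stop("nuisance design is rank deficient; collinear column(s): ",
         paste(nm, collapse = ", "))
  }
  # normal equations: much cheaper than Householder application for the
  # typical 8-10 well-conditioned confound columns against many series
  ts - X %*% solve(crossprod(X), crossprod(X, ts))
}

#' Assemble a confound set
#'
#' @param motion T x 6 motion matrix.
#' @param wm,csf Length-T white-matter and CSF mean signals.
#' @return T x 8 confound matrix with named columns.
#' @export
confound_set <- function(motion, wm, csf) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  if (length(wm) != nrow(motion) || length(csf) != nrow(motion))
    stop("wm/csf length must match motion rows")
  cbind(tx = motion[, 1], ty = motion[, 2], tz = motion[, 3],
        rx = motion[, 4], ry = motion[, 5], rz = motion[, 6],
        wm = as.numeric(wm), csf = as.numeric(csf))
}

#' Clean a time-series matrix
#'
#' The matrix-level core of [clean_pipeline()]: detrend -> band-pass ->
#' nuisance regression (confounds detrended and band-passed the same way
#' first; zero-variance confound columns dropped). Input rows must already
#' be the retained (post-discard) frames.
#'
#' @param ts T x K matrix (time by series).
#' @param tr Repetition time, seconds.
#' @param confounds T x C matrix or `NULL`.
#' @param cfg A [clean_config()] (its `discard` is not applied here).
#' @return Cleaned T x K matrix.
#' @export
clean_timeseries <- function(ts, tr, confounds = NULL,
                             cfg = clean_config()) {
  ts <- detrend_linear(ts)
  ts <- bandpass(ts, tr, cfg$low, cfg$high)
  if (!is.null(confounds)) {
    cf <- detrend_linear(as.matrix(confounds))
    cf <- bandpass(cf, tr, cfg$low, cfg$high)
    keep <- apply(cf, 2, function(x) stats::sd(x) > 1e-12)
    if (any(keep)) ts <- regress_nuisance(ts, cf[, keep, drop = FALSE])
  }
  ts
}

#' Full cleaning pipeline for one subject
#'
#' Applies discard -> detrend -> band-pass -> nuisance regression, in that
#' fixed order. Confounds are passed through the same band-pass before
#' regression so that regressing them cannot reintroduce out-of-band
#' variance. Confound rows must correspond to the retained (post-discard)
#' frames. No global-signal regression, no spatial smoothing.
#'
#' @param vol A [volume4d].
#' @param confounds T' x C confound matrix (see [confound_set()]), where
#'   T' = `t - cfg$discard`, or `NULL` to skip regression.
#' @param cfg A [clean_config()].
#' @param mask Optional [label_volume]; when given, only in-mask voxels are
#'   cleaned (out-of-mask voxels are zeroed), which is substantially faster
#'   for mask-restricted analyses.
#' @return A cleaned [volume4d] with a `clean_log` attribute recording the
#'   stage order and parameters in effect.
#' @export
clean_pipeline <- function(vol, confounds = NULL, cfg = clean_config(),
                           mask = NULL) {
  vol <- discard_initial(vol, cfg$discard)
  d <- dim(vol$data)
  T_ <- d[4]
  if (!is.null(confounds) && nrow(as.matrix(confounds)) != T_)
    stop("confound rows must equal post-discard timepoints (", T_, ")")
  if (is.null(mask)) {
    ts <- t(matrix(vol$data, nrow = prod(d[1:3]), ncol = T_))
    idx <- seq_len(prod(d[1:3]))
  } else {
    assert_same_grid(vol, mask)
    idx <- which(mask$data > 0L)
    ts <- t(matrix(vol$data, nrow = prod(d[1:3]), ncol = T_)[idx, ,
                                                             drop = FALSE])
  }
  ts <- clean_timeseries(ts, vol$tr, confounds, cfg)
  out <- matrix(0, nrow = prod(d[1:3]), ncol = T_)
  out[idx, ] <- t(ts)
  res <- new_volume4d(array(out, dim = d), vol$affine, vol$tr)
  attr(res, "clean_log") <- list(
    order = c("discard", "detrend", "bandpass", "regress"),
    discard = cfg$discard, band = c(cfg$low, cfg$high),
    confounds_bandpassed = !is.null(confounds),
    global_signal_regression = FALSE, spatial_smoothing = FALSE)
  res
}
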