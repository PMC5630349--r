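# Time-series-level preprocessing: framewise displacement, volume
# dropping, detrending, ideal bandpass filtering, nuisance regression
# and motion scrubbing.

#' Framewise displacement from rigid-body motion parameters
#'
#' For each frame t, sums the absolute frame-to-frame changes of the six
#' rigid-body parameters, converting each rotation difference from
#' degrees to millimetres as arc length on a sphere of radius `radius`
#' (|d degrees| * pi/180 * r). The first frame has no predecessor and
#' its displacement is defined as 0.
#'
#' @param motion numeric matrix with frames in rows and six columns:
#'   three translations (mm) then three rotations (degrees).
#' @param radius head-radius approximation in mm used for the
#'   rotation-to-translation conversion (default 50, roughly the mean
#'   cortical distance from the centre of MNI space).
#' @return Numeric vector of per-frame displacements in mm.
#' @export
#' @examples
#' m <- matrix(0, 10, 6); m[4:10, 1] <- 0.1
#' framewise_displacement(m)  # 0.1 at frame 4, zero elsewhere
framewise_displacement <- function(motion, radius = 50) {
  if (!is.matrix(motion) || ncol(motion) != 6)
    stop_input("motion must be a matrix with 6 columns (3 translations mm, 3 rotations degrees)")
  if (nrow(motion) < 2)
    stop_input("motion must have at least 2 frames")
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * (pi / 180) * radius
  c(0, rowSums(d))
}

#' Root-mean-square successive variance (QC statistic)
#'
#' DVARS-like quality-control statistic: the root mean square over ROIs
#' of the frame-to-frame signal difference. Reported for inspection
#' only; no exclusion rule is attached to it.
#'
#' @param ts an [roi_ts].
#' @return Numeric vector (length = frames, first element 0).
#' @export
rms_successive_variance <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  d <- diff(t(ts$signal))
  c(0, sqrt(rowMeans(d^2)))
}

#' Drop initial acquisition volumes
#'
#' Removes the first `n_drop` frames (magnetisation-equilibrium
#' volumes) from a regional time series.
#'
#' @param ts an [roi_ts].
#' @param n_drop number of leading frames to remove (< frame count).
#' @return The shortened [roi_ts]; the retained-frame mask records the
#'   dropped frames.
#' @export
drop_initial_volumes <- function(ts, n_drop) {
  stopifnot(inherits(ts, "roi_ts"))
  if (!is_count(n_drop) || n_drop < 0)
    stop_input("n_drop must be a non-negative integer")
  n <- ncol(ts$signal)
  if (n_drop >= n)
    stop_input(sprintf("cannot drop %d of %d frames: no data would remain", n_drop, n))
  if (n_drop == 0) return(ts)
  keep_cols <- (n_drop + 1):n
  mask <- ts$mask
  mask[which(mask)[seq_len(n_drop)]] <- FALSE
  replace_signal(ts, ts$signal[, keep_cols, drop = FALSE], mask)
}

#' Remove the linear trend from each region
#'
#' Per ROI, subtracts the least-squares line over frame index, removing
#' slow scanner drift. The output has zero best-fit slope and intercept
#' to numerical precision.
#'
#' @param ts an [roi_ts] with at least 3 frames.
#' @return Detrended [roi_ts].
#' @export
detrend_linear <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  n <- ncol(ts$signal)
  if (n < 3) stop_input("detrending needs at least 3 frames")
  x <- cbind(1, seq_len(n))
  # residuals of each ROI (row) regressed on [1 | t]
  fit <- t(stats::lm.fit(x, t(ts$signal))$residuals)
  replace_signal(ts, fit)
}

#' Ideal (rectangular) bandpass filter
#'
#' Frequency-domain filter retaining the discrete-Fourier bins whose
#' frequency lies in `[low_hz, high_hz]` and zeroing all others
#' (including DC when `low_hz > 0`), then inverse-transforming. The
#' default band 0.01-0.10 Hz isolates the resting-state fluctuation
#' range, suppressing scanner drift below and physiological noise
#' above.
#'
#' @param ts an [roi_ts].
#' @param low_hz,high_hz band edges in Hz; `high_hz` must not exceed
#'   the Nyquist frequency `1 / (2 * tr)`.
#' @return Filtered [roi_ts].
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.10) {
  stopifnot(inherits(ts, "roi_ts"))
  nyquist <- 1 / (2 * ts$tr)
  if (high_hz > nyquist)
    stop_input(sprintf("high_hz = %g exceeds the Nyquist frequency %g Hz for TR = %g s",
                       high_hz, nyquist, ts$tr))
  if (low_hz >= high_hz) stop_input("low_hz must be below high_hz")
  n <- ncol(ts$signal)
  freq <- pmin(0:(n - 1), n - (0:(n - 1))) / (n * ts$tr)
  keep <- freq >= low_hz & freq <= high_hz
  filt <- t(apply(ts$signal, 1, function(row) {
    f <- stats::fft(row)
    f[!keep] <- 0
    Re(stats::fft(f, inverse = TRUE)) / n
  }))
  replace_signal(ts, filt)
}

#' Regress nuisance signals out of every region
#'
#' Ordinary least-squares residualisation of each ROI's series against
#' an intercept plus the supplied regressor columns (head-motion
#' parameters, white-matter and cerebrospinal-fluid signals, or any
#' component regressors computed upstream). Residuals are orthogonal to
#' every regressor.
#'
#' @param ts an [roi_ts].
#' @param regressors numeric matrix, frames in rows, one column per
#'   nuisance signal.
#' @return Residualised [roi_ts].
#' @export
regress_nuisance <- function(ts, regressors) {
  stopifnot(inherits(ts, "roi_ts"))
  regressors <- as.matrix(regressors)
  n <- ncol(ts$signal)
  if (nrow(regressors) != n)
    stop_input(sprintf("regressors have %d rows but the series has %d frames",
                       nrow(regressors), n))
  x <- cbind(intercept = 1, regressors)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop_input("nuisance design is rank deficient; collinear columns: ",
               paste(dropped, collapse = ", "))
  }
  res <- t(qr.resid(qrx, t(ts$signal)))
  replace_signal(ts, res)
}

#' Scrub motion-contaminated frames
#'
#' Deletes frames whose framewise displacement exceeds
#' `threshold_mm` from the signal matrix outright (no interpolation),
#' preserving the order of surviving frames and updating the
#' retained-frame mask.
#'
#' @param ts an [roi_ts].
#' @param fd framewise-displacement vector aligned with the current
#'   frames of `ts`.
#' @param threshold_mm scrubbing threshold in mm (default 0.3).
#' @return Scrubbed [roi_ts] with attribute `n_scrubbed`.
#' @export
scrub_frames <- function(ts, fd, threshold_mm = 0.3) {
  stopifnot(inherits(ts, "roi_ts"))
  n <- ncol(ts$signal)
  if (length(fd) != n)
    stop_input(sprintf("fd has length %d but the series has %d frames",
                       length(fd), n))
  bad <- which(fd > threshold_mm)
  if (length(bad) == n)
    stop_input(sprintf("subject '%s': all %d frames exceed the %g mm threshold",
                       ts$id, n, threshold_mm))
  if (length(bad) == 0) {
    attr(ts, "n_scrubbed") <- 0L
    return(ts)
  }
  mask <- ts$mask
  mask[which(mask)[bad]] <- FALSE
  out <- replace_signal(ts, ts$signal[, -bad, drop = FALSE], mask)
  attr(out, "n_scrubbed") <- length(bad)
  out
}

#' Full time-series preprocessing for one subject
#'
#' Applies the fixed pipeline order: drop initial volumes, detrend,
#' bandpass, nuisance regression, then scrubbing. Framewise
#' displacement is computed from the raw motion trace before any signal
#' step, and the motion parameters (aligned to the retained frames) are
#' included as nuisance regressors alongside any extra columns
#' supplied. Filtering runs on the full uniform frame grid before any
#' frame deletion so that spectra are well defined; scrubbing follows.
#'
#' @param ts an [roi_ts] covering the full acquisition.
#' @param motion raw motion-parameter matrix over the full acquisition
#'   (frames x 6), or `NULL` to skip motion-based steps.
#' @param extra_regressors optional matrix of additional nuisance
#'   columns over the full acquisition (e.g. white-matter / CSF /
#'   component signals).
#' @param n_drop initial volumes to discard (default 3).
#' @param low_hz,high_hz bandpass edges (defaults 0.01 and 0.10 Hz).
#' @param fd_threshold scrubbing threshold in mm (default 0.3; set to
#'   `Inf` to disable).
#' @param radius rotation-conversion radius in mm.
#' @return Preprocessed [roi_ts] with a `qc` attribute: list with
#'   `mean_fd` (over the post-drop frames), `n_scrubbed`, and
#'   `n_frames`.
#' @export
preprocess_subject <- function(ts, motion = NULL, extra_regressors = NULL,
                               n_drop = 3, low_hz = 0.01, high_hz = 0.10,
                               fd_threshold = 0.3, radius = 50) {
  stopifnot(inherits(ts, "roi_ts"))
  n_full <- ncol(ts$signal)
  fd <- NULL
  if (!is.null(motion)) {
    if (nrow(motion) != n_full)
      stop_input("motion trace and time series must cover the same frames")
    fd <- framewise_displacement(motion, radius = radius)
  }
  keep <- if (n_drop > 0) (n_drop + 1):n_full else seq_len(n_full)
  out <- drop_initial_volumes(ts, n_drop)
  out <- detrend_linear(out)
  out <- bandpass_filter(out, low_hz, high_hz)
  reg <- NULL
  if (!is.null(motion)) reg <- motion[keep, , drop = FALSE]
  if (!is.null(extra_regressors)) {
    extra <- as.matrix(extra_regressors)
    if (nrow(extra) != n_full)
      stop_input("extra_regressors must cover the full acquisition")
    reg <- cbind(reg, extra[keep, , drop = FALSE])
  }
  if (!is.null(reg)) out <- regress_nuisance(out, reg)
  n_scrubbed <- 0L
  mean_fd <- NA_real_
  if (!is.null(fd)) {
    fd_kept <- fd[keep]
    mean_fd <- mean(fd_kept)
    out <- scrub_frames(out, fd_kept, fd_threshold)
    n_scrubbed <- attr(out, "n_scrubbed")
  }
  attr(out, "qc") <- list(mean_fd = mean_fd, n_scrubbed = n_scrubbed,
                          n_frames = ncol(out$signal))
  out
}
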