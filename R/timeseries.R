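# Regional time-series container used by every preprocessing and
# network-construction step.

#' Construct a regional time-series object
#'
#' Bundles an ROI-by-time signal matrix with its sampling interval,
#' region labels, retained-frame mask and subject id. All preprocessing
#' operations accept and return this class.
#'
#' @param signal numeric matrix, regions in rows, time frames in columns.
#' @param tr sampling interval (repetition time) in seconds.
#' @param labels character vector of region labels; defaults to
#'   `ROI1..ROIn`.
#' @param mask logical vector over the *original* acquisition frames
#'   marking which are still present; defaults to all `TRUE`.
#' @param id subject identifier string.
#' @return An object of class `roi_ts`.
#' @export
#' @examples
#' ts <- roi_ts(matrix(rnorm(20), 2, 10), tr = 3)
#' ts
roi_ts <- function(signal, tr, labels = NULL, mask = NULL, id = "subject") {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop_input("signal must be a numeric matrix (ROIs x frames)")
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0)
    stop_input("tr must be a positive duration in seconds")
  n_roi <- nrow(signal)
  if (is.null(labels)) labels <- paste0("ROI", seq_len(n_roi))
  if (length(labels) != n_roi)
    stop_input("labels length must equal the number of ROIs")
  if (is.null(mask)) mask <- rep(TRUE, ncol(signal))
  if (sum(mask) != ncol(signal))
    stop_input("mask must retain exactly ncol(signal) frames")
  structure(
    list(signal = signal, tr = tr, labels = labels, mask = mask, id = id),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf(
    "Regional time series '%s': %d ROIs x %d frames (TR = %g s, %d of %d frames retained)\n",
    x$id, nrow(x$signal), ncol(x$signal), x$tr, sum(x$mask), length(x$mask)
  ))
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$signal)

# Replace the signal matrix, keeping metadata consistent.
replace_signal <- function(ts, signal, mask = ts$mask) {
  ts$signal <- signal
  ts$mask <- mask
  ts
}
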