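#' Multichannel continuous raw recording
#'
#' @param samples channels x time numeric matrix (uV).
#' @param rate sampling rate, Hz.
#' @param channel_names optional channel labels.
#' @param excluded_channels character vector of channels excluded from
#'   referencing and analysis (manual-inspection surrogate).
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(samples, rate, channel_names = NULL,
                          excluded_channels = character(0)) {
  samples <- as.matrix(samples)
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(samples)))
  rownames(samples) <- channel_names
  if (!all(is.finite(samples)))
    stop_hfb("hfbdeconv_invalid_input", "raw samples must be finite")
  structure(list(samples = samples, rate = rate,
                 channel_names = channel_names,
                 excluded_channels = excluded_channels),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  if (length(x$excluded_channels))
    cat("  excluded:", paste(x$excluded_channels, collapse = ", "), "\n")
  invisible(x)
}

#' Per-channel high-frequency broadband envelope timecourse
#'
#' Values are in percent signal change once baseline-normalized (see
#' [baseline_normalize()]); before that they are unit-mean envelopes.
#'
#' @param values channels x time numeric matrix.
#' @param rate sampling rate, Hz (250 in the standard pipeline).
#' @param channel_names optional labels.
#' @param rejection_mask logical vector (length = time) marking outlier
#'   timepoints; defaults to all FALSE.
#' @param baseline_intervals matrix with columns start, end (seconds).
#' @return an object of class `hfb_timecourse`.
#' @export
hfb_timecourse <- function(values, rate, channel_names = NULL,
                           rejection_mask = NULL,
                           baseline_intervals = NULL) {
  values <- as.matrix(values)
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(values)))
  rownames(values) <- channel_names
  if (is.null(rejection_mask)) rejection_mask <- logical(ncol(values))
  if (length(rejection_mask) != ncol(values))
    stop_hfb("hfbdeconv_invalid_input",
             "rejection mask length must equal the number of timepoints")
  structure(list(values = values, rate = rate,
                 channel_names = channel_names,
                 rejection_mask = rejection_mask,
                 baseline_intervals = baseline_intervals),
            class = "hfb_timecourse")
}

#' @export
print.hfb_timecourse <- function(x, ...) {
  cat(sprintf("<hfb_timecourse> %d channels x %d samples @ %g Hz, %d masked\n",
              nrow(x$values), ncol(x$values), x$rate, sum(x$rejection_mask)))
  invisible(x)
}
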