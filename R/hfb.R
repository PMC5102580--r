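# Preprocessing: common-average reference, eight-band Hilbert envelope,
# outlier scan, percent-signal-change normalisation.

#' Re-reference a recording to the common average
#'
#' Subtracts, at every sample, the mean over all non-excluded channels from
#' each channel. Recomputable after channel exclusion.
#'
#' @param rec a [raw_recording()].
#' @return the re-referenced `raw_recording`.
#' @export
common_average_reference <- function(rec) {
  keep <- !(rec$channel_names %in% rec$excluded_channels)
  if (sum(keep) < 2)
    stop_hfb("hfbdeconv_insufficient_channels",
             "common average needs at least 2 non-excluded channels")
  avg <- colMeans(rec$samples[keep, , drop = FALSE])
  rec$samples <- sweep(rec$samples, 2L, avg)
  rec
}

# analytic signal via FFT; magnitude gives the instantaneous amplitude
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# zero-phase FIR band-pass; default order gives a transition band
# comparable to the (narrow) pass-band width, so adjacent 10 Hz bands are
# well separated
bandpass_envelope <- function(x, rate, band, order = NULL) {
  if (is.null(order))
    order <- 2L * as.integer(round(1.5 * rate / (band[2] - band[1])))
  if (length(x) < 3 * (order + 1))
    stop_hfb("hfbdeconv_too_short",
             "record shorter than filter warm-up (order %d)", order)
  b <- signal::fir1(order, band / (rate / 2), type = "pass")
  Mod(analytic_signal(signal::filtfilt(b, x)))
}

#' Extract the high-frequency broadband envelope
#'
#' Splits each channel into eight contiguous 10 Hz bands tiling
#' `band_range` (default 70-150 Hz), takes the magnitude of the analytic
#' signal in each band, divides each band envelope by its own temporal mean
#' (equal weighting across the 1/f amplitude spectrum), averages the eight
#' normalized envelopes, and downsamples the result to `rate_out`. The
#' output has temporal mean ~1 per channel prior to baseline normalisation.
#'
#' @param rec a [raw_recording()]; expected notch-filtered and at 500 Hz
#'   (512 Hz inputs are resampled first).
#' @param band_range c(low, high) Hz of the broadband range.
#' @param n_bands number of sub-bands (default 8).
#' @param rate_out output rate, Hz (default 250).
#' @param filter_order optional FIR order override.
#' @return an `hfb_timecourse` (not yet baseline-normalized).
#' @export
extract_hfb <- function(rec, band_range = c(70, 150), n_bands = 8L,
                        rate_out = 250, filter_order = NULL) {
  rate <- rec$rate
  if (!rate %in% c(500, 512))
    stop_hfb("hfbdeconv_invalid_input", "input rate must be 500 or 512 Hz")
  if (rate == 512) {
    rec <- resample_recording(rec, 500)
    rate <- 500
  }
  edges <- seq(band_range[1], band_range[2], length.out = n_bands + 1L)
  keep <- !(rec$channel_names %in% rec$excluded_channels)
  chans <- which(keep)
  dec <- rate / rate_out
  if (abs(dec - round(dec)) > 1e-9)
    stop_hfb("hfbdeconv_invalid_input", "output rate must divide input rate")
  dec <- as.integer(round(dec))
  n_out <- ceiling(ncol(rec$samples) / dec)
  out <- matrix(0, nrow = length(chans), ncol = n_out)
  for (i in seq_along(chans)) {
    x <- rec$samples[chans[i], ]
    env <- 0
    for (b in seq_len(n_bands)) {
      e <- bandpass_envelope(x, rate, c(edges[b], edges[b + 1L]), filter_order)
      env <- env + e / mean(e)
    }
    env <- env / n_bands
    out[i, ] <- decimate_env(env, dec)
  }
  hfb_timecourse(out, rate_out, channel_names = rec$channel_names[chans])
}

# anti-alias low-pass (zero-phase FIR) then keep every dec-th sample
decimate_env <- function(x, dec) {
  if (dec == 1L) return(x)
  b <- signal::fir1(64, 0.8 / dec)
  y <- signal::filtfilt(b, x)
  y[seq(1L, length(y), by = dec)]
}

# naive linear resampling for 512 -> 500 Hz inputs
resample_recording <- function(rec, rate_out) {
  n_in <- ncol(rec$samples)
  t_in <- (seq_len(n_in) - 1L) / rec$rate
  t_out <- seq(0, t_in[n_in], by = 1 / rate_out)
  samples <- t(apply(rec$samples, 1L, function(x)
    approx(t_in, x, xout = t_out)$y))
  raw_recording(samples, rate_out, rec$channel_names, rec$excluded_channels)
}

#' Scan an HFB timecourse for widespread outliers
#'
#' Per channel, the discrete-time first difference is z-normalized (global
#' mean/SD, ignoring any previously masked points) and its absolute value
#' taken. Timepoints at which the across-channel median of these absolute
#' z-scores exceeds `threshold` (default 2) are marked for rejection, along
#' with all timepoints within `dilate_ms` (default 200 ms) of them.
#'
#' @param hfb an `hfb_timecourse`.
#' @param threshold median |z| threshold.
#' @param dilate_ms rejection dilation, ms.
#' @return the `hfb_timecourse` with an updated `rejection_mask`.
#' @export
reject_outliers <- function(hfb, threshold = 2, dilate_ms = 200) {
  v <- hfb$values
  if (nrow(v) < 2)
    warning("single-channel input: across-channel median equals the channel itself")
  prev <- hfb$rejection_mask
  dz <- matrix(0, nrow = nrow(v), ncol = ncol(v))
  for (i in seq_len(nrow(v))) {
    d <- c(0, diff(v[i, ]))
    use <- !prev
    s <- sd(d[use])
    if (s == 0) s <- 1
    dz[i, ] <- abs((d - mean(d[use])) / s)
  }
  med <- apply(dz, 2L, median)
  bad <- med > threshold
  if (any(bad)) {
    w <- as.integer(round(dilate_ms / 1000 * hfb$rate))
    idx <- which(bad)
    for (i in idx) bad[max(1L, i - w):min(length(bad), i + w)] <- TRUE
  }
  hfb$rejection_mask <- prev | bad
  hfb
}

#' Normalize an HFB timecourse to percent signal change
#'
#' Divides each channel by its mean activation over the baseline intervals
#' (masked timepoints excluded) and transforms to percent change:
#' `100 * (x / baseline_mean - 1)`, so the baseline mean maps to 0%.
#'
#' @param hfb an `hfb_timecourse`.
#' @param intervals baseline intervals (matrix with columns start, end, in
#'   seconds); defaults to `hfb$baseline_intervals`.
#' @return the normalized `hfb_timecourse`.
#' @export
baseline_normalize <- function(hfb, intervals = NULL) {
  if (is.null(intervals)) intervals <- hfb$baseline_intervals
  if (is.null(intervals) || nrow(intervals) == 0)
    stop_hfb("hfbdeconv_no_baseline", "no baseline intervals supplied")
  idx <- intervals_to_index(intervals, ncol(hfb$values), hfb$rate)
  idx <- idx & !hfb$rejection_mask
  if (!any(idx))
    stop_hfb("hfbdeconv_no_baseline",
             "all baseline timepoints are masked")
  for (i in seq_len(nrow(hfb$values))) {
    b <- mean(hfb$values[i, idx])
    if (b <= 0)
      stop_hfb("hfbdeconv_no_baseline", "non-positive baseline mean")
    hfb$values[i, ] <- 100 * (hfb$values[i, ] / b - 1)
  }
  hfb$baseline_intervals <- intervals
  hfb
}
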