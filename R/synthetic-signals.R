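# HFB-level and raw-level session synthesis ----------------------------------

# event onset -> 1-based sample index; the single rounding rule shared by the
# generator and the design-matrix builder, so noiseless recovery is exact
event_sample <- function(onset_s, rate) as.integer(round(onset_s * rate)) + 1L

add_kernel_at <- function(y, kernel, onset_s, rate) {
  if (kernel$rate != rate)
    stop_hfb("hfbdeconv_invalid_config", "kernel rate mismatch")
  i0 <- event_sample(onset_s, rate) +
    as.integer(round(kernel$window_ms[1] * rate / 1000))
  idx <- i0:(i0 + length(kernel$values) - 1L)
  ok <- idx >= 1L & idx <= length(y)
  y[idx[ok]] <- y[idx[ok]] + kernel$values[ok]
  y
}

#' Stationary AR(1) noise with a given marginal standard deviation
#' @param n length.
#' @param ar lag-1 coefficient.
#' @param sd marginal standard deviation.
#' @return numeric vector.
#' @export
ar1_noise <- function(n, ar = 0.9, sd = 1) {
  if (abs(ar) >= 1) stop_hfb("hfbdeconv_invalid_config", "|ar| must be < 1")
  e <- rnorm(n, 0, sd * sqrt(1 - ar^2))
  as.numeric(stats::filter(e, ar, method = "recursive",
                           init = rnorm(1, 0, sd)))
}

#' 1/f^alpha ("pink") noise via spectral shaping
#' @param n length.
#' @param exponent spectral exponent alpha (power ~ 1/f^alpha).
#' @param sd marginal standard deviation.
#' @return numeric vector.
#' @export
pink_noise <- function(n, exponent = 1, sd = 1) {
  nf <- n %/% 2L
  f <- seq_len(nf)
  amp <- f^(-exponent / 2)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(length.out = n)
  full[2:(nf + 1L)] <- spec
  full[n:(n - nf + 2L)] <- Conj(spec[1:(nf - 1L)])
  x <- Re(fft(full, inverse = TRUE))
  x <- x - mean(x)
  x / sd(x) * sd
}

noise_draw <- function(n, model) {
  if (is.null(model) || model$sd == 0) return(numeric(n))
  switch(model$kind,
    ar1 = ar1_noise(n, model$ar, model$sd),
    pink = pink_noise(n, model$exponent, model$sd),
    stop_hfb("hfbdeconv_invalid_config", "unknown noise model '%s'", model$kind)
  )
}

#' Generate an HFB-level synthetic session
#'
#' Builds per-electrode HFB timecourses as the exact linear superposition of
#' ground-truth kernels at the scheduled event times: stimulus kernels at
#' stimulus onsets (by category; animal trials use the nonface kernel),
#' disappearance kernels at gap/blink onsets and reappearance kernels at
#' gap/blink offsets, plus optional noise. Exact linearity in the noiseless
#' case makes deconvolution recovery testable to numerical precision.
#'
#' @param config a [sim_config()].
#' @param truth a [ground_truth()] whose kernels live on `config$rate_hfb`.
#' @param schedule optional precomputed [generate_schedule()] output.
#' @return an `hfb_timecourse` (see [hfb_timecourse()]) with the events as
#'   attribute `events` and the truth as attribute `truth`.
#' @export
generate_hfb_session <- function(config, truth, schedule = NULL) {
  if (is.null(schedule)) schedule <- generate_schedule(config)
  rate <- config$rate_hfb
  n <- as.integer(round(attr(schedule, "duration_s") * rate))
  set.seed(derive_seed(config$seed, 2L))
  stim <- schedule[schedule$kind == "stimulus", ]
  intr <- schedule[schedule$kind %in% c("gap", "blink"), ]
  itype <- ifelse(intr$kind == "gap", "gap", intr$subtype)

  values <- matrix(0, nrow = nrow(truth$electrodes), ncol = n)
  for (e in seq_len(nrow(truth$electrodes))) {
    k <- truth$kernels[[e]]
    y <- numeric(n)
    for (r in seq_len(nrow(stim))) {
      cat_k <- if (stim$category[r] == "face") k$stimulus$face else k$stimulus$nonface
      y <- add_kernel_at(y, cat_k, stim$onset_s[r], rate)
    }
    if (nrow(intr) > 0) for (r in seq_len(nrow(intr))) {
      y <- add_kernel_at(y, k$disappearance[[itype[r]]], intr$onset_s[r], rate)
      y <- add_kernel_at(y, k$reappearance[[itype[r]]], intr$offset_s[r], rate)
    }
    values[e, ] <- y + noise_draw(n, config$noise)
  }
  out <- hfb_timecourse(values, rate,
                        channel_names = truth$electrodes$electrode,
                        baseline_intervals = attr(schedule, "baseline_intervals"))
  attr(out, "events") <- schedule
  attr(out, "truth") <- truth
  out
}

#' Synthesize one raw channel: 1/f background plus an amplitude-modulated
#' band-limited carrier
#'
#' The carrier is white noise band-passed to `carrier_band` whose
#' instantaneous amplitude follows `1 + depth * modulator`; the extracted
#' high-frequency broadband envelope of the channel should therefore track
#' the modulator.
#'
#' @param n number of samples.
#' @param rate sampling rate, Hz.
#' @param modulator numeric vector of length `n` (zero-mean, scaled so that
#'   `1 + depth * modulator > 0`), or NULL for constant amplitude.
#' @param depth modulation depth.
#' @param carrier_band c(low, high) Hz.
#' @param carrier_amp carrier RMS amplitude (uV).
#' @param background_sd 1/f background SD (uV), 0 to disable.
#' @param carrier_type "multisine" (deterministic sum of sinusoids tiling
#'   the band; stable instantaneous envelope, so the extracted HFB tracks
#'   the modulator closely) or "noise" (band-passed white noise; stochastic
#'   envelope, closer to a real field potential).
#' @param n_components sinusoids in the multisine carrier.
#' @return numeric vector of length `n`.
#' @export
synth_raw_channel <- function(n, rate, modulator = NULL, depth = 0.5,
                              carrier_band = c(70, 150), carrier_amp = 10,
                              background_sd = 5,
                              carrier_type = c("multisine", "noise"),
                              n_components = 8L) {
  carrier_type <- match.arg(carrier_type)
  if (carrier_type == "multisine") {
    half_bw <- diff(carrier_band) / n_components / 2
    freqs <- seq(carrier_band[1] + half_bw, carrier_band[2] - half_bw,
                 length.out = n_components)
    tt <- (seq_len(n) - 1L) / rate
    ph <- runif(n_components, 0, 2 * pi)
    carrier <- rowSums(vapply(seq_len(n_components), function(k)
      sin(2 * pi * freqs[k] * tt + ph[k]), numeric(n)))
  } else {
    ord <- 2L * as.integer(round(rate / carrier_band[1] * 3))
    bp <- signal::fir1(ord, carrier_band / (rate / 2), type = "pass")
    carrier <- signal::filtfilt(bp, rnorm(n))
  }
  carrier <- carrier / sd(carrier) * carrier_amp
  am <- if (is.null(modulator)) 1 else 1 + depth * modulator
  bg <- if (background_sd > 0) pink_noise(n, 1, background_sd) else 0
  carrier * am + bg
}

#' Generate a raw-level synthetic session
#'
#' For each electrode, renders the ground-truth HFB profile (kernel
#' superposition, as in [generate_hfb_session()] but on the raw grid) as the
#' amplitude modulation of a 70-150 Hz carrier riding on 1/f background
#' noise, sampled at `config$rate_raw`.
#'
#' @inheritParams generate_hfb_session
#' @param depth modulation depth applied to the normalized HFB profile.
#' @param background_sd 1/f background SD (uV).
#' @return a `raw_recording` (see [raw_recording()]), events in attribute
#'   `events`.
#' @export
generate_raw_session <- function(config, truth, schedule = NULL,
                                 depth = 0.5, background_sd = 5) {
  if (is.null(schedule)) schedule <- generate_schedule(config)
  rate <- config$rate_raw
  cfg_raw <- config
  cfg_raw$rate_hfb <- rate
  cfg_raw$noise <- NULL
  # noiseless kernel superposition on the raw grid as modulation profile
  truth_raw <- truth
  truth_raw$kernels <- lapply(truth$kernels, function(k)
    lapply(k, function(set) lapply(set, resample_kernel, rate = rate)))
  profile <- generate_hfb_session(cfg_raw, truth_raw, schedule)
  set.seed(derive_seed(config$seed, 3L))
  n <- ncol(profile$values)
  samples <- matrix(0, nrow = nrow(profile$values), ncol = n)
  for (e in seq_len(nrow(samples))) {
    m <- profile$values[e, ]
    span <- max(abs(m), 1e-12)
    samples[e, ] <- synth_raw_channel(n, rate, modulator = m / span,
                                      depth = depth,
                                      background_sd = background_sd)
  }
  out <- raw_recording(samples, rate, channel_names = truth$electrodes$electrode)
  attr(out, "events") <- schedule
  attr(out, "truth") <- truth
  out
}

# linear interpolation of a kernel onto another grid
resample_kernel <- function(k, rate) {
  if (k$rate == rate) return(k)
  lags <- kernel_lags_ms(k)
  new_lags <- seq(k$window_ms[1], k$window_ms[2] - 1000 / rate,
                  by = 1000 / rate)
  v <- approx(lags, k$values, xout = new_lags, rule = 2)$y
  hfb_kernel(v, k$window_ms, rate)
}
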