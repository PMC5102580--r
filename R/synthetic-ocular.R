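# Synthetic pupil-size and EOG traces with blink artifacts --------------------

logistic <- function(t, m, tau) 1 / (1 + exp(-(t - m) / tau))

#' Generate synthetic pupil and EOG channels for a schedule
#'
#' The pupil trace sits at `pupil_base` with slow drift; around each blink
#' it descends through a logistic closing ramp (inflection at the scheduled
#' blink onset), is lost (NA) while the eyelid covers the pupil, and
#' reopens through a mirror-image ramp at the scheduled offset. The EOG
#' trace is a slow polynomial drift plus, per blink, a trapezoid artifact
#' whose half-height width equals the blink duration, plus white noise.
#'
#' For every blink the analytically known peak-|curvature| times of the
#' measured (pre-loss / post-reacquisition) pupil segments are stored as
#' ground truth for timing-recovery tests: the logistic second derivative
#' peaks 1.317 time constants before/after the inflection.
#'
#' @param config a [sim_config()] (only `seed` and rates are used).
#' @param schedule an event table containing blink events.
#' @param rate sampling rate, Hz (default `config$rate_raw`).
#' @param pupil_base nominal pupil size (arbitrary units).
#' @param ramp_tau_ms logistic time constant of eyelid ramps, ms.
#' @param loss_fraction pupil fraction below which tracking is lost.
#' @param eog_height blink artifact height, uV.
#' @param eog_rise_ms,eog_fall_ms trapezoid ramp durations, ms.
#' @param eog_noise_sd EOG white-noise SD, uV.
#' @return list with `pupil`, `eog` (numeric vectors), `rate`, and
#'   `blink_truth` (data.frame: scheduled onset/offset, true measurable
#'   onset/offset, loss interval).
#' @export
generate_ocular_channels <- function(config, schedule,
                                     rate = config$rate_raw,
                                     pupil_base = 1000,
                                     ramp_tau_ms = 15,
                                     loss_fraction = 0.4,
                                     eog_height = 100,
                                     eog_rise_ms = 40, eog_fall_ms = 40,
                                     eog_noise_sd = 2) {
  set.seed(derive_seed(config$seed, 4L))
  dur <- attr(schedule, "duration_s")
  if (is.null(dur)) dur <- max(schedule$offset_s) + 1
  n <- as.integer(round(dur * rate))
  t <- (seq_len(n) - 1L) / rate
  tau <- ramp_tau_ms / 1000

  blinks <- schedule[schedule$kind == "blink", , drop = FALSE]
  occl <- rep(1, n)
  if (nrow(blinks) > 0) {
    for (r in seq_len(nrow(blinks))) {
      on <- blinks$onset_s[r]; off <- blinks$offset_s[r]
      win <- t >= on - 8 * tau & t <= off + 8 * tau
      f <- 1 - logistic(t[win], on, tau) * logistic(-(t[win] - off), 0, tau)
      occl[win] <- pmin(occl[win], f)
    }
  }
  drift <- 1 + 0.02 * sin(2 * pi * t / 60)
  pupil <- pupil_base * drift * occl
  pupil[occl < loss_fraction] <- NA_real_

  # EOG: degree-5 polynomial drift over the session + trapezoids + noise
  tc <- (t - mean(t)) / (max(t) / 2)
  pc <- rnorm(6, 0, c(5, 5, 3, 3, 2, 2))
  eog <- as.numeric(cbind(1, tc, tc^2, tc^3, tc^4, tc^5) %*% pc)
  if (nrow(blinks) > 0) {
    for (r in seq_len(nrow(blinks))) {
      eog <- eog + trapezoid_wave(t, blinks$onset_s[r], blinks$offset_s[r],
                                  eog_rise_ms / 1000, eog_fall_ms / 1000,
                                  eog_height)
    }
  }
  eog <- eog + rnorm(n, 0, eog_noise_sd)

  truth <- if (nrow(blinks) > 0) data.frame(
    onset_s = blinks$onset_s,
    offset_s = blinks$offset_s,
    subtype = blinks$subtype,
    true_onset_s = blinks$onset_s - 1.317 * tau,
    true_offset_s = blinks$offset_s + 1.317 * tau,
    stringsAsFactors = FALSE
  ) else data.frame()

  list(pupil = pupil, eog = eog, rate = rate, blink_truth = truth)
}

# trapezoid with half-height crossings exactly at onset/offset
trapezoid_wave <- function(t, onset, offset, rise, fall, height) {
  a <- onset - rise / 2; b <- onset + rise / 2
  c_ <- offset - fall / 2; d <- offset + fall / 2
  up <- pmin(pmax((t - a) / (b - a), 0), 1)
  down <- pmin(pmax((d - t) / (d - c_), 0), 1)
  height * pmin(up, down)
}
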