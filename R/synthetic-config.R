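#' Simulation configuration for a synthetic recording session
#'
#' Encodes the structure of the experimental task: continuously presented
#' 1 s object images grouped in ten-trial blocks separated by 3 s gray
#' blanks, experimenter-inserted gaps in 60% of the trials of non-voluntary
#' blocks (at 350/550/750 ms, lasting 100-200 ms), blocks of cued ~1 Hz
#' voluntary blinks, and spontaneous blinks throughout.
#'
#' @param n_blocks number of ten-trial blocks (default 32).
#' @param trials_per_block images per block (default 10).
#' @param stimulus_period_ms image duration / inter-onset interval (default 1000).
#' @param interblock_blank_ms gray baseline between blocks (default 3000).
#' @param gap_latencies_ms allowed gap onsets relative to trial onset
#'   (default 350, 550, 750).
#' @param gap_duration_range_ms uniform range of gap durations (default 100-200).
#' @param gap_fraction fraction of gap-block trials carrying a gap (default 0.6).
#' @param voluntary_block_fraction fraction of blocks cued for voluntary
#'   blinking (default 12/32).
#' @param voluntary_blink_rate_hz cued blink pace (default 1 per second).
#' @param spontaneous_blink_rate_hz Poisson rate of spontaneous blinks
#'   (default 0.25 per second).
#' @param blink_latency voluntary-blink latency model within a trial:
#'   list(mean_ms, sd_ms, min_ms, max_ms) for a truncated normal.
#' @param blink_duration_spontaneous,blink_duration_voluntary truncated
#'   log-normal duration models: list(meanlog, sdlog, min_ms, max_ms) with
#'   meanlog on the log-millisecond scale.
#' @param category_probs named probabilities for face / nonface / animal images.
#' @param gray_gap_fraction fraction of gaps rendered gray rather than black.
#' @param gradual_gap_fraction fraction of gaps faded in/out rather than abrupt.
#' @param noise noise model for the HFB-level simulation:
#'   list(kind = "ar1", ar, sd) or list(kind = "pink", exponent, sd).
#' @param rate_raw raw sampling rate, Hz (default 500).
#' @param rate_hfb HFB-level sampling rate, Hz (default 250).
#' @param seed integer seed; fully determines the generated session.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_blocks = 32L,
                       trials_per_block = 10L,
                       stimulus_period_ms = 1000,
                       interblock_blank_ms = 3000,
                       gap_latencies_ms = c(350, 550, 750),
                       gap_duration_range_ms = c(100, 200),
                       gap_fraction = 0.6,
                       voluntary_block_fraction = 12 / 32,
                       voluntary_blink_rate_hz = 1,
                       spontaneous_blink_rate_hz = 0.25,
                       blink_latency = list(mean_ms = 500, sd_ms = 150,
                                            min_ms = 50, max_ms = 900),
                       blink_duration_spontaneous = list(meanlog = log(150),
                                                         sdlog = 0.3,
                                                         min_ms = 50,
                                                         max_ms = 400),
                       blink_duration_voluntary = list(meanlog = log(200),
                                                       sdlog = 0.25,
                                                       min_ms = 80,
                                                       max_ms = 500),
                       category_probs = c(face = 0.2, nonface = 0.6,
                                          animal = 0.2),
                       gray_gap_fraction = 0.5,
                       gradual_gap_fraction = 0.5,
                       noise = list(kind = "ar1", ar = 0.9, sd = 1),
                       rate_raw = 500,
                       rate_hfb = 250,
                       seed = 1L) {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    stimulus_period_ms = stimulus_period_ms,
    interblock_blank_ms = interblock_blank_ms,
    gap_latencies_ms = gap_latencies_ms,
    gap_duration_range_ms = gap_duration_range_ms,
    gap_fraction = gap_fraction,
    voluntary_block_fraction = voluntary_block_fraction,
    voluntary_blink_rate_hz = voluntary_blink_rate_hz,
    spontaneous_blink_rate_hz = spontaneous_blink_rate_hz,
    blink_latency = blink_latency,
    blink_duration_spontaneous = blink_duration_spontaneous,
    blink_duration_voluntary = blink_duration_voluntary,
    category_probs = category_probs,
    gray_gap_fraction = gray_gap_fraction,
    gradual_gap_fraction = gradual_gap_fraction,
    noise = noise,
    rate_raw = rate_raw,
    rate_hfb = rate_hfb,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_blocks < 1 || cfg$trials_per_block < 1)
    stop_hfb("hfbdeconv_invalid_config", "need at least one block and trial")
  if (any(cfg$gap_latencies_ms < 0) ||
      any(cfg$gap_latencies_ms >= cfg$stimulus_period_ms))
    stop_hfb("hfbdeconv_invalid_config",
             "gap latencies must lie in [0, stimulus_period)")
  if (any(cfg$gap_duration_range_ms <= 0) ||
      diff(cfg$gap_duration_range_ms) < 0)
    stop_hfb("hfbdeconv_invalid_config", "gap durations must be positive")
  if (cfg$gap_fraction < 0 || cfg$gap_fraction > 1 ||
      cfg$voluntary_block_fraction < 0 || cfg$voluntary_block_fraction > 1)
    stop_hfb("hfbdeconv_invalid_config", "fractions must lie in [0, 1]")
  if (abs(sum(cfg$category_probs) - 1) > 1e-8)
    stop_hfb("hfbdeconv_invalid_config", "category probabilities must sum to 1")
  invisible(cfg)
}

# session timing helpers ------------------------------------------------------

#' Total duration (s) of a simulated session
#' @param config a [sim_config()].
#' @return session length in seconds, including the leading blank.
#' @export
session_duration <- function(config) {
  blk <- config$trials_per_block * config$stimulus_period_ms +
    config$interblock_blank_ms
  (config$interblock_blank_ms + config$n_blocks * blk) / 1000
}

#' Inter-block gray baseline intervals of a simulated session
#' @param config a [sim_config()].
#' @return a matrix with columns start, end (seconds).
#' @export
baseline_intervals <- function(config) {
  blank <- config$interblock_blank_ms / 1000
  blk <- config$trials_per_block * config$stimulus_period_ms / 1000
  starts <- c(0, blank + seq_len(config$n_blocks) * (blk + blank) - blank)
  cbind(start = starts, end = starts + blank)
}

block_start_s <- function(config, block) {
  blank <- config$interblock_blank_ms / 1000
  blk <- config$trials_per_block * config$stimulus_period_ms / 1000
  blank + (block - 1) * (blk + blank)
}
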