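#' Generate the event schedule of a synthetic session
#'
#' Produces a block-structured event table: stimulus onsets at a constant
#' 1 Hz pace within blocks, gaps in a configurable fraction of the trials of
#' non-voluntary blocks (one gap per trial, at one of the configured
#' latencies), cued ~1 Hz voluntary blinks within voluntary blocks, and
#' spontaneous blinks elsewhere. Animal trials are kept in the table but are
#' meant for downstream exclusion (they are behavioural targets). Blinks that
#' would overlap a gap, or that do not fall entirely inside a trial, are
#' dropped so that gap and blink events never coincide within a trial.
#'
#' @param config a [sim_config()].
#' @return a data.frame of class `event_table` with columns
#'   `onset_s`, `offset_s`, `kind` (stimulus/gap/blink), `category`
#'   (face/nonface/animal), `subtype` (spontaneous/voluntary for blinks,
#'   black/gray for gaps), `ramp` (abrupt/gradual for gaps), `trial_index`,
#'   `block_index`. Attributes: `baseline_intervals`, `duration_s`, `config`.
#' @export
generate_schedule <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  period_s <- config$stimulus_period_ms / 1000
  n_trials <- config$n_blocks * config$trials_per_block

  n_vol <- round(config$voluntary_block_fraction * config$n_blocks)
  vol_blocks <- if (n_vol > 0) sort(sample.int(config$n_blocks, n_vol)) else integer(0)

  rows <- list()
  trial_idx <- 0L
  for (b in seq_len(config$n_blocks)) {
    b_start <- block_start_s(config, b)
    voluntary <- b %in% vol_blocks
    for (i in seq_len(config$trials_per_block)) {
      trial_idx <- trial_idx + 1L
      t0 <- b_start + (i - 1) * period_s
      category <- sample(names(config$category_probs), 1L,
                         prob = config$category_probs)
      rows[[length(rows) + 1L]] <- data.frame(
        onset_s = t0, offset_s = t0 + period_s, kind = "stimulus",
        category = category, subtype = NA_character_, ramp = NA_character_,
        trial_index = trial_idx, block_index = b,
        stringsAsFactors = FALSE)

      if (!voluntary && runif(1) < config$gap_fraction) {
        lat <- sample(config$gap_latencies_ms, 1L) / 1000
        dur <- runif(1, config$gap_duration_range_ms[1],
                     config$gap_duration_range_ms[2]) / 1000
        dur <- min(dur, period_s - lat - 0.002)  # keep the gap inside its trial
        rows[[length(rows) + 1L]] <- data.frame(
          onset_s = t0 + lat, offset_s = t0 + lat + dur, kind = "gap",
          category = category,
          subtype = if (runif(1) < config$gray_gap_fraction) "gray" else "black",
          ramp = if (runif(1) < config$gradual_gap_fraction) "gradual" else "abrupt",
          trial_index = trial_idx, block_index = b,
          stringsAsFactors = FALSE)
      }

      if (voluntary && config$voluntary_blink_rate_hz > 0 &&
          runif(1) < min(1, config$voluntary_blink_rate_hz * period_s)) {
        bl <- config$blink_latency
        lat <- rnorm(1, bl$mean_ms, bl$sd_ms)
        lat <- min(max(lat, bl$min_ms), bl$max_ms) / 1000
        dur <- rtrunc_lnorm(1, config$blink_duration_voluntary) / 1000
        if (lat + dur < period_s) {
          rows[[length(rows) + 1L]] <- data.frame(
            onset_s = t0 + lat, offset_s = t0 + lat + dur, kind = "blink",
            category = category, subtype = "voluntary", ramp = NA_character_,
            trial_index = trial_idx, block_index = b,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  ev <- do.call(rbind, rows)

  # spontaneous blinks: Poisson process over non-voluntary block time,
  # retained only when fully inside a trial and not overlapping a gap
  if (config$spontaneous_blink_rate_hz > 0) {
    stim <- ev[ev$kind == "stimulus" & !(ev$block_index %in% vol_blocks), ]
    gaps <- ev[ev$kind == "gap", ]
    sp <- list()
    for (r in seq_len(nrow(stim))) {
      n_bl <- stats::rpois(1, config$spontaneous_blink_rate_hz * period_s)
      if (n_bl < 1) next
      on <- stim$onset_s[r] + sort(runif(n_bl, 0, period_s))
      dur <- rtrunc_lnorm(n_bl, config$blink_duration_spontaneous) / 1000
      off <- on + dur
      keep <- off < stim$offset_s[r]
      if (nrow(gaps) > 0) {
        g <- gaps[gaps$trial_index == stim$trial_index[r], ]
        if (nrow(g) > 0)
          keep <- keep & (off < g$onset_s[1] | on > g$offset_s[1])
      }
      # a single blink at a time: drop overlapping pairs
      if (sum(keep) > 1) {
        ok <- which(keep)
        for (j in seq_along(ok)[-1])
          if (on[ok[j]] < off[ok[j - 1]]) keep[ok[j]] <- FALSE
      }
      if (!any(keep)) next
      sp[[length(sp) + 1L]] <- data.frame(
        onset_s = on[keep], offset_s = off[keep], kind = "blink",
        category = stim$category[r], subtype = "spontaneous",
        ramp = NA_character_,
        trial_index = stim$trial_index[r], block_index = stim$block_index[r],
        stringsAsFactors = FALSE)
    }
    if (length(sp) > 0) ev <- rbind(ev, do.call(rbind, sp))
  }

  ev <- ev[order(ev$onset_s, ev$kind), ]
  rownames(ev) <- NULL
  attr(ev, "baseline_intervals") <- baseline_intervals(config)
  attr(ev, "duration_s") <- session_duration(config)
  attr(ev, "voluntary_blocks") <- vol_blocks
  attr(ev, "config") <- config
  class(ev) <- c("event_table", "data.frame")
  ev
}

# truncated log-normal sampler (ms scale); resamples out-of-range draws
rtrunc_lnorm <- function(n, spec) {
  x <- rlnorm(n, spec$meanlog, spec$sdlog)
  bad <- x < spec$min_ms | x > spec$max_ms
  while (any(bad)) {
    x[bad] <- rlnorm(sum(bad), spec$meanlog, spec$sdlog)
    bad <- x < spec$min_ms | x > spec$max_ms
  }
  x
}

#' Write / read an event table as tab-separated values
#' @param events an `event_table` data.frame.
#' @param path file path.
#' @return `read_event_table` returns the event table; `write_event_table`
#'   returns `path` invisibly.
#' @export
write_event_table <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}
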