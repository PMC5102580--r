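# Visual responsiveness screening, face selectivity, ROI assignment ----------

#' Score visual responsiveness of each electrode
#'
#' Compares the mean HFB activation 50-350 ms after each trial onset with
#' the baseline activity, per electrode, by a Wilcoxon rank-sum test over
#' all object images (one-sided: response > baseline), Bonferroni-corrected
#' across the patient's electrodes. Only trials free of blinks and gaps
#' during the response window or the preceding 100 ms are used; animal
#' (target) trials and trials touching masked timepoints are excluded.
#' The effect size is Glass' delta of the maximally responding category:
#' (mean response - mean baseline) / SD(baseline), with baseline sampled as
#' per-interval means to avoid autocorrelation-inflated sample sizes.
#' Electrodes are selected when corrected p < `alpha` and delta >= 2.
#'
#' @param hfb an `hfb_timecourse` (baseline-normalized).
#' @param events an `event_table`.
#' @param window_ms response window relative to trial onset (default
#'   c(50, 350)).
#' @param lookback_ms contamination look-back before the window (default 100).
#' @param alpha significance level on the corrected p-value.
#' @param min_delta Glass' delta inclusion threshold (default 2).
#' @return data.frame of class `responsiveness_result`: electrode, p_raw,
#'   p_corrected, glass_delta, best_category, selected, n_trials.
#' @export
score_visual_responsiveness <- function(hfb, events,
                                        window_ms = c(50, 350),
                                        lookback_ms = 100,
                                        alpha = 0.05, min_delta = 2) {
  rate <- hfb$rate
  base_idx <- hfb$baseline_intervals
  if (is.null(base_idx))
    stop_hfb("hfbdeconv_no_baseline", "hfb carries no baseline intervals")
  stim <- events[events$kind == "stimulus" & events$category != "animal", ]
  intr <- events[events$kind %in% c("gap", "blink"), ]
  # trials contaminated by an interruption in [win_lo - lookback, win_hi]
  clean <- vapply(seq_len(nrow(stim)), function(r) {
    a <- stim$onset_s[r] + (window_ms[1] - lookback_ms) / 1000
    b <- stim$onset_s[r] + window_ms[2] / 1000
    !any(intr$onset_s < b & intr$offset_s > a)
  }, TRUE)
  stim <- stim[clean, ]
  if (nrow(stim) == 0)
    stop_hfb("hfbdeconv_no_trials", "no eligible trials")
  n_time <- ncol(hfb$values)
  win <- lapply(seq_len(nrow(stim)), function(r) {
    i0 <- event_sample(stim$onset_s[r], rate) +
      as.integer(round(window_ms[1] / 1000 * rate))
    i1 <- event_sample(stim$onset_s[r], rate) +
      as.integer(round(window_ms[2] / 1000 * rate)) - 1L
    idx <- i0:i1
    idx[idx >= 1 & idx <= n_time]
  })
  masked_trial <- vapply(win, function(idx) any(hfb$rejection_mask[idx]), TRUE)
  stim <- stim[!masked_trial, ]; win <- win[!masked_trial]
  if (nrow(stim) == 0)
    stop_hfb("hfbdeconv_no_trials", "all trials masked")

  n_el <- nrow(hfb$values)
  res <- vector("list", n_el)
  for (e in seq_len(n_el)) {
    y <- hfb$values[e, ]
    trial_means <- vapply(win, function(idx) mean(y[idx]), 0)
    bmeans <- baseline_interval_means(y, base_idx, rate, hfb$rejection_mask)
    if (length(bmeans) < 2)
      stop_hfb("hfbdeconv_no_baseline", "fewer than 2 baseline intervals")
    p <- suppressWarnings(
      wilcox.test(trial_means, bmeans, alternative = "greater")$p.value)
    cat_means <- tapply(trial_means, stim$category, mean)
    best <- names(cat_means)[which.max(cat_means)]
    delta <- (max(cat_means) - mean(bmeans)) / sd(bmeans)
    res[[e]] <- data.frame(
      electrode = hfb$channel_names[e], p_raw = p,
      glass_delta = delta, best_category = best,
      n_trials = nrow(stim), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_corrected <- pmin(1, out$p_raw * n_el)
  out$selected <- out$p_corrected < alpha & out$glass_delta >= min_delta
  class(out) <- c("responsiveness_result", "data.frame")
  out
}

baseline_interval_means <- function(y, intervals, rate, mask) {
  vapply(seq_len(nrow(intervals)), function(i) {
    idx <- intervals_to_index(intervals[i, , drop = FALSE], length(y), rate)
    idx <- idx & !mask
    if (!any(idx)) NA_real_ else mean(y[idx])
  }, 0) -> m
  m[!is.na(m)]
}

#' Score face selectivity of responsive electrodes
#'
#' An electrode is face-selective when its face-trial responses are
#' significantly stronger than those of every other (non-target) category
#' (one-sided rank-sum per contrast, p < `alpha`, uncorrected).
#'
#' @inheritParams score_visual_responsiveness
#' @param alpha per-contrast significance level.
#' @return data.frame electrode, face_selective, worst_p (the largest
#'   contrast p-value).
#' @export
score_face_selectivity <- function(hfb, events, window_ms = c(50, 350),
                                   lookback_ms = 100, alpha = 0.05) {
  rate <- hfb$rate
  stim <- events[events$kind == "stimulus" & events$category != "animal", ]
  intr <- events[events$kind %in% c("gap", "blink"), ]
  clean <- vapply(seq_len(nrow(stim)), function(r) {
    a <- stim$onset_s[r] + (window_ms[1] - lookback_ms) / 1000
    b <- stim$onset_s[r] + window_ms[2] / 1000
    !any(intr$onset_s < b & intr$offset_s > a)
  }, TRUE)
  stim <- stim[clean, ]
  cats <- setdiff(unique(stim$category), "face")
  if (!("face" %in% stim$category) || !length(cats))
    stop_hfb("hfbdeconv_insufficient_trials", "need face and non-face trials")
  n_time <- ncol(hfb$values)
  win_mean <- function(y, on) {
    i0 <- event_sample(on, rate) + as.integer(round(window_ms[1] / 1000 * rate))
    i1 <- event_sample(on, rate) + as.integer(round(window_ms[2] / 1000 * rate)) - 1L
    idx <- i0:i1; idx <- idx[idx >= 1 & idx <= n_time]
    mean(y[idx])
  }
  out <- lapply(seq_len(nrow(hfb$values)), function(e) {
    y <- hfb$values[e, ]
    fm <- vapply(stim$onset_s[stim$category == "face"], win_mean, 0, y = y)
    ps <- vapply(cats, function(cc) {
      om <- vapply(stim$onset_s[stim$category == cc], win_mean, 0, y = y)
      if (length(om) < 2 || length(fm) < 2)
        stop_hfb("hfbdeconv_insufficient_trials",
                 "category '%s' has fewer than 2 trials", cc)
      suppressWarnings(
        wilcox.test(fm, om, alternative = "greater")$p.value)
    }, 0)
    data.frame(electrode = hfb$channel_names[e],
               face_selective = all(ps < alpha), worst_p = max(ps),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign region-of-interest labels
#'
#' Functional criterion precedes anatomy: electrodes qualifying as
#' face-selective are assigned to FC regardless of their anatomical label.
#' Electrodes labeled `unassigned` are kept (for electrode-level maps) but
#' flagged for exclusion from ROI-level analyses.
#'
#' @param metadata data.frame with columns `electrode` and `roi` (labels in
#'   V1, V2, V3, V4, VO, FC, N-FC, unassigned).
#' @param face_selective logical vector aligned with `metadata` rows.
#' @return the metadata with columns `roi` (updated) and `in_roi_analysis`.
#' @export
assign_rois <- function(metadata, face_selective = NULL) {
  allowed <- c("V1", "V2", "V3", "V4", "VO", "FC", "N-FC", "unassigned")
  if (nrow(metadata) == 0) {
    metadata$in_roi_analysis <- logical(0)
    return(metadata)
  }
  if (!all(metadata$roi %in% allowed))
    stop_hfb("hfbdeconv_invalid_roi", "unknown ROI label(s): %s",
             paste(setdiff(unique(metadata$roi), allowed), collapse = ", "))
  if (!is.null(face_selective)) metadata$roi[face_selective] <- "FC"
  metadata$in_roi_analysis <- metadata$roi != "unassigned"
  metadata
}
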