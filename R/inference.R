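# Electrode-level permutation tests, randomization test of independence,
# FDR adjustment.

#' Smoothed permutation p-value
#' @param b number of permutations with a statistic at least as extreme as
#'   observed.
#' @param m number of permutations.
#' @return `(b + 1) / (m + 1)`.
#' @export
permutation_p <- function(b, m) {
  if (m < 1) stop_hfb("hfbdeconv_invalid_input", "m must be >= 1")
  if (b < 0 || b > m) stop_hfb("hfbdeconv_invalid_input", "need 0 <= b <= m")
  (b + 1) / (m + 1)
}

# plugin gap-minus-blink component difference on the reduced model
component_difference <- function(y, rate, n_time, stim_onsets,
                                 gap_anchor, blink_anchor,
                                 component, excluded,
                                 interruption_window_ms, stimulus_window_ms) {
  sgn <- if (component == "overshoot") +1 else -1
  sets <- list()
  if (length(stim_onsets))
    sets$stimulus <- list(onsets_s = stim_onsets,
                          window_ms = stimulus_window_ms)
  sets$gap <- list(onsets_s = gap_anchor, window_ms = interruption_window_ms)
  sets$blink <- list(onsets_s = blink_anchor,
                     window_ms = interruption_window_ms)
  design <- build_design_matrix(sets, n_time = n_time, rate = rate,
                                excluded = excluded,
                                exclusion_mode = "drop")
  fit <- fir_deconv(design, y, hc3 = FALSE)
  tg <- deconv_trace(fit, "gap"); tb <- deconv_trace(fit, "blink")
  ig <- find_extreme_cluster(tg$beta, tg$lag_ms, sgn)$integral
  ib <- find_extreme_cluster(tb$beta, tb$lag_ms, sgn)$integral
  ig - ib
}

#' Stratified permutation test of gap versus blink components
#'
#' Tests whether an electrode's dip or overshoot differs between gaps and
#' blinks by shuffling the gap/blink labels of the individual interruption
#' events, keeping the counts of gaps and blinks within face trials and
#' within non-face trials constant, re-deconvolving, and recomputing the
#' component difference for each permutation. Both the observed and the
#' permuted data pass through the same cluster selection, so selection bias
#' cancels in the comparison. The reduced model (no face/non-face split of
#' the predictors) is used. p-values are smoothed, `(b + 1) / (m + 1)`, and
#' corrected for two-tailed testing by doubling the smaller tail.
#'
#' @param y HFB timecourse (one channel, percent change).
#' @param events an `event_table`.
#' @param rate Hz.
#' @param component "overshoot" (offset-locked) or "dip" (onset-locked).
#' @param blink_type "spontaneous" or "voluntary" (the contrasted blinks).
#' @param m number of permutations (default 2000).
#' @param seed integer seed.
#' @param excluded excluded timepoint indices.
#' @param interruption_window_ms,stimulus_window_ms FIR windows, ms.
#' @return data.frame of class `permutation_result` with the observed
#'   gap-minus-blink difference, b and p_raw (smaller tail), p_two_tailed,
#'   and the two directional tails `p_gap_gt_blink`, `p_blink_gt_gap`.
#' @export
permutation_test <- function(y, events, rate,
                             component = c("overshoot", "dip"),
                             blink_type = c("spontaneous", "voluntary"),
                             m = 2000L, seed = 1L,
                             excluded = integer(0),
                             interruption_window_ms = c(-250, 500),
                             stimulus_window_ms = c(0, 1500)) {
  component <- match.arg(component)
  blink_type <- match.arg(blink_type)
  lock <- if (component == "overshoot") "offset" else "onset"
  stim <- events[events$kind == "stimulus" & events$category != "animal", ]
  gaps <- events[events$kind == "gap" & events$category != "animal", ]
  blinks <- events[events$kind == "blink" & events$subtype == blink_type &
                     events$category != "animal", ]
  if (nrow(gaps) == 0 || nrow(blinks) == 0)
    stop_hfb("hfbdeconv_degenerate_strata",
             "need both gap and blink events")
  anchor <- function(d) if (lock == "onset") d$onset_s else d$offset_s
  ev_anchor <- c(anchor(gaps), anchor(blinks))
  ev_cat <- c(gaps$category, blinks$category)
  is_gap <- c(rep(TRUE, nrow(gaps)), rep(FALSE, nrow(blinks)))
  n_time <- as.integer(round(attr(events, "duration_s") * rate))
  if (is.na(n_time) || n_time < length(y)) n_time <- length(y)

  diff_for <- function(lab_gap) {
    component_difference(y, rate, length(y), stim$onset_s,
                         ev_anchor[lab_gap], ev_anchor[!lab_gap],
                         component, excluded,
                         interruption_window_ms, stimulus_window_ms)
  }
  observed <- diff_for(is_gap)

  set.seed(seed)
  strata <- ifelse(ev_cat == "face", "face", "nonface")
  perm_diffs <- numeric(m)
  for (k in seq_len(m)) {
    lab <- logical(length(is_gap))
    for (st in unique(strata)) {
      idx <- which(strata == st)
      n_gap_st <- sum(is_gap[idx])
      if (n_gap_st == 0 || n_gap_st == length(idx)) {
        lab[idx] <- is_gap[idx]  # degenerate stratum: labels fixed
      } else {
        lab[idx[sample.int(length(idx), n_gap_st)]] <- TRUE
      }
    }
    perm_diffs[k] <- diff_for(lab)
  }
  b_upper <- sum(perm_diffs >= observed)
  b_lower <- sum(perm_diffs <= observed)
  p_upper <- permutation_p(b_upper, m)   # gap > blink direction
  p_lower <- permutation_p(b_lower, m)   # blink > gap direction
  out <- data.frame(
    component = component, blink_type = blink_type,
    observed = observed, b = min(b_upper, b_lower), m = m,
    p_raw = min(p_upper, p_lower),
    p_two_tailed = min(1, 2 * min(p_upper, p_lower)),
    p_gap_gt_blink = p_upper, p_blink_gt_gap = p_lower,
    stringsAsFactors = FALSE)
  class(out) <- c("permutation_result", "data.frame")
  attr(out, "perm_diffs") <- perm_diffs
  out
}

#' Chi-squared statistic for inhomogeneity of proportions across ROIs
#'
#' `E_i = n_i * sum(O) / sum(n)`; the statistic is
#' `sum((O_i - E_i)^2 / E_i)`.
#'
#' @param O observed counts of significant electrodes per ROI.
#' @param n total electrodes per ROI.
#' @return the statistic (0 when O is exactly proportional to n).
#' @export
chi2_inhomogeneity <- function(O, n) {
  if (length(O) != length(n) || any(n <= 0))
    stop_hfb("hfbdeconv_invalid_counts", "need n_i > 0 matching O")
  if (any(O < 0) || sum(O) > sum(n))
    stop_hfb("hfbdeconv_invalid_counts", "need 0 <= O_i and sum(O) <= sum(n)")
  if (sum(O) == 0) return(0)  # no significant electrodes anywhere
  E <- n * sum(O) / sum(n)
  if (any(E == 0 & O > 0))
    stop_hfb("hfbdeconv_invalid_counts", "E_i = 0 with O_i > 0")
  sum((O - E)^2 / E)
}

#' Randomization test of independence of effect occurrence across ROIs
#'
#' Draws the empirical null by randomly reassigning the significant
#' electrodes across ROIs, keeping the number of electrodes within each ROI
#' and the total number of significant electrodes fixed (multivariate
#' hypergeometric), and compares the observed chi-squared inhomogeneity
#' statistic with the null draws; `p = (b + 1) / (m + 1)` with
#' `b = #(null >= observed)`.
#'
#' @param O observed significant-electrode counts per ROI.
#' @param n electrodes per ROI.
#' @param m number of null draws (default 10000).
#' @param seed integer seed.
#' @return list `chi2_observed`, `df`, `p`, `m`, `null` (draws).
#' @export
randomization_independence_test <- function(O, n, m = 10000L, seed = 1L) {
  chi2_obs <- chi2_inhomogeneity(O, n)
  set.seed(seed)
  k <- length(n)
  pool <- rep.int(seq_len(k), n)
  S <- sum(O)
  null <- vapply(seq_len(m), function(i) {
    hit <- pool[sample.int(length(pool), S)]
    chi2_inhomogeneity(tabulate(hit, nbins = k), n)
  }, 0)
  list(chi2_observed = chi2_obs, df = k - 1L,
       p = permutation_p(sum(null >= chi2_obs - 1e-12), m),
       m = m, null = null)
}

#' Benjamini-Hochberg FDR-adjusted p-values
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values (step-up), same order as input.
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_hfb("hfbdeconv_invalid_input", "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
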