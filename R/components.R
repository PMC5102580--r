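# Dip / overshoot component quantification -----------------------------------

#' Find the extreme contiguous same-sign cluster of a trace
#'
#' Enumerates maximal runs of strictly positive (or strictly negative)
#' timepoints within the search region and returns the run with the largest
#' absolute activation integral (`sum(beta) * dt`, % change x seconds).
#' Points exactly at zero terminate a run. Ties go to the earliest run.
#' If no run of the requested sign exists the integral is 0 with an empty
#' interval.
#'
#' @param beta per-lag coefficients.
#' @param lags_ms lag axis, ms.
#' @param sign_dir +1 for above-zero clusters (overshoot), -1 for
#'   below-zero clusters (dip).
#' @param search_start_ms only lags >= this value are searched (default 0:
#'   clusters following the locking event; the pre-event window is
#'   excluded).
#' @return list `interval_ms` (c(start, end) or NULL), `integral`
#'   (% x s; >= 0 for +, <= 0 for -), `indices` (into `beta`).
#' @export
find_extreme_cluster <- function(beta, lags_ms, sign_dir = +1,
                                 search_start_ms = 0) {
  stopifnot(length(beta) == length(lags_ms))
  dt <- diff(lags_ms[1:2]) / 1000
  eligible <- lags_ms >= search_start_ms & !is.na(beta)
  inside <- eligible & (if (sign_dir > 0) beta > 0 else beta < 0)
  if (!any(inside))
    return(list(interval_ms = NULL, integral = 0, indices = integer(0)))
  r <- rle(as.vector(inside))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- NULL; best_abs <- -Inf
  for (k in runs) {
    idx <- starts[k]:ends[k]
    integral <- sum(beta[idx]) * dt
    if (abs(integral) > best_abs + 1e-15) {
      best_abs <- abs(integral)
      best <- list(interval_ms = c(lags_ms[idx[1]], lags_ms[idx[length(idx)]]),
                   integral = integral, indices = idx)
    }
  }
  best
}

# integrate a trace over a fixed lag interval (used on the held-out half)
integrate_interval <- function(beta, lags_ms, interval_ms) {
  if (is.null(interval_ms)) return(0)
  dt <- diff(lags_ms[1:2]) / 1000
  idx <- which(lags_ms >= interval_ms[1] - 1e-9 & lags_ms <= interval_ms[2] + 1e-9)
  sum(beta[idx], na.rm = TRUE) * dt
}

#' Quantify dip and overshoot components from a fit pair
#'
#' The reappearance-related overshoot is the largest above-zero cluster
#' integral of the offset-locked trace after the reappearance (lags >= 0);
#' the activation dip is the largest-magnitude below-zero cluster integral
#' of the onset-locked trace after the disappearance.
#'
#' @param onset_fit `fir_deconv` of the disappearance (onset)-locked model.
#' @param offset_fit `fir_deconv` of the reappearance (offset)-locked model.
#' @param sets predictor-set names to quantify (default: interruption sets
#'   present in both fits).
#' @return data.frame set, component (dip/overshoot), integral (% x s),
#'   cluster_start_ms, cluster_end_ms, method = "plugin".
#' @export
quantify_components <- function(onset_fit, offset_fit, sets = NULL) {
  if (missing(onset_fit) || missing(offset_fit) ||
      is.null(onset_fit) || is.null(offset_fit))
    stop_hfb("hfbdeconv_missing_model",
             "both onset- and offset-locked fits are required")
  pick_sets <- function(fit) {
    s <- unique(fit$columns$set[fit$columns$type == "fir"])
    s[!startsWith(s, "stimulus")]
  }
  if (is.null(sets)) sets <- intersect(pick_sets(onset_fit), pick_sets(offset_fit))
  rows <- lapply(sets, function(s) {
    tr_on <- deconv_trace(onset_fit, s)
    tr_off <- deconv_trace(offset_fit, s)
    dip <- find_extreme_cluster(tr_on$beta, tr_on$lag_ms, -1)
    over <- find_extreme_cluster(tr_off$beta, tr_off$lag_ms, +1)
    data.frame(
      set = s, component = c("dip", "overshoot"),
      integral = c(dip$integral, over$integral),
      cluster_start_ms = c(ival(dip, 1), ival(over, 1)),
      cluster_end_ms = c(ival(dip, 2), ival(over, 2)),
      method = "plugin", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

ival <- function(cl, i) if (is.null(cl$interval_ms)) NA_real_ else cl$interval_ms[i]

#' Split-half (non-circular) component estimation
#'
#' Cluster selection on the same trace that is integrated inflates the
#' estimate (selection bias / circular analysis). For each of `n_splits`
#' random splits, every interruption event cell is halved into two distinct
#' predictor sets and the model is fitted once; the cluster interval is
#' determined on one half's trace and the integral measured on the other
#' half's trace over that interval (both directions, averaged), then
#' averaged across splits. Under the null the expectation is zero.
#'
#' @param y HFB timecourse (one channel).
#' @param events an `event_table`.
#' @param rate Hz.
#' @param component "overshoot" (offset-locked, positive clusters) or
#'   "dip" (onset-locked, negative clusters).
#' @param n_splits number of random splits (default 30).
#' @param seed integer seed.
#' @param split_by_category halve each interruption x category cell
#'   separately (stratified), and model categories separately.
#' @param interruption_window_ms,stimulus_window_ms FIR windows, ms.
#' @param excluded excluded timepoint indices.
#' @param sets_filter optional character vector restricting which
#'   interruption types are quantified.
#' @return data.frame set, component, integral, method = "split_half",
#'   n_splits.
#' @export
split_half_estimate <- function(y, events, rate,
                                component = c("overshoot", "dip"),
                                n_splits = 30L, seed = 1L,
                                split_by_category = FALSE,
                                interruption_window_ms = c(-250, 500),
                                stimulus_window_ms = c(0, 1500),
                                excluded = integer(0),
                                sets_filter = NULL) {
  component <- match.arg(component)
  lock <- if (component == "overshoot") "offset" else "onset"
  sgn <- if (component == "overshoot") +1 else -1
  base_sets <- predictor_sets(events, lock = lock,
                              split_by_category = split_by_category,
                              stimulus_window_ms = stimulus_window_ms,
                              interruption_window_ms = interruption_window_ms)
  intr_names <- names(base_sets)[!startsWith(names(base_sets), "stimulus")]
  if (!is.null(sets_filter))
    intr_names <- intr_names[sub("_(face|nonface)$", "", intr_names) %in% sets_filter]
  ok <- vapply(intr_names, function(nm)
    length(base_sets[[nm]]$onsets_s) >= 2, TRUE)
  if (any(!ok))
    warning(sprintf("skipping cells with < 2 events: %s",
                    paste(intr_names[!ok], collapse = ", ")))
  intr_names <- intr_names[ok]
  if (!length(intr_names))
    stop_hfb("hfbdeconv_insufficient_events",
             "no interruption cell has >= 2 events")

  set.seed(seed)
  acc <- matrix(0, nrow = length(intr_names), ncol = n_splits,
                dimnames = list(intr_names, NULL))
  for (sp in seq_len(n_splits)) {
    sets <- base_sets[startsWith(names(base_sets), "stimulus")]
    halves <- list()
    for (nm in intr_names) {
      on <- base_sets[[nm]]$onsets_s
      nA <- ceiling(length(on) / 2)
      idxA <- sample(seq_along(on), nA)
      sets[[paste0(nm, "__A")]] <- list(onsets_s = on[idxA],
                                        window_ms = interruption_window_ms)
      sets[[paste0(nm, "__B")]] <- list(onsets_s = on[-idxA],
                                        window_ms = interruption_window_ms)
      halves[[nm]] <- TRUE
    }
    design <- build_design_matrix(sets, n_time = length(y), rate = rate,
                                  excluded = excluded,
                                  exclusion_mode = "drop")
    fit <- fir_deconv(design, y, hc3 = FALSE)
    for (nm in intr_names) {
      trA <- deconv_trace(fit, paste0(nm, "__A"))
      trB <- deconv_trace(fit, paste0(nm, "__B"))
      clA <- find_extreme_cluster(trA$beta, trA$lag_ms, sgn)
      clB <- find_extreme_cluster(trB$beta, trB$lag_ms, sgn)
      est <- (integrate_interval(trB$beta, trB$lag_ms, clA$interval_ms) +
              integrate_interval(trA$beta, trA$lag_ms, clB$interval_ms)) / 2
      acc[nm, sp] <- est
    }
  }
  data.frame(set = intr_names, component = component,
             integral = rowMeans(acc), method = "split_half",
             n_splits = n_splits, stringsAsFactors = FALSE,
             row.names = NULL)
}
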