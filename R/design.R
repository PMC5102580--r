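# FIR design matrices for time-domain deconvolution ---------------------------

#' Build an FIR design matrix from event onsets
#'
#' Each predictor set contributes one 0/1 column per lag bin of its window:
#' a train of non-overlapping unit pulses, one pulse (at the event sample
#' plus the lag) per contributing event. Windows are half-open
#' `[start, end)` tiled by bins of `1000/rate` ms; a trailing partial bin is
#' discarded (a -250 to 500 ms window at 4 ms bins gives 187 columns, and a
#' 0 to 1500 ms window gives 375). Excluded timepoints each get a dummy
#' column holding a single 1, which absorbs that timepoint exactly.
#'
#' @param sets named list of predictor sets; each is a list with
#'   `onsets_s` (event times, seconds) and `window_ms` (c(start, end), ms).
#' @param n_time number of timepoints of the modeled timecourse.
#' @param rate sampling rate of the timecourse, Hz.
#' @param excluded integer vector of excluded timepoint indices (animal
#'   trials, outlier-masked samples, breaks).
#' @param exclusion_mode "dummy" adds one unit-vector dummy column per
#'   excluded timepoint (the printed design); "drop" removes those rows
#'   instead. The two give identical FIR coefficients, leverages and HC3
#'   errors (a dummy saturates exactly its own timepoint); "drop" is the
#'   fast path for permutation and split-half loops.
#' @return list of class `fir_design`: `X` (sparse n_time x p), `columns`
#'   (data.frame set, lag_ms, type), `n_time`, `rate`, and `keep_rows`
#'   (when `exclusion_mode = "drop"`).
#' @export
build_design_matrix <- function(sets, n_time, rate, excluded = integer(0),
                                exclusion_mode = c("dummy", "drop")) {
  exclusion_mode <- match.arg(exclusion_mode)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop_hfb("hfbdeconv_invalid_input", "predictor sets must be named")
  bin_ms <- 1000 / rate
  ii <- integer(0); jj <- integer(0)
  col_set <- character(0); col_lag <- numeric(0)
  p <- 0L
  for (nm in names(sets)) {
    s <- sets[[nm]]
    n_lags <- n_fir_columns(s$window_ms, rate)
    if (n_lags < 1)
      stop_hfb("hfbdeconv_invalid_input", "window of set '%s' is empty", nm)
    lags_ms <- s$window_ms[1] + (seq_len(n_lags) - 1L) * bin_ms
    start_samp <- as.integer(round(s$window_ms[1] / 1000 * rate))
    if (length(s$onsets_s)) {
      base_idx <- event_sample(s$onsets_s, rate) + start_samp
      for (k in seq_len(n_lags)) {
        rows <- base_idx + (k - 1L)
        rows <- rows[rows >= 1L & rows <= n_time]
        ii <- c(ii, rows)
        jj <- c(jj, rep.int(p + k, length(rows)))
      }
    }
    col_set <- c(col_set, rep(nm, n_lags))
    col_lag <- c(col_lag, lags_ms)
    p <- p + n_lags
  }
  excluded <- sort(unique(as.integer(excluded)))
  excluded <- excluded[excluded >= 1L & excluded <= n_time]
  if (length(excluded) && exclusion_mode == "dummy") {
    ii <- c(ii, excluded)
    jj <- c(jj, p + seq_along(excluded))
    col_set <- c(col_set, rep("dummy", length(excluded)))
    col_lag <- c(col_lag, rep(NA_real_, length(excluded)))
    p <- p + length(excluded)
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n_time, p))
  columns <- data.frame(
    set = col_set, lag_ms = col_lag,
    type = ifelse(col_set == "dummy", "dummy", "fir"),
    stringsAsFactors = FALSE)
  cn <- paste0(columns$set, "_", columns$lag_ms)
  if (exclusion_mode == "dummy" && length(excluded))
    cn[columns$type == "dummy"] <- paste0("dummy_t", excluded)
  colnames(X) <- cn
  keep_rows <- NULL
  if (exclusion_mode == "drop" && length(excluded)) {
    keep_rows <- setdiff(seq_len(n_time), excluded)
    X <- X[keep_rows, , drop = FALSE]
  }
  structure(list(X = X, columns = columns, n_time = n_time, rate = rate,
                 keep_rows = keep_rows),
            class = "fir_design")
}

#' Number of FIR columns for a window at a given rate
#' @param window_ms c(start, end) in ms (half-open).
#' @param rate Hz.
#' @return integer column count (trailing partial bin discarded).
#' @export
n_fir_columns <- function(window_ms, rate) {
  as.integer(floor((window_ms[2] - window_ms[1]) * rate / 1000))
}

#' Assemble the standard predictor sets for a session
#'
#' Stimulus onsets get a `[0, 1500)` ms window; interruption events (gaps,
#' voluntary and spontaneous blinks) get `[-250, 500)` ms windows locked to
#' either their onsets (image disappearance) or offsets (image
#' reappearance). Onset- and offset-locked interruption predictors are
#' never mixed: near-perfect collinearity between the two locks makes a
#' combined model unstable, so reappearance effects are estimated from a
#' separate model (`lock = "offset"`). Animal-trial stimuli are not
#' modeled; their timepoints are meant to be excluded via dummies.
#'
#' @param events an `event_table`.
#' @param lock "onset" or "offset" interruption locking.
#' @param split_by_category model face and non-face events separately
#'   (the reduced model pools them).
#' @param stimulus_window_ms,interruption_window_ms FIR windows, ms.
#' @return named list of predictor sets for [build_design_matrix()].
#' @export
predictor_sets <- function(events, lock = c("onset", "offset"),
                           split_by_category = TRUE,
                           stimulus_window_ms = c(0, 1500),
                           interruption_window_ms = c(-250, 500)) {
  lock <- match.arg(lock)
  stim <- events[events$kind == "stimulus" & events$category != "animal", ]
  intr <- events[events$kind %in% c("gap", "blink"), ]
  itype <- ifelse(intr$kind == "gap", "gap", intr$subtype)
  anchor <- if (lock == "onset") intr$onset_s else intr$offset_s
  sets <- list()
  if (split_by_category) {
    for (cc in c("face", "nonface")) {
      on <- stim$onset_s[stim$category == cc]
      if (length(on))
        sets[[paste0("stimulus_", cc)]] <-
          list(onsets_s = on, window_ms = stimulus_window_ms)
    }
    for (ty in unique(itype)) for (cc in c("face", "nonface")) {
      sel <- itype == ty & intr$category == cc
      if (any(sel))
        sets[[paste0(ty, "_", cc)]] <-
          list(onsets_s = anchor[sel], window_ms = interruption_window_ms)
    }
  } else {
    if (nrow(stim))
      sets$stimulus <- list(onsets_s = stim$onset_s,
                            window_ms = stimulus_window_ms)
    for (ty in unique(itype)) {
      sel <- itype == ty & intr$category != "animal"
      if (any(sel))
        sets[[ty]] <- list(onsets_s = anchor[sel],
                           window_ms = interruption_window_ms)
    }
  }
  sets
}

#' Timepoints to exclude from deconvolution
#'
#' Animal-trial samples, outlier-masked samples, and (optionally) any extra
#' intervals such as rest breaks.
#'
#' @param events an `event_table`.
#' @param n_time timeline length.
#' @param rate Hz.
#' @param mask optional logical rejection mask (length `n_time`).
#' @param extra_intervals optional matrix of (start, end) seconds.
#' @return sorted integer vector of excluded timepoint indices.
#' @export
excluded_timepoints <- function(events, n_time, rate, mask = NULL,
                                extra_intervals = NULL) {
  bad <- logical(n_time)
  animal <- events[events$kind == "stimulus" & events$category == "animal", ]
  if (nrow(animal))
    bad <- bad | intervals_to_index(cbind(animal$onset_s, animal$offset_s),
                                    n_time, rate)
  if (!is.null(mask)) bad <- bad | mask
  if (!is.null(extra_intervals))
    bad <- bad | intervals_to_index(extra_intervals, n_time, rate)
  which(bad)
}
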