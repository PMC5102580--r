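# Blink detection and timing from pupil / EOG traces; gap-blink matching.

# runs of lost (NA) pupil samples -> matrix of (start, end) indices
loss_intervals <- function(pupil) {
  lost <- is.na(pupil)
  if (!any(lost)) return(matrix(numeric(0), ncol = 2))
  r <- rle(lost)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

#' Detect blinks from concurrent pupil and EOG traces
#'
#' Candidate blinks are intervals of lost pupil tracking; a candidate is
#' retained only if a super-threshold EOG artifact co-occurs within
#' `eog_window_s` of the loss interval. Losses without a concurrent EOG
#' artifact (e.g. tracking dropouts) are returned as ambiguous events for
#' downstream trial exclusion. Retained events are timed with
#' [time_blink_pupil()].
#'
#' @param pupil pupil-size trace (NA = tracking lost).
#' @param eog EOG trace, time-aligned with `pupil`.
#' @param rate sampling rate, Hz.
#' @param eog_window_s co-occurrence window around the loss interval, s.
#' @param eog_z robust z threshold for the EOG artifact.
#' @param duration_bounds_s sanity bounds on blink duration.
#' @return data.frame with columns `onset_s`, `offset_s`, `loss_start_s`,
#'   `loss_end_s`, `source`; attribute `ambiguous` holds flagged loss
#'   intervals (seconds).
#' @export
detect_blinks_pupil <- function(pupil, eog, rate, eog_window_s = 0.1,
                                eog_z = 5,
                                duration_bounds_s = c(0.05, 1)) {
  if (length(pupil) != length(eog))
    stop_hfb("hfbdeconv_alignment_error",
             "pupil and EOG traces must have equal length")
  iv <- loss_intervals(pupil)
  med <- median(eog)
  s <- stats::mad(eog)
  if (s == 0) s <- 1
  out <- list(); amb <- list()
  w <- as.integer(round(eog_window_s * rate))
  for (r in seq_len(nrow(iv))) {
    a <- max(1L, iv[r, 1] - w); b <- min(length(eog), iv[r, 2] + w)
    has_artifact <- max(abs(eog[a:b] - med)) / s > eog_z
    if (!has_artifact) {
      amb[[length(amb) + 1L]] <- (iv[r, ] - 1L) / rate
      next
    }
    tm <- try(time_blink_pupil(pupil, rate, iv[r, ]), silent = TRUE)
    if (inherits(tm, "try-error")) next
    dur <- tm[2] - tm[1]
    if (dur < duration_bounds_s[1] || dur > duration_bounds_s[2]) {
      amb[[length(amb) + 1L]] <- (iv[r, ] - 1L) / rate
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      onset_s = tm[1], offset_s = tm[2],
      loss_start_s = (iv[r, 1] - 1L) / rate,
      loss_end_s = (iv[r, 2] - 1L) / rate,
      source = "pupil", stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               loss_start_s = numeric(0), loss_end_s = numeric(0),
               source = character(0), stringsAsFactors = FALSE)
  attr(res, "ambiguous") <- if (length(amb)) do.call(rbind, amb) else
    matrix(numeric(0), ncol = 2)
  res
}

#' Time a blink from the pupil trace around a loss interval
#'
#' Onset is the time of peak second-derivative magnitude during the
#' pre-loss pupil decrease (the eyelid crossing the pupil); if no such peak
#' exists (instantaneous dropout), the last valid sample before the loss is
#' used. Offset is defined symmetrically on the post-reacquisition increase.
#' Derivatives are taken by central differences on a lightly smoothed trace.
#'
#' @param pupil pupil trace (NA = lost).
#' @param rate Hz.
#' @param loss integer c(start_index, end_index) of the loss run.
#' @param search_s how far before/after the loss to search, s.
#' @param smooth_ms pre-differentiation moving-average width, ms.
#' @return c(onset_s, offset_s).
#' @export
time_blink_pupil <- function(pupil, rate, loss, search_s = 0.2,
                             smooth_ms = 10) {
  if (loss[2] >= length(pupil))
    stop_hfb("hfbdeconv_unterminated_blink",
             "no pupil reacquisition before the end of the recording")
  w <- as.integer(round(search_s * rate))
  pick <- function(idx, direction) {
    seg <- pupil[idx]
    if (any(is.na(seg))) {
      ok <- !is.na(seg)
      first_block <- if (direction < 0) max(which(!ok)) + 1L else NA
      if (direction < 0 && is.finite(first_block) && first_block <= length(seg))
        { idx <- idx[first_block:length(seg)]; seg <- pupil[idx] }
      else { idx <- idx[ok]; seg <- seg[!is.na(seg)] }
    }
    if (length(seg) < 5) return(NA_integer_)
    width <- max(1L, round(smooth_ms / 1000 * rate))
    sm <- smooth_ma(seg, width)
    # central differences; time index of d2[k] is k-1 (one backward diff
    # in d1, one in d2 -> net one-sample lead correction below)
    d1 <- c(0, diff(sm))
    d2 <- c(0, diff(d1)); d2[length(d2)] <- 0
    moving <- if (direction < 0) d1 < 0 else d1 > 0
    # edge padding of the smoother corrupts d2 near the segment boundaries
    edge <- (width %/% 2L) + 2L
    valid <- seq_along(seg) > edge & seq_along(seg) <= length(seg) - edge
    cand <- which(moving & valid & abs(d2) > 0)
    if (!length(cand)) return(NA_integer_)
    idx[cand[which.max(abs(d2[cand]))]] - 1L  # center the second difference
  }
  pre <- max(1L, loss[1] - w):(loss[1] - 1L)
  on_i <- pick(pre, -1L)
  if (is.na(on_i)) on_i <- loss[1] - 1L  # last sample prior to signal loss
  post <- (loss[2] + 1L):min(length(pupil), loss[2] + w)
  off_i <- pick(post, +1L)
  if (is.na(off_i)) off_i <- loss[2] + 1L
  c((on_i - 1L) / rate, (off_i - 1L) / rate)
}

# trapezoid + degree-5 polynomial fit around a blink -------------------------
# nonlinear parameters: start a, rise r, plateau s, fall f (seconds,
# relative to segment start); polynomial coefficients and height enter
# linearly and are profiled out.
fit_eog_blink <- function(seg, rate, center_rel_s, n_starts = 3) {
  ts <- (seq_along(seg) - 1L) / rate
  tt <- 2 * ts / max(ts) - 1  # scaled time for a well-conditioned basis
  basis <- cbind(1, tt, tt^2, tt^3, tt^4, tt^5)
  shape <- function(p) {
    a <- p[1]; r <- max(p[2], 1e-4); s <- max(p[3], 0); f <- max(p[4], 1e-4)
    up <- pmin(pmax((ts - a) / r, 0), 1)
    dn <- pmin(pmax((a + r + s + f - ts) / f, 0), 1)
    pmin(up, dn)
  }
  resid_fn <- function(p) {
    X <- cbind(basis, shape(p))
    co <- tryCatch(qr.coef(qr(X), seg), error = function(e) NULL)
    if (is.null(co) || any(is.na(co))) return(seg)
    seg - X %*% co
  }
  span <- max(ts)
  starts <- lapply(seq_len(n_starts), function(k)
    c(a = max(0, center_rel_s - 0.05 - 0.04 * k), r = 0.04, s = 0.08,
      f = 0.04))
  best <- NULL; best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = c(0, 0.004, 0, 0.004),
                         upper = c(span, 0.3, 0.8, 0.3),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (rss < best_rss) { best_rss <- rss; best <- fit }
  }
  if (is.null(best))
    stop_hfb("hfbdeconv_timing_failure", "trapezoid fit did not converge")
  p <- best$par
  X <- cbind(basis, shape(p))
  co <- qr.coef(qr(X), seg)
  list(par = p, poly_coef = co[1:6], height = co[7],
       baseline = as.numeric(basis %*% co[1:6]),
       trapezoid = as.numeric(shape(p) * co[7]))
}

#' Time a blink from the EOG trace
#'
#' Fits the EOG segment around the blink (+/- `window_s`) with a sum of a
#' fifth-degree polynomial baseline and a trapezoid (free start, rise,
#' plateau and fall times; height and polynomial coefficients profiled out
#' by linear least squares), subtracts the polynomial, and thresholds the
#' cleaned trace at `threshold_frac` of the fitted artifact height: the
#' first up-crossing marks onset and the next down-crossing marks offset.
#'
#' @param eog EOG trace (band-passed 0.2-40 Hz upstream).
#' @param rate Hz.
#' @param approx_time_s approximate blink time, s.
#' @param threshold_frac threshold as a fraction of artifact height
#'   (default 0.22).
#' @param window_s half-window of the fitted segment, s.
#' @param n_starts multistart count for the nonlinear fit.
#' @return c(onset_s, offset_s).
#' @export
time_blink_eog <- function(eog, rate, approx_time_s, threshold_frac = 0.22,
                           window_s = 0.75, n_starts = 3) {
  i0 <- max(1L, as.integer(round((approx_time_s - window_s) * rate)) + 1L)
  i1 <- min(length(eog), as.integer(round((approx_time_s + window_s) * rate)) + 1L)
  seg <- eog[i0:i1]
  center_rel <- approx_time_s - (i0 - 1L) / rate
  fit <- fit_eog_blink(seg, rate, center_rel_s = center_rel,
                       n_starts = n_starts)
  cleaned <- seg - fit$baseline
  if (fit$height <= 0)
    stop_hfb("hfbdeconv_timing_failure", "no positive blink artifact fitted")
  thr <- threshold_frac * fit$height
  above <- cleaned > thr
  up <- which(!head(above, -1) & tail(above, -1)) + 1L
  if (!length(up))
    stop_hfb("hfbdeconv_timing_failure", "no threshold up-crossing")
  on_i <- up[1]
  dn <- which(head(above, -1) & !tail(above, -1)) + 1L
  dn <- dn[dn > on_i]
  if (!length(dn))
    stop_hfb("hfbdeconv_timing_failure", "no threshold down-crossing")
  c((i0 + on_i - 2L) / rate, (i0 + dn[1] - 2L) / rate)
}

#' Calibrate the EOG duration threshold against pupil-derived durations
#'
#' For sessions with both modalities, scans candidate thresholds (fractions
#' of the per-session median spontaneous-blink EOG artifact height) and
#' returns the fraction whose EOG threshold-crossing durations best predict
#' the pupil-derived durations (minimum mean absolute error; ties go to the
#' smallest fraction).
#'
#' @param sessions list of sessions; each a list with `pupil`, `eog`,
#'   `rate`, and a `blinks` data.frame (`onset_s`, `offset_s`, `subtype`).
#' @param fractions candidate fractions in (0, 1).
#' @return the selected fraction; attribute `errors` holds the error curve.
#' @export
calibrate_eog_threshold <- function(sessions, fractions = seq(0.02, 0.98, by = 0.02)) {
  if (!length(sessions))
    stop_hfb("hfbdeconv_no_data", "no calibration sessions supplied")
  per_blink <- list()
  for (ss in sessions) {
    bl <- ss$blinks
    if (is.null(bl) || nrow(bl) == 0) next
    sp <- bl[is.na(bl$subtype) | bl$subtype == "spontaneous", , drop = FALSE]
    if (nrow(sp) == 0) sp <- bl
    for (r in seq_len(nrow(sp))) {
      mid <- (sp$onset_s[r] + sp$offset_s[r]) / 2
      i0 <- max(1L, as.integer(round((mid - 0.75) * ss$rate)) + 1L)
      i1 <- min(length(ss$eog), as.integer(round((mid + 0.75) * ss$rate)) + 1L)
      seg <- ss$eog[i0:i1]
      center_rel <- mid - (i0 - 1L) / ss$rate
      fit <- tryCatch(fit_eog_blink(seg, ss$rate, center_rel_s = center_rel),
                      error = function(e) NULL)
      if (is.null(fit) || fit$height <= 0) next
      per_blink[[length(per_blink) + 1L]] <- list(
        cleaned = seg - fit$baseline, height = fit$height, rate = ss$rate,
        pupil_duration = sp$offset_s[r] - sp$onset_s[r])
    }
  }
  if (!length(per_blink))
    stop_hfb("hfbdeconv_no_data", "no usable blinks for calibration")
  med_h <- median(vapply(per_blink, function(b) b$height, 0))
  errs <- vapply(fractions, function(f) {
    e <- vapply(per_blink, function(b) {
      thr <- f * med_h
      above <- b$cleaned > thr
      up <- which(!head(above, -1) & tail(above, -1)) + 1L
      if (!length(up)) return(NA_real_)
      dn <- which(head(above, -1) & !tail(above, -1)) + 1L
      dn <- dn[dn > up[1]]
      if (!length(dn)) return(NA_real_)
      abs((dn[1] - up[1]) / b$rate - b$pupil_duration)
    }, 0)
    if (all(is.na(e))) Inf else mean(e, na.rm = TRUE)
  }, 0)
  best <- fractions[which.min(errs)]  # which.min takes the first (smallest) tie
  attr(best, "errors") <- data.frame(fraction = fractions, mae_s = errs)
  best
}

#' Iteratively match gaps to blinks by onset latency or duration
#'
#' In each iteration one eligible gap-blink pair (absolute difference within
#' `tolerance_ms`; 50 ms for latency, 15 ms for duration by default) is
#' added, choosing among eligible pairs the one that, after inclusion,
#' minimizes the absolute difference between the mean of the paired gap
#' values and the mean of the paired blink values. Ties are broken by the
#' smallest per-pair difference, then the earliest gap. Matching stops when
#' no eligible pair remains; the paired subsets are equal-sized.
#'
#' @param gaps numeric vector of gap latencies (or durations), ms.
#' @param blinks numeric vector of blink latencies (or durations), ms.
#' @param mode "latency" or "duration" (sets the default tolerance).
#' @param tolerance_ms overrides the default tolerance.
#' @return list with `pairs` (data.frame gap_index, blink_index, gap_value,
#'   blink_value, difference), `mean_gap`, `mean_blink`, and `flagged`
#'   (TRUE when inputs were non-empty but nothing could be paired).
#' @export
match_events <- function(gaps, blinks, mode = c("latency", "duration"),
                         tolerance_ms = NULL) {
  mode <- match.arg(mode)
  if (is.null(tolerance_ms))
    tolerance_ms <- if (mode == "latency") 50 else 15
  empty <- data.frame(gap_index = integer(0), blink_index = integer(0),
                      gap_value = numeric(0), blink_value = numeric(0),
                      difference = numeric(0))
  if (!length(gaps) || !length(blinks))
    return(list(pairs = empty, mean_gap = NA_real_, mean_blink = NA_real_,
                flagged = FALSE))
  free_g <- rep(TRUE, length(gaps)); free_b <- rep(TRUE, length(blinks))
  pg <- numeric(0); pb <- numeric(0)
  rows <- list()
  repeat {
    gi <- which(free_g); bi <- which(free_b)
    if (!length(gi) || !length(bi)) break
    cand <- expand.grid(g = gi, b = bi)
    d <- abs(gaps[cand$g] - blinks[cand$b])
    cand <- cand[d <= tolerance_ms, , drop = FALSE]
    if (!nrow(cand)) break
    obj <- vapply(seq_len(nrow(cand)), function(r)
      abs(mean(c(pg, gaps[cand$g[r]])) - mean(c(pb, blinks[cand$b[r]]))), 0)
    pd <- abs(gaps[cand$g] - blinks[cand$b])
    ord <- order(obj, pd, gaps[cand$g])
    r <- ord[1]
    g <- cand$g[r]; b <- cand$b[r]
    pg <- c(pg, gaps[g]); pb <- c(pb, blinks[b])
    free_g[g] <- FALSE; free_b[b] <- FALSE
    rows[[length(rows) + 1L]] <- data.frame(
      gap_index = g, blink_index = b, gap_value = gaps[g],
      blink_value = blinks[b], difference = gaps[g] - blinks[b])
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else empty
  list(pairs = pairs,
       mean_gap = if (nrow(pairs)) mean(pairs$gap_value) else NA_real_,
       mean_blink = if (nrow(pairs)) mean(pairs$blink_value) else NA_real_,
       flagged = nrow(pairs) == 0)
}
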