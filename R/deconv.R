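# OLS FIR deconvolution with HC3 heteroskedasticity-consistent errors --------

#' Deconvolve overlapping event-related responses by FIR regression
#'
#' Fits the observed HFB timecourse `y` with ordinary least squares on an
#' FIR design, `beta = (X'X)^-1 X'y`, and estimates the standard error of
#' each per-lag coefficient with the HC3 sandwich estimator
#' `(X'X)^-1 X' diag[e_i^2 / (1 - h_ii)^2] X (X'X)^-1`, where `e_i` are the
#' residuals and `h_ii` the leverages (diagonal of the hat matrix). Unlike
#' homoskedastic errors, HC3 error bars reflect the variability of the
#' particular samples contributing to each lag. The solver is a pivoted
#' Cholesky factorization of the normal equations on the sparse design;
#' exactly collinear columns are dropped with a warning (or an error, see
#' `on_singular`) so the printed formulas stay the contract.
#'
#' @param design an `fir_design` from [build_design_matrix()], or a plain
#'   (possibly sparse) matrix.
#' @param y numeric response (HFB percent-change timecourse).
#' @param hc3 compute HC3 standard errors (default TRUE). With FALSE the
#'   leverage pass is skipped too (`$leverages` is NULL), which makes
#'   repeated refits in permutation and split-half loops much cheaper.
#' @param on_singular "drop" collinear columns with a warning, or "error".
#' @param store_vcov keep the full HC3 covariance matrix on the object.
#' @param chunk rows per block in the leverage computation.
#' @return an object of class `fir_deconv`; see [coef.fir_deconv()],
#'   [summary.fir_deconv()], [deconv_trace()], [test_timepoints()].
#' @export
fir_deconv <- function(design, y, hc3 = TRUE,
                       on_singular = c("drop", "error"),
                       store_vcov = FALSE, chunk = 8192L) {
  on_singular <- match.arg(on_singular)
  if (inherits(design, "fir_design")) {
    X <- design$X
    columns <- design$columns
    rate <- design$rate
    if (!is.null(design$keep_rows) && length(y) == design$n_time)
      y <- y[design$keep_rows]
  } else {
    X <- methods::as(methods::as(Matrix::Matrix(design, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    if (is.null(colnames(X)))
      colnames(X) <- paste0("x", seq_len(ncol(X)))
    columns <- data.frame(set = colnames(X), lag_ms = NA_real_, type = "fir",
                          stringsAsFactors = FALSE)
    rate <- NA_real_
  }
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stop_hfb("hfbdeconv_invalid_input", "length(y) != nrow(X)")
  p <- ncol(X)

  XtX <- as.matrix(Matrix::crossprod(X))
  Xty <- as.numeric(Matrix::crossprod(X, y))
  Rpiv <- suppressWarnings(chol(XtX, pivot = TRUE))
  piv <- attr(Rpiv, "pivot")
  rank <- attr(Rpiv, "rank")
  dvals <- diag(Rpiv)
  tol <- max(dvals) * 1e-8
  rank <- min(rank, sum(dvals > tol))
  kept <- sort(piv[seq_len(rank)])
  dropped <- setdiff(seq_len(p), kept)
  if (length(dropped)) {
    msg <- sprintf("rank-deficient design: dropping %d collinear column(s): %s",
                   length(dropped),
                   paste(head(colnames(X)[dropped], 5), collapse = ", "))
    if (on_singular == "error") stop_hfb("hfbdeconv_singular_design", msg)
    warning(msg)
  }
  Xk <- X[, kept, drop = FALSE]
  R <- chol(XtX[kept, kept, drop = FALSE])
  beta_k <- backsolve(R, backsolve(R, Xty[kept], transpose = TRUE))
  fitted <- as.numeric(Xk %*% beta_k)
  e <- y - fitted

  n <- nrow(X)
  se_k <- rep(NA_real_, length(kept))
  V <- NULL
  h <- NULL
  if (hc3) {
    # leverages h_ii = || R^-T x_i ||^2, in row blocks
    h <- numeric(n)
    for (a in seq(1L, n, by = chunk)) {
      b <- min(n, a + chunk - 1L)
      Xc <- as.matrix(Matrix::t(Xk[a:b, , drop = FALSE]))
      Z <- backsolve(R, Xc, transpose = TRUE)
      h[a:b] <- colSums(Z^2)
    }
    sat <- h > 1 - 1e-8
    # a saturated timepoint (leverage 1) is fitted exactly: its residual is
    # 0 and it contributes no variance (dummy-absorbed excluded points).
    # leverage 1 with a nonzero residual cannot arise from a valid fit.
    if (any(sat & abs(e) > 1e-6 * max(1, sd(y))))
      stop_hfb("hfbdeconv_saturated_design",
               "leverage of 1 with nonzero residual at %d timepoint(s)",
               sum(sat & abs(e) > 1e-6 * max(1, sd(y))))
    w <- numeric(n)
    w[!sat] <- (e[!sat] / (1 - h[!sat]))^2
    meat <- as.matrix(Matrix::crossprod(Xk * sqrt(w)))
    XtX_inv <- chol2inv(R)
    V <- XtX_inv %*% meat %*% XtX_inv
    se_k <- sqrt(pmax(diag(V), 0))
  }

  beta <- rep(NA_real_, p); se <- rep(NA_real_, p)
  beta[kept] <- beta_k; se[kept] <- se_k
  names(beta) <- names(se) <- colnames(X)
  columns$beta <- beta
  columns$se <- se

  structure(list(
    coefficients = beta, se = se, columns = columns,
    residuals = e, fitted.values = fitted, leverages = h,
    rank = rank, dropped = colnames(X)[dropped],
    n = n, rate = rate, df.residual = n - rank,
    vcov = if (store_vcov) V else NULL, kept = kept
  ), class = "fir_deconv")
}

#' @export
print.fir_deconv <- function(x, ...) {
  sets <- unique(x$columns$set[x$columns$type == "fir"])
  cat(sprintf("<fir_deconv> n = %d timepoints, %d predictors (rank %d)\n",
              x$n, length(x$coefficients), x$rank))
  cat("  FIR sets:", paste(sets, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  dropped collinear:", length(x$dropped), "column(s)\n")
  invisible(x)
}

#' @export
coef.fir_deconv <- function(object, ...) object$coefficients

#' @export
fitted.fir_deconv <- function(object, ...) object$fitted.values

#' @export
residuals.fir_deconv <- function(object, ...) object$residuals

#' @export
vcov.fir_deconv <- function(object, ...) {
  if (is.null(object$vcov))
    stop_hfb("hfbdeconv_invalid_input",
             "covariance not stored; refit with store_vcov = TRUE")
  object$vcov
}

#' Summarize a deconvolution fit per predictor set
#' @param object an `fir_deconv`.
#' @param ... unused.
#' @return data.frame with one row per FIR set: number of lags, peak and
#'   trough coefficients (% change) and their lags.
#' @export
summary.fir_deconv <- function(object, ...) {
  cols <- object$columns[object$columns$type == "fir", ]
  out <- do.call(rbind, lapply(split(cols, cols$set), function(d) {
    data.frame(set = d$set[1], n_lags = nrow(d),
               peak = max(d$beta, na.rm = TRUE),
               peak_lag_ms = d$lag_ms[which.max(d$beta)],
               trough = min(d$beta, na.rm = TRUE),
               trough_lag_ms = d$lag_ms[which.min(d$beta)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("summary.fir_deconv", "data.frame")
  out
}

#' Extract the deconvolved trace of one predictor set
#' @param fit an `fir_deconv`.
#' @param set predictor-set name.
#' @return data.frame lag_ms, beta, se.
#' @export
deconv_trace <- function(fit, set) {
  d <- fit$columns[fit$columns$set == set & fit$columns$type == "fir", ]
  if (!nrow(d))
    stop_hfb("hfbdeconv_invalid_input", "no predictor set '%s'", set)
  data.frame(lag_ms = d$lag_ms, beta = d$beta, se = d$se)
}

#' Plot deconvolved traces with HC3 error bounds
#' @param x an `fir_deconv`.
#' @param sets predictor sets to draw (default: all FIR sets).
#' @param ci normal-quantile multiple for the band (default 1, i.e. +/-1 SE).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the plotted data.
#' @export
plot.fir_deconv <- function(x, sets = NULL, ci = 1, ...) {
  cols <- x$columns[x$columns$type == "fir", ]
  if (is.null(sets)) sets <- unique(cols$set)
  traces <- lapply(sets, function(s) deconv_trace(x, s))
  ylim <- range(unlist(lapply(traces, function(d)
    c(d$beta - ci * d$se, d$beta + ci * d$se))), na.rm = TRUE)
  pal <- seq_along(sets)
  first <- TRUE
  for (i in seq_along(traces)) {
    d <- traces[[i]]
    if (first) {
      plot(d$lag_ms, d$beta, type = "n", ylim = ylim,
           xlab = "lag (ms)", ylab = "HFB contribution (%)", ...)
      abline(h = 0, col = "gray")
      first <- FALSE
    }
    ok <- !is.na(d$se)
    polygon(c(d$lag_ms[ok], rev(d$lag_ms[ok])),
            c(d$beta[ok] - ci * d$se[ok], rev(d$beta[ok] + ci * d$se[ok])),
            col = grDevices::adjustcolor(pal[i], alpha.f = 0.2), border = NA)
    lines(d$lag_ms, d$beta, col = pal[i])
  }
  graphics::legend("topright", legend = sets, col = pal, lty = 1, bty = "n")
  invisible(traces)
}

#' Per-timepoint inference on deconvolved coefficients
#'
#' Each coefficient is divided by its HC3 standard error and compared to a
#' standard normal (large-sample approximation); p-values are FDR-adjusted
#' across lags within each predictor set, at a q-value of
#' `q / n_electrodes` (within-patient correction for the number of visually
#' responsive electrodes).
#'
#' @param fit an `fir_deconv` with HC3 errors.
#' @param q base q-value (default 0.05).
#' @param n_electrodes number of visually responsive electrodes in the
#'   patient (divides `q`).
#' @return data.frame set, lag_ms, beta, se, z, p, p_fdr, significant.
#' @export
test_timepoints <- function(fit, q = 0.05, n_electrodes = 1L) {
  cols <- fit$columns[fit$columns$type == "fir", ]
  out <- do.call(rbind, lapply(split(cols, cols$set), function(d) {
    z <- d$beta / d$se
    z[d$se == 0 & d$beta == 0] <- 0
    pp <- 2 * pnorm(-abs(z))
    pp[d$se == 0 & d$beta != 0] <- 0
    data.frame(set = d$set, lag_ms = d$lag_ms, beta = d$beta, se = d$se,
               z = z, p = pp, p_fdr = p.adjust(pp, method = "BH"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$significant <- out$p_fdr < q / n_electrodes
  out
}

#' Template-subtraction alternative to deconvolution
#'
#' Forms a per-category mean response template from uninterrupted trials,
#' subtracts it from every trial of that category, and averages
#' interruption-locked segments of the residual. With
#' `subtract_template = FALSE` it returns the naive event-related average,
#' which carries overlap artifacts from the stimulus response.
#'
#' @param y HFB timecourse (one channel, percent change).
#' @param events an `event_table`.
#' @param rate Hz.
#' @param lock "onset" (disappearance) or "offset" (reappearance) locking
#'   of the interruption segments.
#' @param anchors_s optional explicit anchor times (e.g. pseudo-events);
#'   when given, these replace the interruption events.
#' @param window_ms segment window, ms.
#' @param template_window_ms template extent, ms. Defaults to one trial
#'   period, c(0, 1000): templates then tile the block without overlap, so
#'   per-trial subtraction does not double-count the next trial's onset
#'   response (unlike the 1500 ms FIR window used in deconvolution, where
#'   overlap is modeled explicitly).
#' @param subtract_template subtract the uninterrupted-trial template first.
#' @return list with `lags_ms`, `average`, `se` (SE of the mean across
#'   events), `n`, `templates`.
#' @export
template_subtract_average <- function(y, events, rate,
                                      lock = c("onset", "offset"),
                                      anchors_s = NULL,
                                      window_ms = c(-250, 500),
                                      template_window_ms = c(0, 1000),
                                      subtract_template = TRUE) {
  lock <- match.arg(lock)
  stim <- events[events$kind == "stimulus", ]
  intr <- events[events$kind %in% c("gap", "blink"), ]
  resid <- y
  if (subtract_template) {
    interrupted <- unique(intr$trial_index)
    L <- n_fir_columns(template_window_ms, rate)
    for (cc in unique(stim$category)) {
      tr <- stim[stim$category == cc, ]
      un <- tr[!(tr$trial_index %in% interrupted), ]
      if (nrow(un) == 0)
        stop_hfb("hfbdeconv_no_template",
                 "no uninterrupted '%s' trials for a template", cc)
      seg <- vapply(un$onset_s, function(on) {
        i0 <- event_sample(on, rate)
        if (i0 + L - 1L > length(y)) rep(NA_real_, L) else y[i0:(i0 + L - 1L)]
      }, numeric(L))
      template <- rowMeans(seg, na.rm = TRUE)
      for (on in tr$onset_s) {
        i0 <- event_sample(on, rate)
        idx <- i0:(i0 + L - 1L)
        ok <- idx <= length(resid)
        resid[idx[ok]] <- resid[idx[ok]] - template[ok]
      }
    }
  }
  if (is.null(anchors_s))
    anchors_s <- if (lock == "onset") intr$onset_s else intr$offset_s
  if (!length(anchors_s))
    return(list(lags_ms = numeric(0), average = numeric(0), se = numeric(0),
                n = 0L, templates = NULL))
  Lw <- n_fir_columns(window_ms, rate)
  lags_ms <- window_ms[1] + (seq_len(Lw) - 1L) * 1000 / rate
  start_samp <- as.integer(round(window_ms[1] / 1000 * rate))
  segs <- vapply(anchors_s, function(an) {
    i0 <- event_sample(an, rate) + start_samp
    idx <- i0:(i0 + Lw - 1L)
    out <- rep(NA_real_, Lw)
    ok <- idx >= 1L & idx <= length(resid)
    out[ok] <- resid[idx[ok]]
    out
  }, numeric(Lw))
  avg <- rowMeans(segs, na.rm = TRUE)
  nn <- rowSums(!is.na(segs))
  se <- apply(segs, 1L, sd, na.rm = TRUE) / sqrt(pmax(nn, 1))
  list(lags_ms = lags_ms, average = avg, se = se, n = length(anchors_s),
       templates = NULL)
}
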