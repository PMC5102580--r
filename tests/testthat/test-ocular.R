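# blink detection, timing, EOG calibration, gap-blink matching

test_that("clean traces yield no blink events", {
  det <- detect_blinks_pupil(rep(1000, 5000), rnorm(5000), 500)
  expect_equal(nrow(det), 0)
  expect_equal(nrow(attr(det, "ambiguous")), 0)
})

test_that("synthetic blinks are detected and timed against ground truth", {
  cfg <- quick_config(5, n_blocks = 6)
  sch <- generate_schedule(cfg)
  oc <- generate_ocular_channels(cfg, sch)
  det <- detect_blinks_pupil(oc$pupil, oc$eog, oc$rate)
  tru <- oc$blink_truth
  expect_equal(nrow(det), nrow(tru))
  j <- vapply(det$onset_s, function(o) which.min(abs(tru$onset_s - o)), 0L)
  on_err <- det$onset_s - tru$true_onset_s[j]
  off_err <- det$offset_s - tru$true_offset_s[j]
  expect_lt(median(abs(on_err)) * 1000, 5)
  expect_lt(median(abs(off_err)) * 1000, 5)
  # symmetric ramps: recovered duration within 2 samples of truth
  dur_err <- (det$offset_s - det$onset_s) -
    (tru$true_offset_s - tru$true_onset_s)[j]
  expect_true(all(abs(dur_err) <= 2 / oc$rate + 1e-9))
})

test_that("pupil loss without an EOG artifact is flagged ambiguous", {
  set.seed(1)
  n <- 5000
  pupil <- rep(1000, n); pupil[2000:2100] <- NA  # tracking dropout
  eog <- rnorm(n, 0, 2)                          # no artifact
  det <- detect_blinks_pupil(pupil, eog, 500)
  expect_equal(nrow(det), 0)
  expect_equal(nrow(attr(det, "ambiguous")), 1)
})

test_that("pupil onset matches a finite-difference oracle on a sigmoid ramp", {
  rate <- 500
  t <- (seq_len(4000) - 1) / rate
  m <- 4; tau <- 0.02
  p <- 1000 * (1 - 1 / (1 + exp(-(t - m) / tau)))
  lost <- p < 400
  p[lost] <- NA
  # reopen late so the loss terminates
  p[t > m + 1] <- 1000
  loss <- range(which(is.na(p)))
  tm <- time_blink_pupil(p, rate, loss, smooth_ms = 0)
  # oracle: finite differences on the same measured (pre-loss) segment
  pre <- (loss[1] - 100):(loss[1] - 1)
  seg <- p[pre]
  d2 <- c(0, diff(c(0, diff(seg))))
  d1 <- c(0, diff(seg))
  cand <- which(d1 < 0 & seq_along(seg) > 4 & seq_along(seg) < length(seg) - 4)
  oracle <- (pre[cand[which.max(abs(d2[cand]))]] - 2) / rate
  expect_lt(abs(tm[1] - oracle), 1.5 / rate)
})

test_that("instantaneous dropout falls back to the last pre-loss sample", {
  rate <- 500
  p <- rep(1000, 3000)
  p[1000:1100] <- NA                    # step loss, no decrease before
  tm <- time_blink_pupil(p, rate, c(1000L, 1100L))
  expect_equal(tm[1], (999 - 1) / rate)
})

test_that("unterminated loss signals an error", {
  p <- rep(1000, 1000); p[900:1000] <- NA
  expect_error(time_blink_pupil(p, 500, c(900L, 1000L)),
               class = "hfbdeconv_unterminated_blink")
})

test_that("EOG trapezoid timing recovers construction within 8 ms", {
  set.seed(11)
  rate <- 500
  t <- (seq_len(3000) - 1) / rate
  drift <- 5 * (t - 3)^3 - 2 * t       # cubic drift
  blink_on <- 3.0; blink_off <- 3.12
  trap <- hfbdeconv:::trapezoid_wave
  x <- drift + trap(t, blink_on, blink_off, 0.04, 0.04, 100) +
    rnorm(length(t), 0, 1)
  tm <- time_blink_eog(x, rate, approx_time_s = 3.06, threshold_frac = 0.5)
  expect_lt(abs(tm[1] - blink_on) * 1000, 8)
  expect_lt(abs(tm[2] - blink_off) * 1000, 8)
  # drift-free case: fitted polynomial is negligible next to the artifact
  x2 <- trap(t, blink_on, blink_off, 0.04, 0.04, 100)
  i0 <- round((3.06 - 0.75) * rate) + 1
  seg <- x2[i0:(i0 + round(1.5 * rate))]
  fit <- hfbdeconv:::fit_eog_blink(seg, rate, 0.75)
  expect_lt(max(abs(fit$baseline)), 1)
  # pure polynomial, no artifact -> timing failure
  expect_error(time_blink_eog(drift, rate, 3.0),
               class = "hfbdeconv_timing_failure")
})

test_that("EOG threshold calibration recovers the optimum of the construction", {
  cfg <- quick_config(21, n_blocks = 6)
  sch <- generate_schedule(cfg)
  oc <- generate_ocular_channels(cfg, sch)
  # target durations: the physical (scheduled) occlusions, which the EOG
  # trapezoid's half-height width encodes by construction
  sess <- list(list(pupil = oc$pupil, eog = oc$eog, rate = oc$rate,
                    blinks = data.frame(onset_s = oc$blink_truth$onset_s,
                                        offset_s = oc$blink_truth$offset_s,
                                        subtype = oc$blink_truth$subtype)))
  thr <- calibrate_eog_threshold(sess, fractions = seq(0.05, 0.95, by = 0.05))
  errs <- attr(thr, "errors")
  # grid-search oracle: the returned fraction attains the minimum error
  expect_equal(min(errs$mae_s), errs$mae_s[errs$fraction == as.numeric(thr)])
  # and the calibrated threshold predicts durations to within ~5 ms
  expect_lt(min(errs$mae_s), 0.005)
  # symmetric trapezoid ramps put the optimum near half height
  expect_lt(abs(as.numeric(thr) - 0.5), 0.2)
  expect_error(calibrate_eog_threshold(list()), class = "hfbdeconv_no_data")
})

test_that("latency matching pairs within tolerance and minimizes mean difference", {
  m <- match_events(c(350, 550, 750), c(360, 540, 900), "latency")
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$pairs$gap_value, c(350, 550))
  expect_equal(m$pairs$blink_value, c(360, 540))
  expect_false(m$flagged)
  expect_true(all(abs(m$pairs$difference) <= 50))
  # identical lists pair fully with zero mean difference
  m2 <- match_events(c(100, 200, 300), c(100, 200, 300), "latency")
  expect_equal(nrow(m2$pairs), 3)
  expect_equal(m2$mean_gap, m2$mean_blink)
  # tolerance violation -> empty, flagged
  m3 <- match_events(100, 200, "latency")
  expect_equal(nrow(m3$pairs), 0)
  expect_true(m3$flagged)
  # empty inputs are not an error and not flagged
  m4 <- match_events(numeric(0), c(1, 2), "latency")
  expect_equal(nrow(m4$pairs), 0)
  expect_false(m4$flagged)
  # duration mode default tolerance is 15 ms
  m5 <- match_events(c(100, 150), c(120, 160), "duration")
  expect_equal(nrow(m5$pairs), 1)
  expect_true(all(abs(m5$pairs$difference) <= 15))
})

test_that("matching is a matching: no event used twice, equal subset sizes", {
  set.seed(3)
  for (k in 1:20) {
    g <- runif(8, 0, 1000); b <- runif(10, 0, 1000)
    m <- match_events(g, b, "latency")
    expect_equal(anyDuplicated(m$pairs$gap_index), 0)
    expect_equal(anyDuplicated(m$pairs$blink_index), 0)
    expect_true(all(abs(m$pairs$difference) <= 50))
    if (nrow(m$pairs))
      expect_lte(abs(m$mean_gap - m$mean_blink), 50)
  }
})
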