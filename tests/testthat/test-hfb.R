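# preprocessing: referencing, envelope extraction, outlier scan, normalisation

test_that("common average reference subtracts the across-channel mean", {
  set.seed(1)
  m <- matrix(rnorm(30), 3, 10)
  rec <- common_average_reference(raw_recording(m, 500))
  expect_lt(max(abs(colMeans(rec$samples))), 1e-12)
  # two opposite channels are unchanged
  a <- rnorm(10)
  rec2 <- common_average_reference(raw_recording(rbind(a, -a), 500))
  expect_equal(unname(rec2$samples), unname(rbind(a, -a)))
  # identical channels become zero
  rec3 <- common_average_reference(raw_recording(rbind(a, a), 500))
  expect_true(all(rec3$samples == 0))
  expect_error(common_average_reference(raw_recording(matrix(a, 1), 500)),
               class = "hfbdeconv_insufficient_channels")
})

test_that("excluded channels do not enter the common average", {
  a <- rep(1, 10); b <- rep(3, 10); huge <- rep(1000, 10)
  rec <- raw_recording(rbind(a, b, huge), 500,
                       channel_names = c("a", "b", "bad"),
                       excluded_channels = "bad")
  out <- common_average_reference(rec)
  expect_equal(unname(out$samples["a", ]), rep(-1, 10))
  expect_equal(unname(out$samples["b", ]), rep(1, 10))
})

test_that("constant-amplitude carriers give flat unit-mean envelopes", {
  rate <- 500; n <- rate * 30
  t <- (seq_len(n) - 1) / rate
  # single in-band sinusoid: unit mean by per-band normalisation
  rec <- raw_recording(matrix(20 * sin(2 * pi * 110 * t), 1), rate)
  h <- extract_hfb(rec)
  expect_equal(h$rate, 250)
  expect_lt(abs(mean(h$values) - 1), 0.01)
  # broadband constant-amplitude carrier: flat output
  set.seed(6)
  x <- synth_raw_channel(n, rate, modulator = NULL, background_sd = 0)
  h2 <- extract_hfb(raw_recording(matrix(x, 1), rate))
  expect_lt(abs(mean(h2$values) - 1), 0.01)
  expect_lt(sd(h2$values) / mean(h2$values), 0.1)
})

test_that("white-noise input yields temporal mean within 1 percent of 1", {
  set.seed(4)
  rec <- raw_recording(matrix(rnorm(500 * 40), 1), 500)
  h <- extract_hfb(rec)
  expect_lt(abs(mean(h$values) - 1), 0.01)
})

test_that("the extracted envelope tracks an in-band 2 Hz amplitude modulator", {
  set.seed(2)
  rate <- 500; n <- rate * 60
  t <- (seq_len(n) - 1) / rate
  mod <- sin(2 * pi * 2 * t)
  x <- synth_raw_channel(n, rate, modulator = mod, depth = 0.5,
                         background_sd = 3)
  h <- extract_hfb(raw_recording(matrix(x, 1), rate))
  mod250 <- mod[seq(1, n, 2)][seq_len(ncol(h$values))]
  expect_gt(cor(h$values[1, ], mod250), 0.9)
})

test_that("out-of-band modulation leaves the envelope uncorrelated", {
  set.seed(3)
  rate <- 500; n <- rate * 60
  t <- (seq_len(n) - 1) / rate
  mod <- sin(2 * pi * 30 * t)
  x <- synth_raw_channel(n, rate, modulator = mod, depth = 0.8,
                         carrier_band = c(35, 45), n_components = 2,
                         background_sd = 0)
  h <- extract_hfb(raw_recording(matrix(x, 1), rate))
  m <- mod[seq(1, n, 2)][seq_len(ncol(h$values))]
  expect_lt(abs(cor(h$values[1, ], m)), 0.1)
})

test_that("zero-phase filtering preserves the peak time of a symmetric pulse", {
  rate <- 500; n <- rate * 20
  t <- (seq_len(n) - 1) / rate
  am <- exp(-0.5 * ((t - 10) / 0.5)^2)      # symmetric envelope, peak at 10 s
  x <- sin(2 * pi * 110 * t) * am * 20
  h <- extract_hfb(raw_recording(matrix(x, 1), rate))
  pk <- (which.max(h$values[1, ]) - 1) / h$rate
  expect_lt(abs(pk - 10), 1 / h$rate * 2 + 1e-9)
})

test_that("outlier scan flags synchronized artifacts but spares single channels", {
  rate <- 250; n <- 2500
  set.seed(9)
  base <- matrix(rnorm(11 * n), 11, n)
  h0 <- hfb_timecourse(base, rate)
  # constant channels -> empty mask (sd fallback keeps z finite)
  hconst <- hfb_timecourse(matrix(1, 3, n), rate)
  expect_equal(sum(reject_outliers(hconst)$rejection_mask), 0)
  # synchronized step on all channels
  step <- base; step[, 1250:n] <- step[, 1250:n] + 50
  hs <- reject_outliers(hfb_timecourse(step, rate))
  expect_true(hs$rejection_mask[1250])
  w <- round(0.2 * rate)
  expect_true(all(hs$rejection_mask[(1250 - w):(1250 + w)]))
  # dilation bound: every masked point is within 200 ms of a flagged one
  expect_true(all(which(hs$rejection_mask) >= 1250 - w))
  # artifact on 1 of 11 channels leaves the median untouched
  one <- base; one[4, 1250] <- one[4, 1250] + 500
  h1 <- reject_outliers(hfb_timecourse(one, rate))
  expect_false(h1$rejection_mask[1250])
})

test_that("baseline normalisation maps the baseline mean to 0 percent", {
  rate <- 250
  iv <- cbind(0, 1)
  x <- rep(2, 500)                     # trace identically 2x baseline of 2
  h <- hfb_timecourse(matrix(x, 1), rate, baseline_intervals = iv)
  hn <- baseline_normalize(h)
  expect_true(all(hn$values == 0))
  x2 <- c(rep(1, 250), rep(2, 250))    # baseline 1, rest 2x
  h2 <- baseline_normalize(hfb_timecourse(matrix(x2, 1), rate,
                                          baseline_intervals = iv))
  expect_equal(unname(h2$values[1, 300]), 100)
  set.seed(2)
  x3 <- runif(500, 0.5, 1.5)
  h3 <- baseline_normalize(hfb_timecourse(matrix(x3, 1), rate,
                                          baseline_intervals = iv))
  expect_lt(abs(mean(h3$values[1, seq_len(250)])), 1e-10)
  expect_error(baseline_normalize(h3, cbind(numeric(0), numeric(0))),
               class = "hfbdeconv_no_baseline")
})
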