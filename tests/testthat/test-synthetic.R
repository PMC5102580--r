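# synthetic session generator: schedule structure, determinism, linearity

test_that("schedule has the block structure of the task", {
  cfg <- sim_config(n_blocks = 32, seed = 42)
  sch <- generate_schedule(cfg)
  stim <- sch[sch$kind == "stimulus", ]
  expect_equal(nrow(stim), 320)
  # inter-onset interval exactly 1000 ms within blocks
  for (b in unique(stim$block_index)) {
    on <- stim$onset_s[stim$block_index == b]
    expect_equal(diff(on), rep(1, 9), tolerance = 1e-12)
  }
  # gaps only at the configured latencies
  gaps <- sch[sch$kind == "gap", ]
  stim_on <- stim$onset_s[match(gaps$trial_index, stim$trial_index)]
  lat <- round((gaps$onset_s - stim_on) * 1000)
  expect_true(all(lat %in% c(350, 550, 750)))
  dur <- (gaps$offset_s - gaps$onset_s) * 1000
  expect_true(all(dur >= 99 & dur <= 201))
})

test_that("identical seeds give bit-identical schedules and signals", {
  cfg <- quick_config(99, n_blocks = 3)
  s1 <- generate_schedule(cfg); s2 <- generate_schedule(cfg)
  expect_identical(s1, s2)
  tr <- default_ground_truth("V1", rate = 25)
  h1 <- generate_hfb_session(cfg, tr, s1)
  h2 <- generate_hfb_session(cfg, tr, s2)
  expect_identical(h1$values, h2$values)
})

test_that("voluntary_block_fraction = 0 yields no voluntary blinks", {
  cfg <- quick_config(7, voluntary_block_fraction = 0)
  sch <- generate_schedule(cfg)
  expect_equal(sum(sch$kind == "blink" & sch$subtype == "voluntary"), 0)
})

test_that("gap counts stay within the binomial 99% interval across seeds", {
  counts <- vapply(1:12, function(s) {
    cfg <- sim_config(n_blocks = 4, voluntary_block_fraction = 0,
                      spontaneous_blink_rate_hz = 0, seed = s)
    sum(generate_schedule(cfg)$kind == "gap")
  }, 0L)
  n_trials <- 4 * 10 * 12
  ci <- qbinom(c(0.005, 0.995), n_trials, 0.6)
  expect_gte(sum(counts), ci[1])
  expect_lte(sum(counts), ci[2])
})

test_that("events are consistent: onset < offset, inside their trial, and gaps never overlap blinks", {
  sch <- generate_schedule(quick_config(13, n_blocks = 8, animal = 0.2))
  ev <- sch[sch$kind %in% c("gap", "blink"), ]
  expect_true(all(ev$onset_s < ev$offset_s))
  stim <- sch[sch$kind == "stimulus", ]
  tr_on <- stim$onset_s[match(ev$trial_index, stim$trial_index)]
  tr_off <- stim$offset_s[match(ev$trial_index, stim$trial_index)]
  expect_true(all(ev$onset_s >= tr_on - 1e-9 & ev$offset_s <= tr_off + 1e-9))
  gaps <- ev[ev$kind == "gap", ]; blinks <- ev[ev$kind == "blink", ]
  for (r in seq_len(nrow(gaps))) {
    same <- blinks[blinks$trial_index == gaps$trial_index[r], ]
    if (nrow(same))
      expect_true(all(same$offset_s <= gaps$onset_s[r] |
                        same$onset_s >= gaps$offset_s[r]))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(gap_latencies_ms = c(350, 1000)),
               class = "hfbdeconv_invalid_config")
  expect_error(sim_config(gap_duration_range_ms = c(0, 100)),
               class = "hfbdeconv_invalid_config")
  expect_error(sim_config(category_probs = c(face = 0.5, nonface = 0.1,
                                             animal = 0.1)),
               class = "hfbdeconv_invalid_config")
})

test_that("HFB sessions are exactly linear in the events", {
  rate <- 25
  cfg <- quick_config(3, n_blocks = 2, noise = list(kind = "ar1", ar = 0, sd = 0))
  tr <- default_ground_truth("V1", rate = rate)
  sch <- generate_schedule(cfg)
  h <- generate_hfb_session(cfg, tr, sch)
  # rebuild by hand from the kernels
  n <- ncol(h$values)
  y <- numeric(n)
  add <- function(y, k, t0) {
    i0 <- round(t0 * rate) + 1 + round(k$window_ms[1] * rate / 1000)
    idx <- i0:(i0 + length(k$values) - 1)
    ok <- idx >= 1 & idx <= n
    y[idx[ok]] <- y[idx[ok]] + k$values[ok]
    y
  }
  for (r in which(sch$kind == "stimulus")) {
    kk <- if (sch$category[r] == "face") tr$kernels[[1]]$stimulus$face else
      tr$kernels[[1]]$stimulus$nonface
    y <- add(y, kk, sch$onset_s[r])
  }
  for (r in which(sch$kind %in% c("gap", "blink"))) {
    ty <- if (sch$kind[r] == "gap") "gap" else sch$subtype[r]
    y <- add(y, tr$kernels[[1]]$disappearance[[ty]], sch$onset_s[r])
    y <- add(y, tr$kernels[[1]]$reappearance[[ty]], sch$offset_s[r])
  }
  expect_equal(h$values[1, ], y, tolerance = 1e-12)
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  set.seed(1)
  x <- ar1_noise(1e5, ar = 0.8, sd = 2)
  expect_lt(abs(cor(x[-1], x[-length(x)]) - 0.8), 0.05)
  expect_lt(abs(sd(x) - 2), 0.1)
})

test_that("ocular channels encode blinks recoverably", {
  cfg <- quick_config(5, n_blocks = 4)
  sch <- generate_schedule(cfg)
  oc <- generate_ocular_channels(cfg, sch)
  n_blinks <- sum(sch$kind == "blink")
  expect_equal(nrow(oc$blink_truth), n_blinks)
  # pupil lost during every blink
  for (r in seq_len(nrow(oc$blink_truth))) {
    mid <- round((oc$blink_truth$onset_s[r] + oc$blink_truth$offset_s[r]) / 2 *
                   oc$rate)
    expect_true(is.na(oc$pupil[mid]))
  }
  # no blinks -> no missing samples
  cfg0 <- quick_config(5, n_blocks = 2, voluntary_block_fraction = 0,
                       spontaneous_blink_rate_hz = 0)
  sch0 <- generate_schedule(cfg0)
  oc0 <- generate_ocular_channels(cfg0, sch0)
  expect_false(any(is.na(oc0$pupil)))
})

test_that("EOG trapezoid support at half height matches the blink duration", {
  t <- seq(0, 2, by = 1 / 500)
  w <- hfbdeconv:::trapezoid_wave(t, 1, 1.15, 0.04, 0.04, 100)
  above <- t[w > 50]
  expect_lt(abs((max(above) - min(above)) - 0.15), 0.01)
})

test_that("peak pupil deceleration precedes full signal loss", {
  cfg <- quick_config(8, n_blocks = 4)
  sch <- generate_schedule(cfg)
  oc <- generate_ocular_channels(cfg, sch)
  iv <- hfbdeconv:::loss_intervals(oc$pupil)
  tru <- oc$blink_truth
  for (r in seq_len(min(5, nrow(tru)))) {
    loss_start <- (iv[which.min(abs(iv[, 1] / oc$rate - tru$onset_s[r])), 1] - 1) /
      oc$rate
    expect_lt(tru$true_onset_s[r], loss_start)
  }
})
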