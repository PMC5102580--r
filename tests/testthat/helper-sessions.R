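# shared fixtures built in code

# fast desk-scale config: coarse HFB grid, no animal targets unless asked
quick_config <- function(seed, n_blocks = 6, rate_hfb = 25,
                         noise = list(kind = "ar1", ar = 0.9, sd = 1),
                         animal = 0, ...) {
  sim_config(n_blocks = n_blocks, rate_hfb = rate_hfb, noise = noise,
             category_probs = c(face = 0.3, nonface = 0.7 - animal,
                                animal = animal),
             seed = seed, ...)
}

# ground truth with all interruption kernels zeroed (null electrode)
null_truth <- function(rate = 25, roi = "V1",
                       window_ms = c(-250, 500)) {
  tr <- default_ground_truth(roi, rate = rate,
                             interruption_window_ms = window_ms)
  for (e in seq_along(tr$kernels)) {
    z <- kernel_zero(rate, window_ms)
    tr$kernels[[e]]$disappearance <- list(gap = z, voluntary = z,
                                          spontaneous = z)
    tr$kernels[[e]]$reappearance <- list(gap = z, voluntary = z,
                                         spontaneous = z)
  }
  tr
}

# one-channel session; returns list(y, schedule, rate, truth)
quick_session <- function(seed, truth = NULL, rate_hfb = 25, ...) {
  cfg <- quick_config(seed, rate_hfb = rate_hfb, ...)
  sch <- generate_schedule(cfg)
  if (is.null(truth)) truth <- default_ground_truth("V1", rate = rate_hfb)
  h <- generate_hfb_session(cfg, truth, sch)
  list(y = h$values[1, ], hfb = h, schedule = sch, rate = rate_hfb,
       truth = truth, config = cfg)
}

# combined onset+offset-locked design over a schedule (fully modeled world)
full_design <- function(schedule, n_time, rate, excluded = integer(0)) {
  on <- predictor_sets(schedule, "onset", split_by_category = FALSE)
  off <- predictor_sets(schedule, "offset", split_by_category = FALSE)
  off <- off[!startsWith(names(off), "stimulus")]
  names(off) <- paste0(names(off), "_off")
  build_design_matrix(c(on, off), n_time, rate, excluded = excluded)
}

kernel_lags_ms_pkg <- function(k) hfbdeconv:::kernel_lags_ms(k)

# brute-force oracle: largest |integral| over all strictly same-sign runs
cluster_oracle <- function(beta, lags_ms, sign_dir, search_start_ms = 0) {
  dt <- diff(lags_ms[1:2]) / 1000
  keep <- lags_ms >= search_start_ms
  best <- 0; best_iv <- NULL
  n <- length(beta)
  for (a in seq_len(n)) for (b in a:n) {
    idx <- a:b
    if (!all(keep[idx])) next
    vals <- beta[idx]
    if (sign_dir > 0 && !all(vals > 0)) next
    if (sign_dir < 0 && !all(vals < 0)) next
    # must be maximal: not extendable on either side
    if (a > 1 && keep[a - 1] &&
        ((sign_dir > 0 && beta[a - 1] > 0) || (sign_dir < 0 && beta[a - 1] < 0)))
      next
    if (b < n && keep[b + 1] &&
        ((sign_dir > 0 && beta[b + 1] > 0) || (sign_dir < 0 && beta[b + 1] < 0)))
      next
    integral <- sum(vals) * dt
    if (abs(integral) > abs(best)) { best <- integral; best_iv <- c(lags_ms[a], lags_ms[b]) }
  }
  list(integral = best, interval_ms = best_iv)
}
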