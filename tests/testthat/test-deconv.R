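# design construction, OLS, HC3, per-timepoint inference, template subtraction

test_that("FIR windows tile into the expected column counts", {
  expect_equal(n_fir_columns(c(0, 1500), 250), 375L)
  expect_equal(n_fir_columns(c(-250, 500), 250), 187L)
  # partial trailing bin is discarded, never rounded up
  expect_equal(n_fir_columns(c(0, 1502), 250), 375L)
  expect_equal(n_fir_columns(c(0, 1504), 250), 376L)
})

test_that("design matrix has one pulse per event per lag and unit dummies", {
  sets <- list(a = list(onsets_s = c(1, 2.5), window_ms = c(0, 100)))
  d <- build_design_matrix(sets, n_time = 2000, rate = 250,
                           excluded = c(5L, 9L, 700L))
  n_lags <- n_fir_columns(c(0, 100), 250)
  expect_equal(ncol(d$X), n_lags + 3L)
  fir <- d$X[, d$columns$type == "fir", drop = FALSE]
  expect_true(all(Matrix::colSums(fir) == 2))       # one 1 per event
  expect_true(all(fir@x == 1))
  dum <- d$X[, d$columns$type == "dummy", drop = FALSE]
  expect_true(all(Matrix::colSums(dum) == 1))
  expect_equal(which(as.matrix(dum[, 1]) == 1), 5L)
  # pulses land at event sample + lag
  i0 <- round(1 * 250) + 1
  expect_equal(which(as.matrix(fir[, 1]) == 1), c(i0, round(2.5 * 250) + 1))
  expect_equal(which(as.matrix(fir[, 2]) == 1), c(i0 + 1, round(2.5 * 250) + 2))
})

test_that("dummy-column and row-dropping exclusion give identical fits", {
  s <- quick_session(31, rate_hfb = 25, animal = 0.2)
  excl <- excluded_timepoints(s$schedule, length(s$y), s$rate)
  expect_gt(length(excl), 0)
  sets <- predictor_sets(s$schedule, "offset", split_by_category = FALSE)
  d1 <- build_design_matrix(sets, length(s$y), s$rate, excl, "dummy")
  d2 <- build_design_matrix(sets, length(s$y), s$rate, excl, "drop")
  f1 <- suppressWarnings(fir_deconv(d1, s$y))
  f2 <- suppressWarnings(fir_deconv(d2, s$y))
  fir <- d1$columns$type == "fir"
  expect_equal(f1$coefficients[fir], f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$se[fir], f2$se, tolerance = 1e-6)
})

test_that("OLS matches closed forms and an independent oracle", {
  # identity design returns y
  f <- fir_deconv(diag(4), c(1, -2, 0, 7), hc3 = FALSE)
  expect_equal(unname(f$coefficients), c(1, -2, 0, 7))
  # ones column returns the mean
  f2 <- fir_deconv(matrix(1, 3, 1), c(0, 0, 3))
  expect_equal(unname(f2$coefficients), 1)
  # random design vs normal-equations pseudo-inverse oracle
  set.seed(8)
  X <- matrix(rnorm(250), 50, 5); y <- rnorm(50)
  f3 <- fir_deconv(X, y)
  oracle <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_equal(unname(f3$coefficients), as.numeric(oracle), tolerance = 1e-8)
  # residual orthogonality and leverage identities
  expect_lt(max(abs(t(X) %*% f3$residuals)), 1e-10)
  expect_true(all(f3$leverages >= -1e-12 & f3$leverages <= 1 + 1e-12))
  expect_equal(sum(f3$leverages), f3$rank, tolerance = 1e-10)
})

test_that("HC3 standard errors match the printed formula and sandwich", {
  # hand evaluation: X = ones(3), y = (0,0,3): var = 1.5
  f <- fir_deconv(matrix(1, 3, 1), c(0, 0, 3))
  expect_equal(unname(f$se), sqrt(1.5), tolerance = 1e-12)
  skip_if_not_installed("sandwich")
  set.seed(10)
  for (k in 1:3) {
    X <- matrix(rnorm(250), 50, 5); y <- rnorm(50)
    f <- fir_deconv(X, y)
    lmf <- lm(y ~ X - 1)
    se_o <- sqrt(diag(sandwich::vcovHC(lmf, type = "HC3")))
    expect_equal(unname(f$se), unname(se_o), tolerance = 1e-8)
  }
})

test_that("perfect fit gives zero standard errors", {
  X <- diag(3)
  f <- fir_deconv(X, c(1, 2, 3) * 0)
  expect_equal(unname(f$se), c(0, 0, 0))
})

test_that("HC3 approaches classical OLS errors under homoskedasticity", {
  set.seed(12)
  n <- 4000
  X <- matrix(rnorm(n * 3), n, 3); y <- X %*% c(1, 0, -1) + rnorm(n)
  f <- fir_deconv(X, y)
  lmf <- lm(y ~ X - 1)
  se_cl <- sqrt(diag(vcov(lmf)))
  expect_true(all(abs(f$se / se_cl - 1) < 0.1))
})

test_that("collinear columns are dropped with a warning or raise an error", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_warning(f <- fir_deconv(X, c(1, 2, 3, 5)), "collinear")
  expect_equal(f$rank, 2)
  expect_error(fir_deconv(X, c(1, 2, 3, 5), on_singular = "error"),
               class = "hfbdeconv_singular_design")
})

test_that("noiseless fully modeled session is recovered exactly", {
  rate <- 25
  cfg <- quick_config(3, n_blocks = 4, noise = list(kind = "ar1", ar = 0, sd = 0))
  sch <- generate_schedule(cfg)
  tr <- default_ground_truth("V1", rate = rate)
  h <- generate_hfb_session(cfg, tr, sch)
  y <- h$values[1, ]
  fit <- fir_deconv(full_design(sch, length(y), rate), y)
  for (nm in c("gap", "spontaneous", "voluntary")) {
    expect_equal(deconv_trace(fit, nm)$beta,
                 tr$kernels[[1]]$disappearance[[nm]]$values,
                 tolerance = 1e-10)
    expect_equal(deconv_trace(fit, paste0(nm, "_off"))$beta,
                 tr$kernels[[1]]$reappearance[[nm]]$values,
                 tolerance = 1e-10)
  }
})

test_that("z-tests and FDR behave at the reference points", {
  fit <- list(columns = data.frame(
    set = "a", lag_ms = c(0, 4, 8), type = "fir",
    beta = c(0, 1.959964, 10), se = c(1, 1, 0)))
  class(fit) <- "fir_deconv"
  tt <- test_timepoints(fit)
  expect_equal(tt$p[1], 1)
  expect_lt(abs(tt$p[2] - 0.05), 1e-6)
  expect_equal(tt$p[3], 0)  # zero SE with nonzero beta: infinitely precise
})

test_that("template subtraction matches deconvolution in a noiseless low-overlap world", {
  # gaps only, all at 550 ms with a fixed duration, zero reappearance
  # kernels: interruption windows never overlap and the dip kernel is the
  # unique answer for both estimators
  rate <- 25
  cfg <- quick_config(17, n_blocks = 6,
                      noise = list(kind = "ar1", ar = 0, sd = 0),
                      voluntary_block_fraction = 0,
                      spontaneous_blink_rate_hz = 0,
                      gap_latencies_ms = 550,
                      gap_duration_range_ms = c(150, 150))
  sch <- generate_schedule(cfg)
  tr <- default_ground_truth("V1", rate = rate)
  tr$kernels[[1]]$stimulus$face <- tr$kernels[[1]]$stimulus$nonface
  tr$kernels[[1]]$reappearance$gap <- kernel_zero(rate, c(-250, 500))
  h <- generate_hfb_session(cfg, tr, sch)
  y <- h$values[1, ]
  ts <- template_subtract_average(y, sch, rate, lock = "onset")
  fit <- fir_deconv(build_design_matrix(
    predictor_sets(sch, "onset", split_by_category = FALSE),
    length(y), rate), y, hc3 = FALSE)
  dec <- deconv_trace(fit, "gap")
  kd <- tr$kernels[[1]]$disappearance$gap$values
  expect_lt(max(abs(dec$beta - kd)), 1e-8)        # deconvolution exact
  lag_in <- ts$lags_ms >= 0 & ts$lags_ms <= 400   # away from template edges
  expect_lt(max(abs(ts$average[lag_in] - dec$beta[lag_in])), 0.15)
  # no uninterrupted trials -> no template
  intr <- sch[sch$kind == "gap", ]
  sch2 <- sch[sch$kind != "stimulus" | sch$trial_index %in% intr$trial_index, ]
  attr(sch2, "duration_s") <- attr(sch, "duration_s")
  expect_error(template_subtract_average(y, sch2, rate),
               class = "hfbdeconv_no_template")
  # zero interruption events -> empty output
  none <- sch[sch$kind == "stimulus", ]
  attr(none, "duration_s") <- attr(sch, "duration_s")
  out <- template_subtract_average(y, none, rate)
  expect_equal(out$n, 0L)
})
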