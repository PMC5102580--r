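#' Ground-truth response kernels for simulation
#'
#' A kernel is the deterministic HFB contribution (percent signal change) of
#' one event, defined over a finite lag window on a sampling grid. Sessions
#' are generated as exact linear superpositions of kernels plus noise, so the
#' FIR deconvolution can be validated against known truth.
#'
#' @param rate sampling rate of the kernel grid, Hz.
#' @param window_ms c(start, end) lag window in ms (half-open).
#' @param values amplitude at each 1/rate bin of the window (% change).
#' @return an object of class `hfb_kernel`.
#' @export
hfb_kernel <- function(values, window_ms, rate) {
  structure(list(values = values, window_ms = window_ms, rate = rate),
            class = "hfb_kernel")
}

kernel_lags_ms <- function(k) {
  dt <- 1000 / k$rate
  seq(k$window_ms[1], by = dt, length.out = length(k$values))
}

#' Gaussian-bump kernel
#'
#' @param rate grid rate, Hz.
#' @param window_ms lag window, ms.
#' @param center_ms,sd_ms bump location and width, ms.
#' @param amplitude peak amplitude, % change (negative for a dip).
#' @return an `hfb_kernel`.
#' @export
kernel_bump <- function(rate, window_ms, center_ms, sd_ms, amplitude) {
  lags <- seq(window_ms[1], window_ms[2] - 1000 / rate, by = 1000 / rate)
  v <- amplitude * exp(-0.5 * ((lags - center_ms) / sd_ms)^2)
  v[abs(lags - center_ms) > 4 * sd_ms] <- 0  # finite support
  hfb_kernel(v, window_ms, rate)
}

#' Stimulus-response kernel: fast transient plus decaying sustained activity
#'
#' @param rate grid rate, Hz.
#' @param window_ms lag window, ms (default 0-1500).
#' @param peak peak transient amplitude, % change.
#' @param sustained plateau amplitude, % change.
#' @param peak_ms transient latency, ms.
#' @param decay_ms sustained-component decay constant, ms.
#' @return an `hfb_kernel`.
#' @export
kernel_stimulus <- function(rate, window_ms = c(0, 1500), peak = 10,
                            sustained = 3, peak_ms = 150, decay_ms = 600) {
  lags <- seq(window_ms[1], window_ms[2] - 1000 / rate, by = 1000 / rate)
  tr <- ifelse(lags > 0, (lags / peak_ms) * exp(1 - lags / peak_ms), 0)
  su <- ifelse(lags > 50, (1 - exp(-(lags - 50) / 80)) * exp(-(lags - 50) / decay_ms), 0)
  hfb_kernel(peak * tr + sustained * su, window_ms, rate)
}

#' Zero kernel
#' @inheritParams kernel_bump
#' @return an `hfb_kernel` of all zeros.
#' @export
kernel_zero <- function(rate, window_ms) {
  n <- floor((window_ms[2] - window_ms[1]) * rate / 1000)
  hfb_kernel(numeric(n), window_ms, rate)
}

#' Assemble a ground-truth object
#'
#' @param electrodes data.frame with columns `electrode`, `roi`, `patient`.
#' @param kernels list (one entry per electrode) of lists with elements
#'   `stimulus` (named by category: face, nonface), `disappearance` and
#'   `reappearance` (each named by interruption type: gap, voluntary,
#'   spontaneous), all `hfb_kernel` objects.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(electrodes, kernels) {
  if (nrow(electrodes) != length(kernels))
    stop_hfb("hfbdeconv_invalid_config",
             "one kernel set per electrode is required")
  structure(list(electrodes = electrodes, kernels = kernels),
            class = "ground_truth")
}

#' Default ground truth encoding the hierarchical gap/blink dissociation
#'
#' Early visual ROIs (V1, V2, V3) receive a disappearance dip and a
#' reappearance overshoot for gaps and both blink types, with blink dips
#' deeper than gap dips (markedly so for voluntary blinks, whose occlusions
#' are longer, and slightly for spontaneous blinks). High-level ROIs
#' (V4, VO, FC, N-FC) receive a reappearance overshoot for gaps only, blink
#' overshoots near zero, and shallow dips. FC electrodes respond more
#' strongly to faces.
#'
#' @param rois character vector, one entry per electrode (labels among
#'   V1, V2, V3, V4, VO, FC, N-FC, unassigned). `unassigned` electrodes are
#'   non-visual sites: all their kernels are zero, as for the majority of
#'   channels in a clinical implant.
#' @param rate kernel grid rate, Hz.
#' @param patient patient label(s), recycled.
#' @param seed integer seed for small between-electrode amplitude jitter
#'   (NULL for none).
#' @param interruption_window_ms lag window of interruption kernels.
#' @return a `ground_truth`.
#' @export
default_ground_truth <- function(rois, rate = 250, patient = "P01",
                                 seed = NULL,
                                 interruption_window_ms = c(-250, 500)) {
  early <- c("V1", "V2", "V3")
  if (!is.null(seed)) set.seed(derive_seed(seed, 7L))
  # one multiplicative gain per electrode: amplitudes vary across sites but
  # the sign and ratio structure of the true effects is preserved
  jit <- function() if (is.null(seed)) 1 else exp(rnorm(1, 0, 0.15))
  w <- interruption_window_ms
  kernels <- lapply(rois, function(roi) {
    if (roi == "unassigned") {
      z <- kernel_zero(rate, w)
      zs <- kernel_zero(rate, c(0, 1500))
      return(list(stimulus = list(face = zs, nonface = zs),
                  disappearance = list(gap = z, voluntary = z, spontaneous = z),
                  reappearance = list(gap = z, voluntary = z, spontaneous = z)))
    }
    is_early <- roi %in% early
    face_gain <- if (roi == "FC") 2.5 else 1
    g <- jit()
    dip_gap <- g * if (is_early) -3 else -0.6
    dip_spont <- g * if (is_early) -3.5 else -1
    dip_vol <- g * if (is_early) -4.5 else -1.3
    over_gap <- g * 3
    # early sites respond to reappearance alike for gaps and blinks;
    # the blink overshoot vanishes up the hierarchy
    over_blink <- g * if (is_early) 3 else 0
    dip <- function(a) if (a == 0) kernel_zero(rate, w) else
      kernel_bump(rate, w, center_ms = 150, sd_ms = 50, amplitude = a)
    over <- function(a) if (a == 0) kernel_zero(rate, w) else
      kernel_bump(rate, w, center_ms = 180, sd_ms = 60, amplitude = a)
    list(
      stimulus = list(
        face = kernel_stimulus(rate, peak = 8 * face_gain, sustained = 2.5),
        nonface = kernel_stimulus(rate, peak = 8, sustained = 2.5)
      ),
      disappearance = list(gap = dip(dip_gap), voluntary = dip(dip_vol),
                           spontaneous = dip(dip_spont)),
      reappearance = list(gap = over(over_gap), voluntary = over(over_blink),
                          spontaneous = over(over_blink))
    )
  })
  electrodes <- data.frame(
    electrode = sprintf("e%02d", seq_along(rois)),
    roi = rois,
    patient = rep_len(patient, length(rois)),
    stringsAsFactors = FALSE)
  ground_truth(electrodes, kernels)
}
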