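# End-to-end pipeline on synthetic sessions ----------------------------------

#' Pipeline configuration
#'
#' Bundles the simulation and analysis parameters of an end-to-end run.
#' One global seed deterministically derives every stage's seed.
#'
#' @param n_patients number of simulated patients.
#' @param rois electrode ROI labels per patient (character vector); the
#'   default montage mixes early, high-level and non-visual (`unassigned`,
#'   zero-kernel) sites, as in a clinical implant where most channels are
#'   not visually responsive. Only electrodes passing the responsiveness
#'   screen enter deconvolution and inference.
#' @param sim named list of overrides passed to [sim_config()] (per-patient
#'   seeds are derived automatically).
#' @param rate_hfb HFB grid rate for simulation and analysis, Hz.
#' @param n_splits split-half repetitions (default 30).
#' @param m_permutations permutations per electrode-level test.
#' @param alpha significance level for electrode-level FDR decisions.
#' @param m_randomization draws for the ROI independence test.
#' @param interruption_window_ms,stimulus_window_ms FIR windows, ms.
#' @param seed global seed.
#' @param out_dir optional output directory for TSV tables and a JSON
#'   manifest.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 2,
                            rois = c("V1", "V1", "V2", "V3", "VO", "FC",
                                     "FC", "N-FC",
                                     rep("unassigned", 8)),
                            sim = list(n_blocks = 12, rate_hfb = 50),
                            rate_hfb = NULL,
                            n_splits = 30L,
                            m_permutations = 200L,
                            alpha = 0.05,
                            m_randomization = 2000L,
                            interruption_window_ms = c(-250, 500),
                            stimulus_window_ms = c(0, 1500),
                            seed = 1L,
                            out_dir = NULL) {
  cfg <- list(n_patients = n_patients, rois = rois, sim = sim,
              n_splits = n_splits, m_permutations = m_permutations,
              alpha = alpha, m_randomization = m_randomization,
              interruption_window_ms = interruption_window_ms,
              stimulus_window_ms = stimulus_window_ms,
              seed = as.integer(seed), out_dir = out_dir)
  if (!is.null(rate_hfb)) cfg$sim$rate_hfb <- rate_hfb
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic-session analysis pipeline
#'
#' Stages: simulate schedules and ground truth; generate HFB sessions;
#' outlier scan; synthesize ocular channels and detect blinks; screen
#' electrodes for visual responsiveness and face selectivity; assign ROIs;
#' deconvolve onset- and offset-locked reduced models per electrode;
#' quantify plugin and split-half dip/overshoot components; run
#' electrode-level permutation tests (gap vs spontaneous and voluntary
#' blinks) with FDR adjustment; run the ROI randomization test of
#' independence. Re-running with an identical configuration reproduces all
#' stochastic outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param progress print stage progress.
#' @return a list (report bundle) with per-stage outputs and a `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  stages <- character(0)
  patients <- vector("list", config$n_patients)

  for (pt in seq_len(config$n_patients)) {
    sim_args <- config$sim
    sim_args$seed <- derive_seed(config$seed, 100L + pt)
    scfg <- do.call(sim_config, sim_args)
    schedule <- generate_schedule(scfg)
    truth <- default_ground_truth(config$rois, rate = scfg$rate_hfb,
                                  patient = sprintf("P%02d", pt),
                                  seed = scfg$seed)
    hfb <- generate_hfb_session(scfg, truth, schedule)
    hfb <- reject_outliers(hfb)
    oc <- generate_ocular_channels(scfg, schedule)
    blinks <- detect_blinks_pupil(oc$pupil, oc$eog, oc$rate)
    resp <- score_visual_responsiveness(hfb, schedule)
    fsel <- score_face_selectivity(hfb, schedule)
    meta <- assign_rois(
      data.frame(electrode = truth$electrodes$electrode,
                 roi = truth$electrodes$roi, stringsAsFactors = FALSE),
      face_selective = fsel$face_selective)
    meta$patient <- sprintf("P%02d", pt)
    patients[[pt]] <- list(config = scfg, schedule = schedule, truth = truth,
                           hfb = hfb, ocular = oc, blinks = blinks,
                           responsiveness = resp, face_selectivity = fsel,
                           metadata = meta)
    say("patient %d simulated and screened", pt)
  }
  stages <- c(stages, "simulate", "hfb", "outlier_scan", "ocular_events",
              "screening")

  # deconvolution + components + permutation inference per electrode
  comp_rows <- list(); perm_rows <- list(); fits <- list()
  for (pt in seq_len(config$n_patients)) {
    P <- patients[[pt]]
    rate <- P$hfb$rate
    excl <- excluded_timepoints(P$schedule, ncol(P$hfb$values), rate,
                                mask = P$hfb$rejection_mask)
    has_vol <- any(P$schedule$kind == "blink" &
                     P$schedule$subtype == "voluntary")
    responsive <- which(P$responsiveness$selected)
    for (e in responsive) {
      y <- P$hfb$values[e, ]
      el <- P$metadata$electrode[e]
      fit_on <- fir_deconv(build_design_matrix(
        predictor_sets(P$schedule, "onset", split_by_category = FALSE,
                       config$stimulus_window_ms,
                       config$interruption_window_ms),
        length(y), rate, excl, exclusion_mode = "drop"), y)
      fit_off <- fir_deconv(build_design_matrix(
        predictor_sets(P$schedule, "offset", split_by_category = FALSE,
                       config$stimulus_window_ms,
                       config$interruption_window_ms),
        length(y), rate, excl, exclusion_mode = "drop"), y)
      fits[[paste(pt, e, sep = "_")]] <-
        list(onset = fit_on, offset = fit_off, electrode = el, patient = pt)

      plugin <- quantify_components(fit_on, fit_off)
      for (comp in c("overshoot", "dip")) {
        sh <- split_half_estimate(
          y, P$schedule, rate, component = comp,
          n_splits = config$n_splits,
          seed = derive_seed(config$seed, 200L + 37L * pt + e),
          interruption_window_ms = config$interruption_window_ms,
          stimulus_window_ms = config$stimulus_window_ms,
          excluded = excl)
        sh$electrode <- el
        sh$patient <- P$metadata$patient[e]
        sh$roi <- P$metadata$roi[e]
        comp_rows[[length(comp_rows) + 1L]] <- sh
      }
      plugin$electrode <- el
      plugin$patient <- P$metadata$patient[e]
      plugin$roi <- P$metadata$roi[e]
      plugin$n_splits <- NA_integer_
      comp_rows[[length(comp_rows) + 1L]] <- plugin[
        , c("set", "component", "integral", "method", "n_splits",
            "electrode", "patient", "roi")]

      for (comp in c("overshoot", "dip")) {
        for (bt in c("spontaneous", if (has_vol) "voluntary")) {
          pr <- permutation_test(
            y, P$schedule, rate, component = comp, blink_type = bt,
            m = config$m_permutations,
            seed = derive_seed(config$seed, 300L + 101L * pt + e),
            excluded = excl,
            interruption_window_ms = config$interruption_window_ms,
            stimulus_window_ms = config$stimulus_window_ms)
          pr$electrode <- el
          pr$patient <- P$metadata$patient[e]
          pr$roi <- P$metadata$roi[e]
          attr(pr, "perm_diffs") <- NULL
          perm_rows[[length(perm_rows) + 1L]] <- pr
        }
      }
    }
    say("patient %d deconvolved and tested", pt)
  }
  if (!length(comp_rows))
    stop_hfb("hfbdeconv_no_trials", "no electrode passed the screening stage")
  components <- do.call(rbind, comp_rows)
  permutations <- do.call(rbind, perm_rows)
  stages <- c(stages, "deconvolution", "components")

  # FDR across all electrodes, per contrast x component (both directions)
  permutations$p_fdr <- NA_real_
  for (comp in unique(permutations$component))
    for (bt in unique(permutations$blink_type)) {
      sel <- permutations$component == comp & permutations$blink_type == bt
      permutations$p_fdr[sel] <- fdr_adjust(permutations$p_two_tailed[sel])
    }
  permutations$significant <- permutations$p_fdr < config$alpha

  # ROI inhomogeneity of significant gap > blink overshoot electrodes
  roi_tests <- list()
  for (comp in unique(permutations$component))
    for (bt in unique(permutations$blink_type)) {
      sel <- permutations$component == comp & permutations$blink_type == bt
      d <- permutations[sel & permutations$roi != "unassigned", ]
      if (!nrow(d)) next
      tab_n <- table(d$roi)
      tab_o <- tapply(d$significant, d$roi, sum)
      rt <- randomization_independence_test(
        as.integer(tab_o), as.integer(tab_n),
        m = config$m_randomization,
        seed = derive_seed(config$seed, 400L))
      roi_tests[[paste(comp, bt, sep = "_")]] <-
        list(component = comp, blink_type = bt,
             O = as.integer(tab_o), n = as.integer(tab_n),
             roi = names(tab_n), chi2 = rt$chi2_observed, p = rt$p)
    }
  stages <- c(stages, "inference")

  bundle <- list(
    patients = patients, fits = fits, components = components,
    permutations = permutations, roi_tests = roi_tests,
    config = config,
    manifest = list(
      package_version = as.character(utils::packageVersion("hfbdeconv")),
      seed = config$seed, stages = c(stages, "report"),
      n_patients = config$n_patients,
      config_hash = config_hash(config))
  )
  bundle$report <- make_report(bundle)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

config_hash <- function(config) {
  config$out_dir <- NULL
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Summary tables from a pipeline bundle
#'
#' Grand-average deconvolved traces per ROI (averaged within patients
#' first, then across patients), the split-half component summary per
#' ROI x interruption x component, and the per-ROI significance table of
#' the permutation tests.
#'
#' @param bundle output of [run_pipeline()].
#' @return list `grand_averages` (long data.frame), `component_summary`,
#'   `significance_by_roi`.
#' @export
make_report <- function(bundle) {
  # grand averages: offset-locked traces per interruption set
  rows <- list()
  for (key in names(bundle$fits)) {
    f <- bundle$fits[[key]]
    pt <- f$patient
    meta <- bundle$patients[[pt]]$metadata
    roi <- meta$roi[meta$electrode == f$electrode]
    for (s in setdiff(unique(f$offset$columns$set[f$offset$columns$type == "fir"]),
                      "stimulus")) {
      tr <- deconv_trace(f$offset, s)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = pt, roi = roi, set = s, lag_ms = tr$lag_ms,
        beta = tr$beta, stringsAsFactors = FALSE)
    }
  }
  traces <- do.call(rbind, rows)
  # within-patient means, then across-patient means (patients-equal weights)
  wp <- stats::aggregate(beta ~ patient + roi + set + lag_ms, traces, mean)
  ga <- stats::aggregate(beta ~ roi + set + lag_ms, wp, mean)

  comp <- bundle$components[bundle$components$method == "split_half", ]
  comp_sum <- stats::aggregate(integral ~ roi + set + component, comp, mean)

  perm <- bundle$permutations
  sig <- stats::aggregate(
    cbind(significant = perm$significant, total = 1) ~
      roi + component + blink_type, perm, sum)

  list(grand_averages = ga, component_summary = comp_sum,
       significance_by_roi = sig)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(bundle$components, "components.tsv")
  wt(bundle$permutations, "permutation_tests.tsv")
  wt(bundle$report$grand_averages, "grand_averages.tsv")
  wt(bundle$report$component_summary, "component_summary.tsv")
  wt(bundle$report$significance_by_roi, "significance_by_roi.tsv")
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Export a component table for external mixed-effects fitting
#'
#' Long-format table (electrode, patient, roi, interruption, component,
#' integral) ready for a mixed-effects group analysis; with
#' `log_transform = TRUE` values are uniformly shifted positive (dips are
#' sign-inverted first) and log-transformed.
#'
#' @param components component table from [run_pipeline()].
#' @param path optional TSV path.
#' @param log_transform apply the positive-shift + log transform.
#' @return the (possibly transformed) table, invisibly if written.
#' @export
export_component_table <- function(components, path = NULL,
                                   log_transform = FALSE) {
  d <- components
  if (log_transform) {
    d$value <- ifelse(d$component == "dip", -d$integral, d$integral)
    shift <- max(0, -min(d$value)) + 1e-6
    d$log_value <- log(d$value + shift)
    attr(d, "shift") <- shift
  }
  if (!is.null(path)) {
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(d))
  }
  d
}
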