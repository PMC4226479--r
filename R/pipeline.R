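#' Pipeline configuration
#'
#' Bundles inputs and per-stage parameters for [run_pipeline]. Inputs
#' may be paths (`eeg`, plus exactly one R-peak source: an `events` text
#' file or the name of an `ecg_channel` inside the recording) or
#' in-memory objects (`recording`, `rpeaks`).
#'
#' @param eeg path to a `.vhdr` or `.edf` file (or `NULL` when
#'   `recording` is given).
#' @param events path to a plain-text R-peak event file.
#' @param ecg_channel name of an ECG channel to run R-peak detection on;
#'   the channel is excluded from the EEG processing.
#' @param recording an in-memory [eeg_recording] (alternative to `eeg`).
#' @param rpeaks an in-memory [rpeak_series].
#' @param out_dir output directory (`NULL` for no files).
#' @param obs list: `n_pc` (default 3), `window_ms` (default `c(0, 700)`).
#' @param ica list: `interval_mode` (default `"whole"`), `max_iter`,
#'   `tol`.
#' @param selection list: `method` (default `"pvaf"`) plus the method's
#'   threshold parameters (`pvaf_threshold_pct`, `corr_rel_threshold`,
#'   `pacf_block_size`, `pacf_rel_threshold`, `wave_threshold`,
#'   `wave_band_hz`).
#' @param metrics list: `ar_order` (default 16).
#' @param seed master seed; all stage randomness derives from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(eeg = NULL, events = NULL, ecg_channel = NULL,
                            recording = NULL, rpeaks = NULL, out_dir = NULL,
                            obs = list(), ica = list(), selection = list(),
                            metrics = list(), seed = 1L) {
  n_peak_sources <- sum(!is.null(events), !is.null(ecg_channel), !is.null(rpeaks))
  if (n_peak_sources != 1L)
    stop("config error: exactly one of events file, ecg_channel or in-memory rpeaks is required")
  if (is.null(recording) && is.null(eeg))
    stop("config error: an EEG input (path or in-memory recording) is required")
  if (!is.null(eeg) && !file.exists(eeg))
    stop("config error: EEG file not found: ", eeg)
  if (!is.null(events) && !file.exists(events))
    stop("config error: events file not found: ", events)
  obs <- utils::modifyList(list(n_pc = 3L, window_ms = c(0, 700)), obs)
  ica <- utils::modifyList(list(interval_mode = "whole", max_iter = 1000L,
                                tol = NA), ica)
  selection <- utils::modifyList(
    list(method = "pvaf", pvaf_threshold_pct = 2.5, corr_rel_threshold = 0.4,
         pacf_block_size = 4L, pacf_rel_threshold = 1/3,
         wave_threshold = 3, wave_band_hz = c(1, 13)), selection)
  metrics <- utils::modifyList(list(ar_order = 16L), metrics)
  structure(list(eeg = eeg, events = events, ecg_channel = ecg_channel,
                 recording = recording, rpeaks = rpeaks, out_dir = out_dir,
                 obs = obs, ica = ica, selection = selection,
                 metrics = metrics, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  rec <- config$recording %||% read_eeg(config$eeg)
  if (!is.null(config$ecg_channel)) {
    if (!config$ecg_channel %in% rec$labels)
      stop("config error: ecg_channel '", config$ecg_channel, "' not in the recording")
    ecg <- rec$data[match(config$ecg_channel, rec$labels), ]
    keep <- rec$labels != config$ecg_channel
    rec <- eeg_recording(rec$data[keep, , drop = FALSE], rec$fs,
                         rec$labels[keep], stage = rec$stage, meta = rec$meta)
    rpeaks <- detect_r_peaks(ecg, qrs_template(rec$fs), rec$fs)
  } else if (!is.null(config$events)) {
    rpeaks <- read_rpeaks(config$events, rec$fs)
  } else {
    rpeaks <- config$rpeaks
  }
  # drop auxiliary channels (e.g. a recorded ECG trace) that are not
  # 10-20 scalp positions: every downstream stage assumes EEG labels
  is_eeg <- grepl("^[A-Za-z]{1,4}([0-9]{1,2}|z|Z)$", rec$labels) &
    !toupper(rec$labels) %in% c("ECG", "EKG", "EOG", "EMG")
  if (!all(is_eeg)) {
    message("excluding non-EEG channel(s): ",
            paste(rec$labels[!is_eeg], collapse = ", "))
    rec <- eeg_recording(rec$data[is_eeg, , drop = FALSE], rec$fs,
                         rec$labels[is_eeg], stage = rec$stage, meta = rec$meta)
  }
  list(recording = rec, rpeaks = rpeaks)
}

score_by_method <- function(method, dec, post_obs, raw, rpeaks, sel, pa_window) {
  switch(method,
    pvaf = score_pvaf(dec, post_obs, rpeaks, pa_window,
                      threshold_pct = sel$pvaf_threshold_pct),
    corr = {
      part <- partition_channels(raw$labels)
      tmpl <- build_pa_templates(raw, rpeaks, part, pa_window)
      score_corr(dec, tmpl, rpeaks, rel_threshold = sel$corr_rel_threshold)
    },
    pacf = score_pacf(dec, rpeaks, pa_window, block_size = sel$pacf_block_size,
                      rel_threshold = sel$pacf_rel_threshold),
    wave = score_wave(dec, rpeaks, pa_window, band = sel$wave_band_hz,
                      threshold = sel$wave_threshold),
    stop("unknown selection method: ", method))
}

#' Run the full correction pipeline
#'
#' read -> R peaks -> OBS -> ICA -> component selection -> removal ->
#' validation metrics. When `out_dir` is set, writes the corrected
#' recording (BrainVision), a per-component score table (TSV), the
#' quality report (JSON and TSV), the detected/used R peaks, and a run
#' log with all parameters.
#'
#' @param config a [pipeline_config].
#' @return the [quality_report], with the corrected recording, the
#'   decomposition and the selection attached as attributes
#'   (`"corrected"`, `"decomposition"`, `"selection"`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  tryCatch({
    inputs <- load_pipeline_inputs(config)
    raw <- inputs$recording; rpeaks <- inputs$rpeaks
    pa_window <- epoch_window(config$obs$window_ms[1], config$obs$window_ms[2])
    stage <- "obs"
    obs_res <- obs_correct(raw, rpeaks, pa_window, n_pc = config$obs$n_pc)
    post_obs <- obs_res$recording
    stage <- "ica"
    dec <- fit_ica(post_obs, rpeaks, interval_mode = config$ica$interval_mode,
                   seed = config$seed, pa_window = pa_window,
                   max_iter = config$ica$max_iter,
                   tol = if (is.na(config$ica$tol)) NULL else config$ica$tol)
    stage <- "selection"
    sel <- score_by_method(config$selection$method, dec, post_obs, raw, rpeaks,
                           config$selection, pa_window)
    corrected <- apply_selection(post_obs, dec, sel)
    stage <- "metrics"
    report <- quality_report(post_obs, corrected, rpeaks,
                             ar_order = config$metrics$ar_order,
                             method = paste0(config$ica$interval_mode, "_",
                                             config$selection$method))
    if (!is.null(config$out_dir)) {
      stage <- "output"
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_brainvision(corrected, file.path(config$out_dir, "corrected"), rpeaks)
      write_rpeaks(rpeaks, file.path(config$out_dir, "rpeaks.txt"))
      utils::write.table(
        data.frame(component = seq_along(sel$scores), score = sel$scores,
                   removed = sel$mask),
        file.path(config$out_dir, "component_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_quality_report(report,
                           json_path = file.path(config$out_dir, "report.json"),
                           tsv_path = file.path(config$out_dir, "report.tsv"))
      writeLines(c(sprintf("method: %s", report$method),
                   sprintf("seed: %d", config$seed),
                   sprintf("ica_rank: %d", dec$rank),
                   sprintf("ica_iterations: %d", dec$iterations),
                   sprintf("components_removed: %d", sum(sel$mask)),
                   sprintf("n_rpeaks: %d", length(rpeaks$indices))),
                 file.path(config$out_dir, "run_log.txt"))
    }
    attr(report, "corrected") <- corrected
    attr(report, "decomposition") <- dec
    attr(report, "selection") <- sel
    report
  }, error = function(e) {
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the 2 x 4 method-comparison sweep
#'
#' Fits ICA once per interval mode (whole recording and concatenated
#' pulse-artifact epochs) on the same OBS-corrected input, applies all
#' four selection criteria to each decomposition, and returns the eight
#' quality reports.
#'
#' @param config a [pipeline_config]; its `selection$method` is ignored.
#' @param methods selection criteria to sweep (default all four).
#' @param interval_modes ICA intervals to sweep (default both).
#' @return named list of [quality_report]s, keys like `"whole_pvaf"`.
#' @export
run_sweep <- function(config, methods = c("pvaf", "corr", "pacf", "wave"),
                      interval_modes = c("whole", "pa_epochs")) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- load_pipeline_inputs(config)
  raw <- inputs$recording; rpeaks <- inputs$rpeaks
  pa_window <- epoch_window(config$obs$window_ms[1], config$obs$window_ms[2])
  post_obs <- obs_correct(raw, rpeaks, pa_window, n_pc = config$obs$n_pc)$recording
  reports <- list()
  for (mode in interval_modes) {
    dec <- fit_ica(post_obs, rpeaks, interval_mode = mode, seed = config$seed,
                   pa_window = pa_window, max_iter = config$ica$max_iter,
                   tol = if (is.na(config$ica$tol)) NULL else config$ica$tol)
    for (m in methods) {
      sel <- score_by_method(m, dec, post_obs, raw, rpeaks, config$selection,
                             pa_window)
      corrected <- apply_selection(post_obs, dec, sel)
      key <- paste0(mode, "_", m)
      reports[[key]] <- quality_report(post_obs, corrected, rpeaks,
                                       ar_order = config$metrics$ar_order,
                                       method = key)
      if (!is.null(config$out_dir)) {
        dir.create(file.path(config$out_dir, key), recursive = TRUE,
                   showWarnings = FALSE)
        write_quality_report(reports[[key]],
                             json_path = file.path(config$out_dir, key, "report.json"),
                             tsv_path = file.path(config$out_dir, key, "report.tsv"))
      }
    }
  }
  reports
}

#' Compare one metric across correction methods
#'
#' Collects a scalar metric from per-subject (or per-seed) sets of
#' quality reports, tabulates it as subjects x methods, and runs the
#' nonparametric omnibus and pairwise comparison of [compare_methods].
#'
#' @param report_sets list (one element per subject/dataset) of named
#'   lists of [quality_report]s, all sharing the same method names.
#' @param metric scalar report field to compare (e.g. `"ptp_ratio_mean"`,
#'   `"qc"`, `"delta_theta_ratio"`, `"cwt_md_all"`).
#' @return list with `table` (subjects x methods data frame), `stats`
#'   (from [compare_methods]), and `ranking` (methods by mean rank).
#' @export
compare_runs <- function(report_sets, metric) {
  if (length(report_sets) < 2L) stop("need reports from at least 2 subjects")
  methods <- names(report_sets[[1]])
  vals <- vapply(report_sets, function(reps) {
    vapply(methods, function(m) {
      v <- reps[[m]][[metric]]
      if (is.null(v)) stop("metric '", metric, "' absent from report '", m, "'")
      as.numeric(v)
    }, 1.0)
  }, numeric(length(methods)))
  tab <- as.data.frame(t(vals))
  rownames(tab) <- names(report_sets) %||% paste0("subject", seq_along(report_sets))
  groups <- as.list(tab)
  stats <- compare_methods(groups)
  mean_rank <- rowMeans(apply(tab, 1, rank))
  list(table = tab, stats = stats,
       ranking = names(sort(mean_rank)))
}
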