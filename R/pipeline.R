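#' Pipeline run configuration
#'
#' Whole-run parameter set, loss-lessly round-trippable through YAML.
#' Unknown keys are rejected so configs cannot silently drift.
#'
#' @param days Number of synthetic days (simulate stage).
#' @param day_length Scene length in seconds.
#' @param sample_rate Audio sample rate (Hz).
#' @param seed Master seed.
#' @param whistle_rate,overlap_prob,transient_rate,ambient_level Scene
#'   parameters, see [scene_config()].
#' @param band Analysis band in Hz.
#' @param backend Likelihood backend id.
#' @param roi_threshold,roi_min_area ROI stage parameters.
#' @param rho,accept_threshold,min_length Trace stage parameters.
#' @param theta_w Clustering pruning threshold.
#' @param snr_threshold SNR filter in dB.
#' @param with_buffer,no_buffer Labeling buffers in seconds.
#' @return A `run_config` object.
#' @export
run_config <- function(days = 2, day_length = 20, sample_rate = 48000,
                       seed = 1L, whistle_rate = 12, overlap_prob = 0.15,
                       transient_rate = 5, ambient_level = -40,
                       band = c(5000, 20000), backend = "energy",
                       roi_threshold = 0.8, roi_min_area = 20, rho = 3L,
                       accept_threshold = 0.6, min_length = 10L,
                       theta_w = 0.2, snr_threshold = 15, with_buffer = 60,
                       no_buffer = 300) {
  structure(as.list(environment()), class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path`; `read_run_config()` the
#'   `run_config` (unknown keys are an error).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("read_run_config: unknown keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full analysis pipeline on synthetic scenes
#'
#' Executes simulate -> preprocess -> likelihood/trace -> cluster ->
#' features -> label -> SNR filter -> classify, persisting every
#' intermediate under `out_dir` (WAV per day, trace/record CSV, cluster and
#' manifest JSON). A rerun with the same config and seed is deterministic.
#' Classification requires at least two days with both labels present; when
#' the miniature dataset cannot support it the stage is recorded as skipped
#' in the manifest rather than failing the run.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; must not contain a previous
#'   manifest unless `overwrite = TRUE`).
#' @param overwrite Allow writing into a non-empty run directory.
#' @return A `run_manifest` list: config hash, per-stage record counts,
#'   package version and seed.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "manifest.json")) &&
      !overwrite)
    stop("run_pipeline: ", out_dir, " already holds a run (use overwrite = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  # simulate
  with_local_seed(config$seed, {
    day_seeds <- sample.int(2^31 - 2, config$days)
  })
  scenes <- vector("list", config$days)
  for (d in seq_len(config$days)) {
    vessel <- if (d %% 2 == 1L)
      vessel_noise_spec(cbind(config$day_length * 0.3, config$day_length * 0.7))
    else NULL
    cfg <- scene_config(
      day_index = d, day_length = config$day_length,
      sample_rate = config$sample_rate,
      class_label = if (is.null(vessel)) "no_vessel" else "with_vessel",
      whistle_rate = config$whistle_rate, overlap_prob = config$overlap_prob,
      vessel = vessel, ambient_level = config$ambient_level,
      transient_rate = config$transient_rate, seed = day_seeds[d]
    )
    scenes[[d]] <- synth_scene(cfg)
    write_wav(scenes[[d]]$waveform, file.path(out_dir, sprintf("day%02d.wav", d)),
              bits = 16)
    gt <- scenes[[d]]$ground_truth
    jsonlite::write_json(
      list(whistles = gt$whistles, vessel_intervals = gt$vessel_intervals,
           class_label = gt$class_label, seed = gt$seed),
      file.path(out_dir, sprintf("day%02d_gt.json", d)),
      dataframe = "columns", auto_unbox = TRUE, digits = NA
    )
  }
  counts$segments <- config$days
  counts$gt_whistles <- sum(vapply(
    scenes, function(s) nrow(s$ground_truth$whistles), numeric(1)
  ))

  # preprocess + detect + cluster + features
  all_records <- list()
  n_rois <- 0L; n_traces <- 0L; n_clusters <- 0L
  for (d in seq_len(config$days)) {
    seg <- scenes[[d]]$waveform
    seg <- bandpass(seg, config$band[1], config$band[2])
    seg <- wavelet_denoise(seg)
    spec <- make_spectrogram(seg, band = config$band)
    det <- detect_traces(spec, backend = config$backend,
                         threshold = config$roi_threshold,
                         min_area = config$roi_min_area, rho = config$rho,
                         accept_threshold = config$accept_threshold,
                         min_length = config$min_length)
    n_rois <- n_rois + length(det$rois)
    n_traces <- n_traces + length(det$traces)
    utils::write.csv(traces_tbl(det$traces, spec),
                     file.path(out_dir, sprintf("day%02d_traces.csv", d)),
                     row.names = FALSE)
    if (length(det$traces) == 0L) next
    aff <- build_affinity(det$traces, spec)
    asg <- solve_clustering(aff, traces = det$traces, theta_w = config$theta_w)
    n_clusters <- n_clusters + asg$K
    jsonlite::write_json(
      list(membership = asg$membership, roles = asg$roles, K = asg$K,
           objective = asg$objective),
      file.path(out_dir, sprintf("day%02d_clusters.json", d)),
      auto_unbox = TRUE, digits = NA
    )
    feats <- compute_features(asg, det$traces, spec, day_index = d)
    # place each day's scene at local noon of its own calendar day
    feats$timestamp <- feats$timestamp + (d - 1) * 86400 + 12 * 3600
    feats$is_daytime <- TRUE
    all_records[[length(all_records) + 1L]] <- feats
  }
  counts$rois <- n_rois
  counts$traces <- n_traces
  counts$clusters <- n_clusters

  records <- dplyr::bind_rows(all_records)
  counts$records <- nrow(records)

  # label + SNR filter
  iv <- do.call(rbind, lapply(seq_len(config$days), function(d) {
    m <- scenes[[d]]$ground_truth$vessel_intervals
    if (nrow(m) == 0) return(NULL)
    m + (d - 1) * 86400 + 12 * 3600
  }))
  vlog <- if (is.null(iv)) vessel_log(numeric(0), numeric(0))
          else vessel_log(iv[, 1], iv[, 2])
  if (nrow(records) > 0) {
    records <- label_whistles(records, vlog, config$with_buffer, config$no_buffer)
    counts$labelled <- sum(records$label != "excluded")
    kept <- snr_filter(records, config$snr_threshold)
    counts$snr_kept <- nrow(kept)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
  } else {
    counts$labelled <- 0L
    counts$snr_kept <- 0L
    kept <- records
  }

  # classify (needs >= 2 days and both labels)
  classify_status <- "ok"
  report <- NULL
  usable <- kept[kept$label %in% c("with_vessel", "no_vessel"), , drop = FALSE]
  if (nrow(usable) > 10 && length(unique(usable$day_index)) >= 2 &&
      length(unique(usable$label[drop = TRUE])) == 2) {
    report <- tryCatch(
      evaluate_lodo(usable, svm_grid(cv_cap = 400, refit_cap = 1000),
                    seed = config$seed),
      error = function(e) { classify_status <<- conditionMessage(e); NULL }
    )
    if (!is.null(report))
      utils::write.csv(report$by_day, file.path(out_dir, "eval_by_day.csv"),
                       row.names = FALSE)
  } else {
    classify_status <- "skipped: insufficient labelled data for LODO"
  }

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("whistlevessel")),
    counts = counts,
    classify_status = classify_status
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(c(manifest, list(report = report)), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$config_hash, "\n")
  for (nm in names(x$counts)) cat(sprintf("  %-12s %d\n", nm, x$counts[[nm]]))
  cat("  classify:", x$classify_status, "\n")
  invisible(x)
}
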