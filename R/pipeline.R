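# End-to-end orchestration: configuration, the full analysis pipeline, and
# a human-readable report. The command-line entry point at
# inst/cli/dyadcoord is a thin wrapper over these functions.

#' Pipeline configuration with study defaults
#'
#' Every default is the study-protocol value: 60 Hz recordings of 15-minute
#' sessions (54,000 frames), likelihood cutoff 0.6 with a 5-frame median
#' filter, 1 s / 3 SD outlier removal and 0.5 s speed smoothing, 5 s
#' rolling Spearman window, classifier threshold y = 0.5, 1000 data slides
#' at the 95th percentile, NSTE with m = 3 / tau 6-15 / 2 s windows
#' stepped 0.5 s, and a 90 s per-side (180 s total) co-occurrence
#' tolerance.
#'
#' @param ... Named overrides of any default.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fps = 60,
    expected_frames = 54000,
    p_cutoff = 0.6,
    median_window = 5,
    outlier_window = 1,
    outlier_nsd = 3,
    smooth_window = 0.5,
    mcv_window = 5,
    classifier_y = 0.5,
    n_slides = 1000,
    percentile = 95,
    slide_participant = "A",
    nste_m = 3,
    nste_tau_min = 6,
    nste_tau_max = 15,
    nste_window = 2,
    nste_step = 0.5,
    nste_shuffles = 10,
    cooccur_tolerance = 90,
    marker_map = as.list(default_marker_map()))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a YAML pipeline configuration
#'
#' Fields absent from the file keep their defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(pipeline_config, over)
}

#' Print the active configuration
#'
#' @param config A [pipeline_config()].
#' @export
print_config <- function(config = pipeline_config()) {
  desc <- c(
    fps = "frame rate of the recording [frames/s]",
    expected_frames = "nominal session length [frames]; longer series are trimmed",
    p_cutoff = "tracker likelihood below which samples are masked",
    median_window = "coordinate median filter [frames, odd]",
    outlier_window = "local window for speed outlier detection [s]",
    outlier_nsd = "outlier criterion [local SDs from local mean]",
    smooth_window = "speed moving-mean smoothing [s]",
    mcv_window = "rolling Spearman correlation window [s]",
    classifier_y = "evidence threshold y for high/low classification [rho]",
    n_slides = "data slides per moment for the significance test",
    percentile = "percentile of the pooled shuffled MCV distribution",
    slide_participant = "participant whose series are slid",
    nste_m = "NSTE embedding dimension",
    nste_tau_min = "smallest embedding/prediction delay [samples]",
    nste_tau_max = "largest embedding/prediction delay [samples]",
    nste_window = "NSTE analysis window [s]",
    nste_step = "NSTE window step [s]",
    nste_shuffles = "source shuffles for the NSTE bias term",
    cooccur_tolerance = "moment/segment co-occurrence expansion per side [s]",
    marker_map = "canonical marker id -> tracked body-part name")
  for (k in names(desc)) {
    v <- config[[k]]
    if (is.list(v)) v <- paste(names(v), unlist(v), sep = "=", collapse = " ")
    cat(sprintf("%-18s %-10s %s\n", k, paste(v, collapse = ","), desc[[k]]))
  }
  invisible(config)
}

#' @export
print.pipeline_config <- function(x, ...) print_config(x)

#' Run the full coordination pipeline on one session
#'
#' Stages: read pose data (DeepLabCut dialect, falling back to the plain
#' long dialect), likelihood cutoff + interpolation, coordinate median
#' filter, speed preprocessing, MCV, per-moment data-sliding significance
#' thresholds, evidence classification + confusion-matrix evaluation,
#' windowed NSTE with asymmetry, and moment/segment co-occurrence. Missing
#' moments or segments files skip the dependent stages with a warning.
#'
#' @param pose_file Coordinate CSV (DeepLabCut or plain long dialect).
#' @param moments_file Optional rated-moments CSV (see
#'   [read_moments_csv()]).
#' @param segments_file Optional participant-segments CSV (see
#'   [read_segments_csv()]).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed for the permutation test and NSTE shuffles.
#' @return Invisibly, a list with every stage's in-memory result; artifacts
#'   (speed/MCV/NSTE CSVs, thresholds and report JSON) are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(pose_file, moments_file = NULL,
                         segments_file = NULL, config = pipeline_config(),
                         out_dir = ".", seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[dyadcoord] %s", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  track <- stage("read pose data", {
    tr <- tryCatch(
      read_dlc_csv(pose_file, marker_map = unlist(config$marker_map),
                   fps = config$fps),
      error = function(e) NULL)
    if (is.null(tr)) tr <- read_pose_long(pose_file, fps = config$fps)
    tr
  })
  track <- stage("likelihood cutoff",
                 apply_pcutoff(track, cutoff = config$p_cutoff))
  track <- stage("median filter",
                 median_filter_track(track, window = config$median_window))
  expected <- if (track$frames >= config$expected_frames)
    config$expected_frames else NULL
  if (is.null(expected))
    message(sprintf(
      "[dyadcoord] session shorter than nominal %d frames; no trimming",
      config$expected_frames))
  speeds <- stage("speed preprocessing",
                  preprocess_speeds(track, expected_frames = expected,
                                    outlier_window = config$outlier_window,
                                    outlier_nsd = config$outlier_nsd,
                                    smooth_window = config$smooth_window))
  write_speed_csv(speeds, file.path(out_dir, "speed.csv"),
                  sidecar = file.path(out_dir, "outlier_fractions.json"))
  mcv <- stage("maximum correlation vector",
               compute_mcv(speeds, window = config$mcv_window))
  write_mcv_csv(mcv, file.path(out_dir, "mcv.csv"))

  moments <- NULL
  thresholds <- NULL
  eval_out <- NULL
  if (!is.null(moments_file) && file.exists(moments_file)) {
    duration <- track$frames / track$fps
    moments <- stage("read moments",
                     read_moments_csv(moments_file,
                                      session_duration = duration))
    thresholds <- stage("data-sliding significance", {
      lapply(seq_len(nrow(moments)), function(i)
        significance_threshold(speeds, moments[i, ],
                               n_slides = config$n_slides,
                               percentile = config$percentile,
                               window = config$mcv_window,
                               slide = config$slide_participant,
                               seed = seed + i))
    })
    jsonlite::write_json(
      lapply(thresholds, function(th)
        list(start = th$moment$start, end = th$moment$end,
             threshold = th$threshold, n_slides = th$n_slides,
             percentile = th$percentile, seed = th$seed)),
      file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
    moments <- stage("evidence classification",
                     classify_moments(mcv, moments, y = config$classifier_y))
    if (any(moments$label %in% c("high", "low")))
      eval_out <- evaluate_classification(moments)
  } else {
    warning("no moments file: skipping significance test and classification",
            call. = FALSE)
  }

  nste_res <- stage("windowed NSTE", {
    params <- nste_params(m = config$nste_m,
                          tau_range = config$nste_tau_min:config$nste_tau_max,
                          window = config$nste_window,
                          step = config$nste_step,
                          n_shuffles = config$nste_shuffles,
                          fps = config$fps)
    nste_windowed(speeds, params, seed = seed)
  })
  write_nste_csv(nste_res, file.path(out_dir, "nste.csv"))

  cooccur <- NULL
  if (!is.null(segments_file) && file.exists(segments_file) &&
      !is.null(moments)) {
    segments <- stage("read segments", read_segments_csv(segments_file))
    cooccur <- stage("co-occurrence",
                     cooccurring(moments, segments,
                                 tolerance = config$cooccur_tolerance))
  }

  report <- list(
    seed = seed,
    config = unclass(config),
    outlier_fractions = lapply(speeds, function(s) s$outlier_fraction),
    moments = moments,
    evaluation = if (!is.null(eval_out)) list(
      confusion = as.list(eval_out$confusion),
      accuracy = eval_out$accuracy, precision = eval_out$precision,
      sensitivity = eval_out$sensitivity) else NULL,
    cooccurrence = cooccur)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(list(track = track, speeds = speeds, mcv = mcv,
                 moments = moments, thresholds = thresholds,
                 evaluation = eval_out, nste = nste_res,
                 cooccurrence = cooccur))
}
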