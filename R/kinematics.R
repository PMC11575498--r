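# Hand-speed time series.
#
# All coordination measures in this package operate on scalar hand speed
# (px/s), not velocity: speed captures the temporal alignment of movement
# dynamics while staying invariant to movement direction, mirroring how
# "interpersonal coordination" is defined for the rating task (similarity in
# speed dynamics, with joint stillness counting as coordination).

#' Construct a speed series
#'
#' @param values Numeric vector of speeds (px/s), one per inter-frame
#'   interval; sample `i` spans frames `i` to `i+1` and is timestamped
#'   `i / fps` seconds.
#' @param fps Frame rate of the underlying recording.
#' @param marker Marker id the series belongs to (`A_left`, ...).
#' @param outlier_fraction Fraction of samples replaced by outlier removal.
#' @return An object of class `speed_series`.
#' @export
speed_series <- function(values, fps, marker = NA_character_,
                         outlier_fraction = 0) {
  structure(list(values = as.numeric(values), fps = fps, marker = marker,
                 outlier_fraction = outlier_fraction),
            class = "speed_series")
}

#' @export
print.speed_series <- function(x, ...) {
  cat(sprintf(
    "<speed_series> %s: %d samples @ %g fps (%.1f s), outliers replaced %.2f%%\n",
    x$marker, length(x$values), x$fps, length(x$values) / x$fps,
    100 * x$outlier_fraction))
  invisible(x)
}

#' Timestamps of a speed series
#'
#' @param series A [speed_series()].
#' @return Numeric vector of times in seconds (`i / fps`).
#' @export
speed_times <- function(series) seq_along(series$values) / series$fps

#' Compute hand speed from coordinates
#'
#' Frame-to-frame Euclidean displacement divided by the frame interval:
#' `speed[f-1] = sqrt((x_f - x_{f-1})^2 + (y_f - y_{f-1})^2) * fps`,
#' yielding `n - 1` samples for `n` frames.
#'
#' @param track A [pose_track()].
#' @param marker Marker id (`A_left`, `A_right`, `B_left`, `B_right`).
#' @return A [speed_series()] of length `frames - 1`.
#' @export
compute_speed <- function(track, marker) {
  m <- track$markers[[marker]]
  if (is.null(m)) stop("unknown marker: ", marker, call. = FALSE)
  if (track$frames < 2)
    stop("need at least 2 frames to compute speed", call. = FALSE)
  v <- sqrt(diff(m$x)^2 + diff(m$y)^2) * track$fps
  speed_series(v, fps = track$fps, marker = marker)
}

#' Trim a speed series to a session's nominal length
#'
#' Sessions have a fixed nominal frame count (54,000 frames at 60 Hz for a
#' 15-minute improvisation); surplus samples are dropped from the end so
#' every series has exactly `expected_frames - 1` speed samples. Series
#' already shorter than the nominal length are an error.
#'
#' @param series A [speed_series()].
#' @param expected_frames Nominal coordinate frame count.
#' @return The trimmed [speed_series()].
#' @export
trim_series <- function(series, expected_frames) {
  target <- expected_frames - 1
  n <- length(series$values)
  if (n < target)
    stop("series has ", n, " samples, fewer than expected ", target,
         call. = FALSE)
  series$values <- series$values[seq_len(target)]
  series
}

#' Remove local outliers from a speed series
#'
#' A sample is an outlier when it lies more than `nsd` local standard
#' deviations from the local mean, both computed over a centered window of
#' `window` seconds (the window is widened to an odd sample count so it is
#' symmetric). Outliers are replaced by linear interpolation between the
#' nearest retained neighbors; leading/trailing outliers take the nearest
#' retained value. Detection is a single pass on the raw series.
#' Zero-variance windows flag nothing.
#'
#' @param series A [speed_series()].
#' @param window Local window in seconds (default 1).
#' @param nsd Number of local standard deviations (default 3).
#' @return The cleaned [speed_series()] with `outlier_fraction` set.
#' @export
remove_outliers <- function(series, window = 1, nsd = 3) {
  v <- series$values
  w <- round(window * series$fps)
  if (w < 3) stop("outlier window too short: needs >= 3 samples", call. = FALSE)
  if (w %% 2 == 0) w <- w + 1
  mu <- moving_mean(v, w)
  sd <- moving_sd(v, w)
  out <- sd > 0 & abs(v - mu) > nsd * sd
  if (any(out) && !all(out)) v <- interp_masked(v, out)
  series$values <- v
  series$outlier_fraction <- mean(out)
  series
}

#' Smooth a speed series with a moving mean
#'
#' Centered moving-mean filter; edge windows shrink. Even sample counts
#' follow the MATLAB `movmean` convention (one extra sample toward the
#' past). Nonnegativity of speeds is preserved.
#'
#' @param series A [speed_series()].
#' @param window Window in seconds (default 0.5).
#' @return The smoothed [speed_series()].
#' @export
smooth_series <- function(series, window = 0.5) {
  w <- round(window * series$fps)
  if (w < 1) stop("smoothing window shorter than one sample", call. = FALSE)
  series$values <- moving_mean(series$values, w)
  series
}

#' Preprocess all four hand-speed series of a track
#'
#' Composition, in order: [compute_speed()] per marker, [trim_series()] to
#' the nominal frame count, [remove_outliers()], [smooth_series()].
#'
#' @param track A [pose_track()].
#' @param expected_frames Nominal frame count; `NULL` (default) skips
#'   trimming and uses the track's own length.
#' @param outlier_window,outlier_nsd Parameters of [remove_outliers()].
#' @param smooth_window Parameter of [smooth_series()].
#' @return Named list of four [speed_series()], one per marker id.
#' @export
preprocess_speeds <- function(track, expected_frames = NULL,
                              outlier_window = 1, outlier_nsd = 3,
                              smooth_window = 0.5) {
  out <- lapply(MARKER_IDS, function(id) {
    s <- compute_speed(track, id)
    if (!is.null(expected_frames)) s <- trim_series(s, expected_frames)
    s <- remove_outliers(s, window = outlier_window, nsd = outlier_nsd)
    smooth_series(s, window = smooth_window)
  })
  names(out) <- MARKER_IDS
  out
}

#' Write speed series to CSV, with an outlier-fraction sidecar
#'
#' @param speeds Named list of [speed_series()] (as from
#'   [preprocess_speeds()]).
#' @param path Output CSV path (`sample`, `t_s`, one column per marker).
#' @param sidecar Optional JSON path for per-marker outlier fractions.
#' @return `path`, invisibly.
#' @export
write_speed_csv <- function(speeds, path, sidecar = NULL) {
  df <- data.frame(sample = seq_along(speeds[[1]]$values),
                   t_s = speed_times(speeds[[1]]))
  for (id in names(speeds)) df[[id]] <- speeds[[id]]$values
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(sidecar)) {
    fr <- lapply(speeds, function(s) s$outlier_fraction)
    jsonlite::write_json(fr, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
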