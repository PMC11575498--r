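# Rated moments, the evidence-based high/low classifier, and linkage to
# participant-annotated segments.
#
# A "moment" is a human-rated interval of sustained (>= 10 s) high or low
# interpersonal coordination. The classifier integrates the MCV's excursions
# about a threshold y: area above y is evidence for high coordination, area
# below y evidence for low, and the larger evidence wins (ties go to high —
# over-detection of high coordination is the preferred failure mode when
# moments are screened as candidate episodes of social connection).

#' Construct a moment
#'
#' @param start,end Interval in session seconds; `end - start >= 10`.
#' @param label Rated label: `"high"`, `"low"` or `"unrated"`.
#' @param session_duration Upper bound for the interval (default 900 s).
#' @return A one-row data frame with columns `start`, `end`, `label`.
#' @export
moment <- function(start, end, label = "unrated", session_duration = 900) {
  if (end - start < 10)
    stop("a moment must be sustained for at least 10 s", call. = FALSE)
  if (start < 0 || end > session_duration)
    stop("moment outside the session [0, ", session_duration, "] s",
         call. = FALSE)
  if (!label %in% c("high", "low", "unrated"))
    stop("label must be high, low or unrated", call. = FALSE)
  data.frame(start = start, end = end, label = label)
}

#' Read a moments CSV
#'
#' Expected columns: `start_s`, `end_s`, `label` (optionally `session`).
#' Moments shorter than 10 s are rejected.
#'
#' @param path CSV path.
#' @param session_duration Session length in seconds (default 900).
#' @return Data frame of moments (`start`, `end`, `label`).
#' @export
read_moments_csv <- function(path, session_duration = 900) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df)))
    stop("moments CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    moment(df$start_s[i], df$end_s[i], df$label[i],
           session_duration = session_duration)))
  out
}

# Indices of speed/MCV samples within a moment. Sample i (timestamped
# i/fps) covers the displacement interval ((i-1)/fps, i/fps], so a moment
# [start, end] contains the samples with start < t <= end and a 10 s
# moment holds exactly 10 * fps of them.
moment_sample_index <- function(moment, series) {
  fps <- series$fps
  n <- length(series$values)
  t <- seq_len(n) / fps
  which(t > moment$start & t <= moment$end)
}

#' Evidence for high vs. low coordination within a moment
#'
#' Integrates the MCV about the classifier threshold `y` over the moment:
#' `e_high = sum over samples with MCV > y of (MCV - y) * dt` and
#' `e_low = sum over samples with MCV < y of (y - MCV) * dt` (dt = 1/fps).
#' Undefined MCV samples are skipped. The predicted label is `"high"` iff
#' `e_high >= e_low`.
#'
#' @param mcv An `mcv_series`.
#' @param moment One-row moment data frame or list with `start`, `end` (s).
#' @param y Evidence threshold in (-1, 1) (default 0.5).
#' @return List of class `evidence`: `e_high`, `e_low` (rho-seconds),
#'   `predicted` label.
#' @export
evidence <- function(mcv, moment, y = 0.5) {
  stopifnot(y > -1, y < 1)
  idx <- moment_sample_index(moment, mcv)
  v <- mcv$values[idx]
  v <- v[!is.na(v)]
  if (length(v) == 0)
    stop("unclassifiable moment: no defined MCV samples", call. = FALSE)
  dt <- 1 / mcv$fps
  e_high <- sum(pmax(v - y, 0)) * dt
  e_low <- sum(pmax(y - v, 0)) * dt
  structure(list(e_high = e_high, e_low = e_low,
                 predicted = if (e_high >= e_low) "high" else "low"),
            class = "evidence")
}

#' @export
print.evidence <- function(x, ...) {
  cat(sprintf("<evidence> high %.3f vs low %.3f rho*s -> %s\n",
              x$e_high, x$e_low, x$predicted))
  invisible(x)
}

#' Classify all moments of a session
#'
#' @param mcv An `mcv_series`.
#' @param moments Data frame of moments (see [read_moments_csv()]).
#' @param y Evidence threshold (default 0.5).
#' @return The moments data frame with added columns `e_high`, `e_low`,
#'   `predicted`.
#' @export
classify_moments <- function(mcv, moments, y = 0.5) {
  ev <- lapply(seq_len(nrow(moments)), function(i)
    evidence(mcv, moments[i, ], y = y))
  moments$e_high <- vapply(ev, `[[`, numeric(1), "e_high")
  moments$e_low <- vapply(ev, `[[`, numeric(1), "e_low")
  moments$predicted <- vapply(ev, `[[`, character(1), "predicted")
  moments
}

#' Confusion matrix and performance metrics
#'
#' Positive class is `"high"`. Metrics with a zero denominator are reported
#' as `NA`. `granularity = "moment"` scores one prediction per moment;
#' `granularity = "sample"` scores every defined MCV sample inside each
#' moment (predicted high iff MCV >= y) against the moment's rated label,
#' for which `mcv` and `y` must be supplied.
#'
#' @param classified Data frame with `label` (truth) and `predicted`
#'   columns, as from [classify_moments()].
#' @param granularity `"moment"` (default) or `"sample"`.
#' @param mcv,y Required for sample granularity.
#' @return List of class `coord_eval`: `confusion` (tp, fp, fn, tn),
#'   `accuracy`, `precision`, `sensitivity`, `granularity`.
#' @export
evaluate_classification <- function(classified,
                                    granularity = c("moment", "sample"),
                                    mcv = NULL, y = 0.5) {
  granularity <- match.arg(granularity)
  if (granularity == "moment") {
    truth <- classified$label
    pred <- classified$predicted
  } else {
    if (is.null(mcv))
      stop("sample granularity needs the mcv series", call. = FALSE)
    truth <- character(0)
    pred <- character(0)
    for (i in seq_len(nrow(classified))) {
      v <- mcv$values[moment_sample_index(classified[i, ], mcv)]
      v <- v[!is.na(v)]
      truth <- c(truth, rep(classified$label[i], length(v)))
      pred <- c(pred, ifelse(v >= y, "high", "low"))
    }
  }
  keep <- truth %in% c("high", "low")
  truth <- truth[keep]
  pred <- pred[keep]
  tp <- sum(truth == "high" & pred == "high")
  fp <- sum(truth == "low" & pred == "high")
  fn <- sum(truth == "high" & pred == "low")
  tn <- sum(truth == "low" & pred == "low")
  n <- tp + fp + fn + tn
  structure(list(
    confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
    accuracy = if (n > 0) (tp + tn) / n else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    granularity = granularity), class = "coord_eval")
}

#' @export
print.coord_eval <- function(x, ...) {
  cat(sprintf("<coord_eval> (%s-level) tp %d fp %d fn %d tn %d\n",
              x$granularity, x$confusion["tp"], x$confusion["fp"],
              x$confusion["fn"], x$confusion["tn"]))
  cat(sprintf("  accuracy %.4f  precision %.4f  sensitivity %.4f\n",
              x$accuracy, x$precision, x$sensitivity))
  invisible(x)
}

#' Default perceptual-condition block schedule
#'
#' Five 3-minute blocks over the 15-minute improvisation, varying which
#' participant has eyes open: 1 both closed, 2 both open, 3 A open / B
#' closed, 4 A closed / B open, 5 both open.
#'
#' @return Data frame with `block`, `start`, `end`, `eyes_A`, `eyes_B`.
#' @export
default_block_schedule <- function() {
  data.frame(block = 1:5,
             start = (0:4) * 180, end = (1:5) * 180,
             eyes_A = c("closed", "open", "open", "closed", "open"),
             eyes_B = c("closed", "open", "closed", "open", "open"))
}

#' Perceptual condition of a moment
#'
#' The block containing the moment's midpoint (blocks are half-open
#' `[start, end)`; a midpoint exactly on a boundary belongs to the later
#' block; the session end belongs to the last block).
#'
#' @param moment One-row moment data frame or list with `start`, `end`.
#' @param schedule Block schedule (default [default_block_schedule()]).
#' @return List with `block`, `eyes_A`, `eyes_B`.
#' @export
condition_of <- function(moment, schedule = default_block_schedule()) {
  mid <- (moment$start + moment$end) / 2
  b <- which(mid >= schedule$start & mid < schedule$end)
  if (length(b) == 0 && mid == max(schedule$end)) b <- nrow(schedule)
  if (length(b) != 1)
    stop("moment midpoint outside the block schedule", call. = FALSE)
  list(block = schedule$block[b], eyes_A = schedule$eyes_A[b],
       eyes_B = schedule$eyes_B[b])
}

#' Read a participant segments CSV
#'
#' Expected columns: `participant`, `start_s`, `end_s`, `rating` (1-10),
#' `role`, `connection`, `flag3`, `flag4` (binary selections), `comment`.
#'
#' @param path CSV path.
#' @return Data frame of segments.
#' @export
read_segments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "start_s", "end_s", "rating")
  if (!all(need %in% names(df)))
    stop("segments CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$end_s <= df$start_s))
    stop("segment end must exceed start", call. = FALSE)
  if (any(df$rating < 1 | df$rating > 10))
    stop("coordination ratings must lie in 1..10", call. = FALSE)
  df
}

#' Co-occurring (moment, segment) pairs
#'
#' A moment and a segment co-occur when the moment interval, expanded by
#' `tolerance` seconds on each side (180 s total by default), intersects
#' the segment interval (closed intervals: touching counts).
#'
#' @param moments Data frame of moments (`start`, `end`).
#' @param segments Data frame of segments (`start_s`, `end_s`).
#' @param tolerance Expansion per side in seconds (default 90).
#' @return Data frame with `moment_idx`, `segment_idx` for each pair.
#' @export
cooccurring <- function(moments, segments, tolerance = 90) {
  pairs <- expand.grid(moment_idx = seq_len(nrow(moments)),
                       segment_idx = seq_len(nrow(segments)))
  hit <- mapply(function(mi, si) {
    (moments$start[mi] - tolerance) <= segments$end_s[si] &&
      segments$start_s[si] <= (moments$end[mi] + tolerance)
  }, pairs$moment_idx, pairs$segment_idx)
  pairs[as.logical(hit), , drop = FALSE]
}
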