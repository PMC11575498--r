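# Maximum correlation vector (MCV) and its data-sliding significance test.
#
# Temporal alignment between the dancers is measured with rolling-window
# Spearman correlations (5 s window by default) of hand speed for the four
# between-participant hand pairings; the MCV takes, at every time point, the
# maximum correlation across pairings, so that coordination is credited
# equally whichever (and however many) hands carry it.

#' Rolling-window Spearman correlation of two speed series
#'
#' Centered window of `round(window * fps)` samples, step 1 sample,
#' Spearman's rho with average ranks for ties. Values are undefined (`NA`)
#' at the edges (where the full window does not fit) and wherever either
#' window has zero variance.
#'
#' @param x,y [speed_series()] of equal length and frame rate.
#' @param window Window in seconds (default 5).
#' @return An object of class `corr_vector`: list with `values` (rho per
#'   time point, `NA` where undefined), `pairing`, `window`, `fps`.
#' @export
rolling_spearman <- function(x, y, window = 5) {
  if (length(x$values) != length(y$values))
    stop("speed series lengths differ", call. = FALSE)
  if (x$fps != y$fps) stop("speed series frame rates differ", call. = FALSE)
  w <- round(window * x$fps)
  if (w < 3) stop("window must cover at least 3 samples", call. = FALSE)
  vals <- cpp_rolling_spearman(x$values, y$values, as.integer(w))
  structure(list(values = vals, pairing = c(x$marker, y$marker),
                 window = window, fps = x$fps),
            class = "corr_vector")
}

#' @export
print.corr_vector <- function(x, ...) {
  cat(sprintf("<corr_vector> %s: %d points (%d defined), window %g s\n",
              pairing_label(x$pairing), length(x$values),
              sum(!is.na(x$values)), x$window))
  invisible(x)
}

#' Maximum correlation vector over the four hand pairings
#'
#' Pointwise maximum of the four between-participant correlation vectors
#' (`A_left-B_left`, `A_left-B_right`, `A_right-B_left`,
#' `A_right-B_right`); undefined pairings are skipped, a point where all
#' four are undefined stays undefined. The winning pairing is recorded.
#'
#' @param cvs List of the four `corr_vector`s, one per pairing.
#' @return An object of class `mcv_series`: list with `values`, `source`
#'   (winning pairing label per point, `NA` where undefined), `window`,
#'   `fps`.
#' @export
max_correlation_vector <- function(cvs) {
  if (length(cvs) != 4)
    stop("expected the four between-participant pairings", call. = FALSE)
  got <- sort(vapply(cvs, function(cv) pairing_label(cv$pairing), character(1)))
  want <- sort(vapply(PAIRINGS, pairing_label, character(1)))
  if (!identical(got, want))
    stop("wrong pairing set: expected ", paste(want, collapse = ", "),
         call. = FALSE)
  lens <- vapply(cvs, function(cv) length(cv$values), integer(1))
  if (length(unique(lens)) != 1)
    stop("correlation vectors are not aligned", call. = FALSE)
  m <- do.call(cbind, lapply(cvs, `[[`, "values"))
  colnames(m) <- vapply(cvs, function(cv) pairing_label(cv$pairing),
                        character(1))
  all_na <- rowSums(!is.na(m)) == 0
  vals <- rep(NA_real_, nrow(m))
  src <- rep(NA_character_, nrow(m))
  if (any(!all_na)) {
    idx <- max.col(replace(m, is.na(m), -Inf), ties.method = "first")
    vals[!all_na] <- m[cbind(which(!all_na), idx[!all_na])]
    src[!all_na] <- colnames(m)[idx[!all_na]]
  }
  structure(list(values = vals, source = src,
                 window = cvs[[1]]$window, fps = cvs[[1]]$fps),
            class = "mcv_series")
}

#' @export
print.mcv_series <- function(x, ...) {
  cat(sprintf("<mcv_series> %d points (%d defined), window %g s @ %g fps\n",
              length(x$values), sum(!is.na(x$values)), x$window, x$fps))
  invisible(x)
}

#' Compute the MCV directly from preprocessed speeds
#'
#' Convenience wrapper: builds the four pairing correlation vectors with
#' [rolling_spearman()] and reduces them with [max_correlation_vector()].
#'
#' @param speeds Named list of four [speed_series()] (as from
#'   [preprocess_speeds()]).
#' @param window Rolling window in seconds (default 5).
#' @return An `mcv_series`; the four `corr_vector`s are attached as
#'   attribute `"cvs"`.
#' @export
compute_mcv <- function(speeds, window = 5) {
  cvs <- lapply(PAIRINGS, function(p)
    rolling_spearman(speeds[[p[1]]], speeds[[p[2]]], window = window))
  out <- max_correlation_vector(cvs)
  attr(out, "cvs") <- cvs
  out
}

#' Slide (rotate) a series about a cut point
#'
#' Surrogate construction for the significance test: the series is cut at a
#' random point and the two pieces are swapped, destroying cross-alignment
#' with the partner's series while preserving autocorrelation.
#'
#' @param x A [speed_series()] or numeric vector.
#' @param cut Cut index in `0..length(x)`; 0 and `length(x)` are identities.
#' @return Object of the same type, values rotated.
#' @export
slide_series <- function(x, cut) {
  v <- if (inherits(x, "speed_series")) x$values else x
  n <- length(v)
  if (cut < 0 || cut > n) stop("cut out of range 0..", n, call. = FALSE)
  slid <- if (cut == 0 || cut == n) v else c(v[(cut + 1):n], v[1:cut])
  if (inherits(x, "speed_series")) {
    x$values <- slid
    x
  } else slid
}

#' Data-sliding significance threshold for a moment
#'
#' Within a rated moment, one participant's two hand-speed series are slid
#' jointly at a uniformly random cut; the MCV is recomputed against the
#' other participant's unshuffled series; all defined shuffled MCV values
#' across all slides are pooled and the threshold is the requested
#' percentile of the pool (linear interpolation between order statistics).
#'
#' @param speeds Named list of the four [speed_series()] for the session.
#' @param moment A single-row moment (see [read_moments_csv()]) or list with
#'   `start` and `end` in seconds; must span at least 10 s.
#' @param n_slides Number of random slides (default 1000).
#' @param percentile Percentile of the pooled distribution (default 95).
#' @param window Rolling-correlation window in seconds (default 5).
#' @param slide Which participant's series to slide, `"A"` or `"B"`
#'   (default `"A"`).
#' @param seed Optional RNG seed, recorded in the result.
#' @param keep_pool Keep the pooled shuffled MCV values in the result
#'   (default `FALSE`; the pool can be large).
#' @return Object of class `sig_threshold`: list with `threshold`,
#'   `n_slides`, `percentile`, `seed`, `moment`, and optionally `pool`.
#' @export
significance_threshold <- function(speeds, moment, n_slides = 1000,
                                   percentile = 95, window = 5,
                                   slide = c("A", "B"), seed = NULL,
                                   keep_pool = FALSE) {
  slide <- match.arg(slide)
  fps <- speeds[[1]]$fps
  idx <- moment_sample_index(moment, speeds[[1]])
  if (length(idx) < round(10 * fps))
    stop("moment must span at least 10 s of samples", call. = FALSE)
  w <- round(window * fps)
  if (w > length(idx)) stop("window longer than the moment", call. = FALSE)
  seg <- lapply(speeds[MARKER_IDS], function(s) s$values[idx])
  L <- length(idx)
  cuts <- with_seed(seed, sample.int(L + 1L, n_slides, replace = TRUE) - 1L)
  if (slide == "A")
    pool <- cpp_slide_mcv_pool(seg$A_left, seg$A_right,
                               seg$B_left, seg$B_right,
                               as.integer(w), as.integer(cuts))
  else
    pool <- cpp_slide_mcv_pool(seg$B_left, seg$B_right,
                               seg$A_left, seg$A_right,
                               as.integer(w), as.integer(cuts))
  if (length(pool) == 0)
    stop("undefined threshold: all shuffled windows degenerate ",
         "(zero-variance speeds)", call. = FALSE)
  thr <- unname(stats::quantile(pool, percentile / 100, type = 7))
  structure(list(threshold = thr, n_slides = n_slides,
                 percentile = percentile, seed = seed,
                 moment = list(start = moment$start, end = moment$end),
                 pool = if (keep_pool) pool else NULL),
            class = "sig_threshold")
}

#' @export
print.sig_threshold <- function(x, ...) {
  cat(sprintf(
    "<sig_threshold> moment [%g, %g] s: rho = %.4f (%gth pct of %d slides)\n",
    x$moment$start, x$moment$end, x$threshold, x$percentile, x$n_slides))
  invisible(x)
}

#' Write MCV (and its pairing correlations) to CSV
#'
#' @param mcv An `mcv_series` from [compute_mcv()] (with attached pairing
#'   vectors).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mcv_csv <- function(mcv, path) {
  df <- data.frame(t_s = seq_along(mcv$values) / mcv$fps)
  cvs <- attr(mcv, "cvs")
  if (!is.null(cvs))
    for (cv in cvs) df[[paste0("cv_", pairing_label(cv$pairing))]] <- cv$values
  df$mcv <- mcv$values
  df$source_pairing <- mcv$source
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
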