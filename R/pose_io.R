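# Reading, writing and conditioning pose-tracker output.
#
# The central container is the `pose_track`: per-frame (x, y, likelihood)
# for the four hand markers of a dyad (participants A and B, left and right
# hand), sampled on a fixed frame grid (60 Hz by default). Coordinates come
# from markerless pose estimation of an overhead camera view, so each sample
# carries the tracker's own confidence ("likelihood" in [0, 1]).

#' Construct a pose track
#'
#' A `pose_track` holds per-frame planar coordinates and tracker likelihoods
#' for the four hand markers of a dyad: `A_left`, `A_right`, `B_left`,
#' `B_right`. All four sequences share one frame grid.
#'
#' @param markers Named list with one entry per marker id; each entry a list
#'   (or data frame) with numeric vectors `x`, `y` (pixels) and `likelihood`
#'   (in \[0, 1\]), all of equal length.
#' @param fps Frame rate in frames per second (default 60).
#' @return An object of class `pose_track` with elements `fps`, `frames` and
#'   `markers` (each marker additionally carries a logical `masked` vector,
#'   initially all `FALSE`).
#' @export
pose_track <- function(markers, fps = 60) {
  if (!all(MARKER_IDS %in% names(markers)))
    stop("markers must contain all of: ", paste(MARKER_IDS, collapse = ", "),
         call. = FALSE)
  markers <- markers[MARKER_IDS]
  lens <- vapply(markers, function(m) length(m$x), integer(1))
  if (length(unique(lens)) != 1)
    stop("all marker sequences must have identical length", call. = FALSE)
  frames <- lens[[1]]
  markers <- lapply(markers, function(m) {
    m <- list(x = as.numeric(m$x), y = as.numeric(m$y),
              likelihood = as.numeric(m$likelihood),
              masked = if (!is.null(m$masked)) as.logical(m$masked)
                       else rep(FALSE, frames))
    if (length(m$y) != frames || length(m$likelihood) != frames)
      stop("x, y and likelihood must have equal length", call. = FALSE)
    bad <- m$likelihood < 0 | m$likelihood > 1
    if (any(bad, na.rm = TRUE))
      stop("likelihood values must lie in [0, 1]", call. = FALSE)
    if (any(!is.finite(m$x[!m$masked])) || any(!is.finite(m$y[!m$masked])))
      stop("coordinates must be finite where not masked", call. = FALSE)
    m
  })
  structure(list(fps = fps, frames = frames, markers = markers),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames @ %g fps (%.1f s), markers: %s\n",
              x$frames, x$fps, x$frames / x$fps,
              paste(names(x$markers), collapse = ", ")))
  masked <- sum(vapply(x$markers, function(m) sum(m$masked), numeric(1)))
  if (masked > 0) cat(sprintf("  %d masked samples\n", masked))
  invisible(x)
}

#' Default marker-name mapping
#'
#' Maps the four canonical marker ids to the body-part names used in the
#' pose-estimation project. Tracker projects name parts freely, so readers
#' take the mapping as an argument rather than hardcoding names.
#'
#' @return Named character vector: canonical id -> body-part name.
#' @export
default_marker_map <- function() {
  c(A_left = "A_left", A_right = "A_right",
    B_left = "B_left", B_right = "B_right")
}

#' Read a DeepLabCut-dialect coordinate CSV
#'
#' The dialect has three header rows (`scorer`, `bodyparts`, `coords`) and
#' one column triplet `x`, `y`, `likelihood` per body part; the first column
#' indexes frames. Non-hand body parts are ignored; the four hand markers
#' are located through `marker_map`.
#'
#' @param path Path to the CSV file.
#' @param marker_map Named character vector mapping the canonical marker ids
#'   (`A_left`, ...) to body-part names in the file.
#' @param fps Frame rate of the recording (default 60).
#' @return A [pose_track()].
#' @export
read_dlc_csv <- function(path, marker_map = default_marker_map(), fps = 60) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("not a DeepLabCut CSV: fewer than 3 header rows", call. = FALSE)
  hdr <- lapply(lines[1:3], function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  tags <- vapply(hdr, `[`, character(1), 1)
  if (!identical(tolower(tags), c("scorer", "bodyparts", "coords")))
    stop("not a DeepLabCut CSV: expected header rows scorer/bodyparts/coords, ",
         "found: ", paste(tags, collapse = "/"), call. = FALSE)
  bodyparts <- hdr[[2]][-1]
  coords <- hdr[[3]][-1]
  ncol_expected <- length(hdr[[1]])
  if (length(hdr[[2]]) != ncol_expected || length(hdr[[3]]) != ncol_expected)
    stop("ragged header rows", call. = FALSE)

  data_lines <- lines[-(1:3)]
  data_lines <- data_lines[nzchar(data_lines)]
  rows <- lapply(data_lines, function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  if (length(rows) > 0 &&
      any(vapply(rows, length, integer(1)) != ncol_expected))
    stop("ragged data rows", call. = FALSE)
  mat <- if (length(rows) > 0)
    matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  else matrix(numeric(0), nrow = 0, ncol = ncol_expected)

  markers <- lapply(MARKER_IDS, function(id) {
    bp <- marker_map[[id]]
    if (is.null(bp) || is.na(bp))
      stop("marker_map has no entry for ", id, call. = FALSE)
    cols <- which(bodyparts == bp) + 1L  # +1 for the frame-index column
    if (length(cols) == 0)
      stop("body part '", bp, "' (marker ", id, ") not found in file",
           call. = FALSE)
    xi <- cols[coords[cols - 1L] == "x"]
    yi <- cols[coords[cols - 1L] == "y"]
    li <- cols[coords[cols - 1L] == "likelihood"]
    if (length(xi) != 1 || length(yi) != 1 || length(li) != 1)
      stop("body part '", bp, "' lacks an x/y/likelihood column triplet",
           call. = FALSE)
    list(x = mat[, xi], y = mat[, yi], likelihood = mat[, li])
  })
  names(markers) <- MARKER_IDS
  pose_track(markers, fps = fps)
}

#' Write a pose track in the DeepLabCut CSV dialect
#'
#' @param track A [pose_track()].
#' @param path Output file path.
#' @param marker_map Canonical id -> body-part name mapping used for the
#'   `bodyparts` header row.
#' @param scorer Scorer name for the first header row.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(track, path, marker_map = default_marker_map(),
                          scorer = "dyadcoord") {
  ids <- MARKER_IDS
  bp <- unname(marker_map[ids])
  h1 <- paste(c("scorer", rep(scorer, 3 * length(ids))), collapse = ",")
  h2 <- paste(c("bodyparts", rep(bp, each = 3)), collapse = ",")
  h3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(ids))),
              collapse = ",")
  cols <- do.call(cbind, lapply(track$markers[ids], function(m)
    cbind(m$x, m$y, m$likelihood)))
  body <- apply(cbind(seq_len(track$frames) - 1L, cols), 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = ","))
  writeLines(c(h1, h2, h3, body), path)
  invisible(path)
}

#' Read a plain long-format coordinate CSV
#'
#' Columns: `frame`, `participant` (A/B), `hand` (left/right), `x`, `y`,
#' `likelihood`.
#'
#' @param path Path to the CSV file.
#' @param fps Frame rate (default 60).
#' @return A [pose_track()].
#' @export
read_pose_long <- function(path, fps = 60) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "participant", "hand", "x", "y", "likelihood")
  if (!all(need %in% names(df)))
    stop("long pose CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$id <- paste(df$participant, df$hand, sep = "_")
  markers <- lapply(MARKER_IDS, function(id) {
    sub <- df[df$id == id, ]
    if (nrow(sub) == 0) stop("marker ", id, " absent from file", call. = FALSE)
    sub <- sub[order(sub$frame), ]
    list(x = sub$x, y = sub$y, likelihood = sub$likelihood)
  })
  names(markers) <- MARKER_IDS
  pose_track(markers, fps = fps)
}

#' Write a pose track as a plain long-format CSV
#'
#' @inheritParams write_dlc_csv
#' @return `path`, invisibly.
#' @export
write_pose_long <- function(track, path) {
  dfs <- lapply(MARKER_IDS, function(id) {
    m <- track$markers[[id]]
    ph <- strsplit(id, "_", fixed = TRUE)[[1]]
    data.frame(frame = seq_len(track$frames) - 1L,
               participant = ph[1], hand = ph[2],
               x = m$x, y = m$y, likelihood = m$likelihood)
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' Mask and fill low-confidence samples
#'
#' Samples whose tracker likelihood falls below `cutoff` are treated as
#' missing and filled by 1-D linear interpolation from the nearest retained
#' neighbors (leading/trailing runs take the nearest retained value), which
#' keeps the fixed frame grid intact for downstream rolling-window measures.
#'
#' @param track A [pose_track()].
#' @param cutoff Likelihood threshold in \[0, 1\] (default 0.6).
#' @return A `pose_track` with sub-cutoff samples masked and interpolated.
#' @export
apply_pcutoff <- function(track, cutoff = 0.6) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  track$markers <- lapply(names(track$markers), function(id) {
    m <- track$markers[[id]]
    mask <- m$likelihood < cutoff
    if (all(mask))
      stop("marker ", id, " unusable: all samples below likelihood cutoff ",
           cutoff, call. = FALSE)
    m$x <- interp_masked(m$x, mask)
    m$y <- interp_masked(m$y, mask)
    m$masked <- m$masked | mask
    m
  })
  names(track$markers) <- MARKER_IDS
  track
}

#' Median-filter marker coordinates
#'
#' Replaces each coordinate sequence by a centered rolling median, the
#' standard conditioning step for single-frame tracker glitches. Edges use
#' shrunken (smaller, still centered) windows.
#'
#' @param track A [pose_track()].
#' @param window Window length in frames; odd, >= 1 (default 5).
#' @return The filtered `pose_track`.
#' @export
median_filter_track <- function(track, window = 5) {
  if (window %% 2 != 1 || window < 1)
    stop("median filter window must be odd and >= 1", call. = FALSE)
  if (window > 1) {
    track$markers <- lapply(track$markers, function(m) {
      m$x <- rolling_median(m$x, window)
      m$y <- rolling_median(m$y, window)
      m
    })
  }
  track
}

# Centered rolling median; positions within half a window of either edge use
# the largest centered window that fits (shrunken, still odd).
rolling_median <- function(x, window) {
  n <- length(x)
  if (n == 0 || window <= 1) return(x)
  k <- min(window, if (n %% 2 == 1) n else n - 1)
  out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  h <- (k - 1) %/% 2
  edge <- unique(c(seq_len(min(h, n)), seq.int(max(n - h + 1, 1), n)))
  for (i in edge) {
    hi <- min(h, i - 1, n - i)
    out[i] <- stats::median(x[(i - hi):(i + hi)])
  }
  out
}
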