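# Synthetic dyad sessions with scripted ground truth.
#
# Two participants x two hands of (x, y, likelihood) at 60 Hz on a bounded
# table surface (900 x 900 px), with scripted episodes of (i) lagged
# unidirectional coupling (a leader's hand speed drives the follower's with
# a known lag), (ii) mutual independence, and (iii) joint stillness.
# Hand speeds are generated directly (all estimators in this package
# consume speed); positions integrate speed along slowly wandering
# headings, reflecting at the table bounds, so coordinate-level readers and
# the likelihood/median-filter conditioning path can be exercised too.
# During joint stillness both dancers share a slow micro-movement component
# (rest/sway dynamics, ~2 px/s): being still together is itself coordinated
# behavior, and it yields the high rank-correlation of near-constant speeds
# that raters score as high coordination, without degenerate zero-variance
# windows.

#' Episode script entry
#'
#' @param start,end Episode interval in seconds.
#' @param mode `"coupled"`, `"independent"` or `"stillness"`.
#' @param leader For coupled episodes: `"A"` or `"B"`.
#' @param lag Coupling lag in ms (coupled only; 50-400 ms).
#' @param coupling Coupling strength alpha in \[0, 1\] (default 0.9).
#' @param noise_sd White measurement-style jitter added to speeds, px/s
#'   (default 5).
#' @return One-row data frame.
#' @export
episode_spec <- function(start, end, mode = c("coupled", "independent",
                                              "stillness"),
                         leader = "A", lag = 150, coupling = 0.9,
                         noise_sd = 5) {
  mode <- match.arg(mode)
  stopifnot(end > start)
  if (mode == "coupled") {
    stopifnot(leader %in% c("A", "B"), lag >= 50, lag <= 400,
              coupling >= 0, coupling <= 1)
  }
  data.frame(start = start, end = end, mode = mode,
             leader = if (mode == "coupled") leader else NA_character_,
             lag = if (mode == "coupled") lag else NA_real_,
             coupling = if (mode == "coupled") coupling else NA_real_,
             noise_sd = noise_sd)
}

#' Default episode script
#'
#' One clear episode of each kind in a session: A-led coupling, mutual
#' independence, joint stillness, and B-led coupling.
#'
#' @param duration Session length in seconds (default 900).
#' @return Episode data frame (see [episode_spec()]).
#' @export
default_episodes <- function(duration = 900) {
  stopifnot(duration >= 300)
  rbind(
    episode_spec(30, 70, "coupled", leader = "A", lag = 150),
    episode_spec(100, 140, "independent"),
    episode_spec(170, 210, "stillness"),
    episode_spec(240, 280, "coupled", leader = "B", lag = 150))
}

# Nonnegative, smoothed AR(1) latent hand speed (px/s). Typical improvised
# table-top hand movement: mean ~120 px/s, sd ~60, never negative.
# Movement-unit timescale ~0.25 s (AR phi = 0.9 at 60 Hz plus 0.1 s
# shaping): lively improvisation shows speed fluctuations at a few Hz, and
# scripted coupling lags in the 50-400 ms band are only resolvable when the
# signal carries power at comparable periods.
latent_speed <- function(n, fps, mean_speed = 120, sd_speed = 60,
                         phi = 0.9) {
  e <- stats::rnorm(n, 0, sqrt(1 - phi^2))
  z <- as.numeric(stats::filter(e, phi, method = "recursive"))
  z <- moving_mean(z, max(1, round(0.1 * fps)))
  pmax(mean_speed + sd_speed * z / stats::sd(z), 0)
}

# Slow shared micro-movement during joint stillness (px/s scale `sd`).
stillness_speed <- function(n, fps, sd = 2) {
  z <- as.numeric(stats::filter(stats::rnorm(n), 0.99, method = "recursive"))
  z <- moving_mean(z, max(1, round(0.5 * fps)))
  abs(z / stats::sd(z)) * sd
}

#' Simulate a synthetic dyad session
#'
#' @param episodes Episode script (see [episode_spec()]); episodes must be
#'   ordered and non-overlapping and fit in `duration`. Time outside
#'   episodes is unscripted independent movement.
#' @param duration Session length in seconds (default 900).
#' @param fps Frame rate (default 60).
#' @param seed RNG seed; the same seed reproduces the track bit-exactly.
#' @param stillness_sd Shared micro-movement scale during stillness, px/s
#'   (default 2; set 0 to exercise degenerate zero-variance windows).
#' @param dropout_prob Per-frame probability of a tracker likelihood
#'   dropout below 0.6 (default 0.005).
#' @param table_px Table surface size in pixels (default 900).
#' @return Object of class `synth_session`: list with `track`
#'   ([pose_track()]), `speeds` (the four latent [speed_series()]),
#'   `episodes`, `seed`.
#' @export
simulate_dyad <- function(episodes = default_episodes(duration),
                          duration = 900, fps = 60, seed = 1,
                          stillness_sd = 2, dropout_prob = 0.005,
                          table_px = 900) {
  episodes <- episodes[order(episodes$start), , drop = FALSE]
  if (nrow(episodes) > 1 &&
      any(episodes$start[-1] < episodes$end[-nrow(episodes)]))
    stop("episodes overlap", call. = FALSE)
  if (any(episodes$start < 0) || any(episodes$end > duration))
    stop("episodes do not fit in the session duration", call. = FALSE)

  n <- round(duration * fps)  # coordinate frames
  with_seed(seed, {
    hands <- c("A_left", "A_right", "B_left", "B_right")
    # Independent latent speed per hand (n-1 inter-frame samples).
    v <- lapply(hands, function(h) latent_speed(n - 1, fps))
    names(v) <- hands

    for (i in seq_len(nrow(episodes))) {
      ep <- episodes[i, ]
      lo <- max(1, round(ep$start * fps))
      hi <- min(n - 1, round(ep$end * fps))
      idx <- lo:hi
      if (ep$mode == "coupled") {
        lead <- ep$leader
        foll <- setdiff(c("A", "B"), lead)
        lag_smp <- max(1, round(ep$lag / 1000 * fps))
        for (side in c("left", "right")) {
          lh <- paste(lead, side, sep = "_")
          fh <- paste(foll, side, sep = "_")
          src <- v[[lh]][pmax(idx - lag_smp, 1)]
          v[[fh]][idx] <- ep$coupling * src +
            (1 - ep$coupling) * v[[fh]][idx]
        }
      } else if (ep$mode == "stillness") {
        common <- stillness_speed(length(idx), fps, sd = stillness_sd)
        for (h in hands)
          v[[h]][idx] <- common +
            abs(stats::rnorm(length(idx), 0, 0.15 * max(stillness_sd, 1e-3)))
      }
      # Measurement-style jitter, clipped to nonnegative speeds.
      if (ep$noise_sd > 0)
        for (h in hands)
          v[[h]][idx] <- pmax(v[[h]][idx] +
                                stats::rnorm(length(idx), 0, ep$noise_sd), 0)
    }

    # Integrate positions along slowly wandering headings, reflecting at the
    # table bounds so |step| / dt always equals the scripted speed.
    markers <- lapply(hands, function(h) {
      dtheta <- stats::rnorm(n - 1, 0, 0.08)
      pos <- matrix(0, nrow = n, ncol = 2)
      pos[1, ] <- stats::runif(2, 0.25 * table_px, 0.75 * table_px)
      dt <- 1 / fps
      theta <- stats::runif(1, 0, 2 * pi)
      for (i in seq_len(n - 1)) {
        # wandering heading with a gentle pull toward the table center so
        # hands work the surface rather than pinning to an edge
        to_center <- atan2(table_px / 2 - pos[i, 2], table_px / 2 - pos[i, 1])
        pull <- atan2(sin(to_center - theta), cos(to_center - theta))
        edge <- max(abs(pos[i, ] - table_px / 2)) / (table_px / 2)
        theta <- theta + dtheta[i] + 0.1 * max(edge - 0.6, 0) * pull
        dir <- c(cos(theta), sin(theta))
        p <- pos[i, ] + v[[h]][i] * dt * dir
        for (d in 1:2) {  # specular reflection: position folds, heading flips
          if (p[d] < 0) { p[d] <- -p[d]; dir[d] <- -dir[d] }
          if (p[d] > table_px) { p[d] <- 2 * table_px - p[d]; dir[d] <- -dir[d] }
        }
        theta <- atan2(dir[2], dir[1])
        pos[i + 1, ] <- p
      }
      lik <- pmin(pmax(stats::rnorm(n, 0.95, 0.02), 0), 1)
      drop <- stats::runif(n) < dropout_prob
      lik[drop] <- stats::runif(sum(drop), 0.05, 0.55)
      list(x = pos[, 1], y = pos[, 2], likelihood = lik)
    })
    names(markers) <- hands
    track <- pose_track(markers, fps = fps)
    speeds <- lapply(hands, function(h)
      speed_series(v[[h]], fps = fps, marker = h))
    names(speeds) <- hands
    structure(list(track = track, speeds = speeds, episodes = episodes,
                   seed = seed, duration = duration),
              class = "synth_session")
  })
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf("<synth_session> %g s @ %g fps, seed %s, %d episodes\n",
              x$duration, x$track$fps, format(x$seed), nrow(x$episodes)))
  print(x$episodes)
  invisible(x)
}

#' Ground-truth moments of a synthetic session
#'
#' Coupled and joint-stillness episodes map to rated label `"high"` (being
#' still together is operationally high coordination), independent episodes
#' to `"low"`. Episodes shorter than 10 s are excluded (they cannot be
#' moments).
#'
#' @param session A `synth_session`.
#' @return Data frame of moments (`start`, `end`, `label`).
#' @export
ground_truth_moments <- function(session) {
  ep <- session$episodes
  ep <- ep[ep$end - ep$start >= 10, , drop = FALSE]
  if (nrow(ep) == 0) return(data.frame(start = numeric(0), end = numeric(0),
                                       label = character(0)))
  do.call(rbind, lapply(seq_len(nrow(ep)), function(i)
    moment(ep$start[i], ep$end[i],
           if (ep$mode[i] == "independent") "low" else "high",
           session_duration = session$duration)))
}

#' Write a synthetic session to disk
#'
#' Writes the pose track as a DeepLabCut-dialect CSV and the episode script
#' plus ground-truth moments as a JSON sidecar.
#'
#' @param session A `synth_session`.
#' @param csv_path Output coordinate CSV path.
#' @param json_path Optional ground-truth JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_synth_session <- function(session, csv_path, json_path = NULL) {
  write_dlc_csv(session$track, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(seed = session$seed, duration = session$duration,
           episodes = session$episodes,
           moments = ground_truth_moments(session)),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(csv_path)
}
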