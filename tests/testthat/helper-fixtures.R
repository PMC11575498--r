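# Fixture builders and independent brute-force oracles used across tests.

# A tiny pose track built directly from coordinate vectors; all four markers
# get the same likelihoods unless overridden.
make_track <- function(coords, fps = 60, likelihood = NULL) {
  n <- length(coords[[1]]$x)
  if (is.null(likelihood)) likelihood <- rep(0.99, n)
  markers <- lapply(dyadcoord:::MARKER_IDS, function(id) {
    m <- coords[[id]]
    list(x = m$x, y = m$y,
         likelihood = if (!is.null(m$likelihood)) m$likelihood else likelihood)
  })
  names(markers) <- dyadcoord:::MARKER_IDS
  pose_track(markers, fps = fps)
}

# Same random-walk coordinates for every marker.
make_walk_track <- function(n, fps = 60, seed = 1) {
  set.seed(seed)
  coords <- lapply(dyadcoord:::MARKER_IDS, function(id)
    list(x = cumsum(rnorm(n)) + 100, y = cumsum(rnorm(n)) + 100))
  names(coords) <- dyadcoord:::MARKER_IDS
  make_track(coords, fps = fps)
}

make_speed <- function(values, fps = 60, marker = "A_left") {
  speed_series(values, fps = fps, marker = marker)
}

# Independent smoothed-noise speed set for all four hands.
make_noise_speeds <- function(n, fps = 60, seed = 1) {
  set.seed(seed)
  out <- lapply(dyadcoord:::MARKER_IDS, function(id)
    smooth_series(make_speed(pmax(120 + 60 * rnorm(n), 0), fps, id)))
  names(out) <- dyadcoord:::MARKER_IDS
  out
}

# An mcv_series with prescribed values (for classifier tests).
make_mcv <- function(values, fps = 60) {
  structure(list(values = as.numeric(values),
                 source = rep("A_left-B_left", length(values)),
                 window = 5, fps = fps),
            class = "mcv_series")
}

# Oracle: per-position Spearman over centered windows, via stats::cor.
naive_rolling_spearman <- function(x, y, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  kb <- ceiling((w - 1) / 2)
  kf <- (w - 1) - kb
  for (i in seq_len(n)) {
    if (i - kb < 1 || i + kf > n) next
    xi <- x[(i - kb):(i + kf)]
    yi <- y[(i - kb):(i + kf)]
    if (length(unique(xi)) < 2 || length(unique(yi)) < 2) next
    suppressWarnings(r <- stats::cor(xi, yi, method = "spearman"))
    out[i] <- r
  }
  out
}

# Oracle: per-position median over centered shrunken windows.
naive_rolling_median <- function(x, w) {
  n <- length(x)
  h <- (w - 1) %/% 2
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1, n - i)
    stats::median(x[(i - hi):(i + hi)])
  }, numeric(1))
}

# Oracle: triple-loop plug-in STE over the full count table (bits).
naive_ste <- function(src, tgt, delta, ns = max(src, tgt) + 1L) {
  n <- length(tgt) - delta
  yf <- tgt[(1 + delta):length(tgt)] + 1L
  yn <- tgt[1:n] + 1L
  x <- src[1:n] + 1L
  cnt <- array(0L, dim = c(ns, ns, ns))  # [x, yn, yf]
  for (t in seq_len(n)) cnt[x[t], yn[t], yf[t]] <- cnt[x[t], yn[t], yf[t]] + 1L
  acc <- 0
  for (i in 1:ns) for (j in 1:ns) for (k in 1:ns) {
    c3 <- cnt[i, j, k]
    if (c3 == 0) next
    c_yn_x <- sum(cnt[i, j, ])
    c_yf_yn <- sum(cnt[, j, k])
    c_yn <- sum(cnt[, j, ])
    acc <- acc + (c3 / n) * log2((c3 * c_yn) / (c_yn_x * c_yf_yn))
  }
  acc
}
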