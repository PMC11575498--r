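# Normalized symbolic transfer entropy (NSTE) and the leader-follower
# asymmetry index.
#
# Transfer entropy quantifies how much the past of a source signal improves
# prediction of a target signal's future beyond the target's own past.
# Symbolizing both signals as ordinal (rank) patterns of m-sample delay
# embeddings makes the estimate robust and cheap; subtracting the mean STE
# obtained with the source symbols shuffled removes small-sample and
# source-signal bias, and dividing by the target's conditional entropy
# H(future | past) makes values comparable across signal pairs. The result
# lies in [-1, 1] (slightly negative values can occur by chance under
# independence).

#' NSTE parameter set
#'
#' @param m Embedding dimension (default 3; symbols are the `m!` rank
#'   permutations).
#' @param tau_range Embedding/prediction delays in samples (default `6:15`,
#'   i.e. 100-250 ms at 60 Hz). The prediction step delta equals tau.
#' @param window Analysis window in seconds (default 2).
#' @param step Window step in seconds (default 0.5).
#' @param n_shuffles Source shuffles for the bias term (default 10).
#' @param tau_aggregate How directed values are aggregated over `tau_range`
#'   and hand pairings: `"max"` (default, the most informative delay) or
#'   `"mean"`.
#' @param fps Frame rate (default 60).
#' @return List of class `nste_params`.
#' @export
nste_params <- function(m = 3, tau_range = 6:15, window = 2, step = 0.5,
                        n_shuffles = 10, tau_aggregate = c("max", "mean"),
                        fps = 60) {
  tau_aggregate <- match.arg(tau_aggregate)
  stopifnot(m >= 2, all(tau_range >= 1), window > 0, step > 0,
            n_shuffles >= 1)
  if (round(window * fps) <= (m - 1) * max(tau_range) + max(tau_range))
    stop("window too short for the embedding span plus prediction step",
         call. = FALSE)
  structure(list(m = m, tau_range = as.integer(tau_range), window = window,
                 step = step, n_shuffles = n_shuffles,
                 tau_aggregate = tau_aggregate, fps = fps),
            class = "nste_params")
}

#' Ordinal-pattern symbolization
#'
#' Each delay-embedded vector `(x_t, x_{t+tau}, ..., x_{t+(m-1)tau})` is
#' mapped to the index of its rank permutation (lexicographic order over
#' permutations, 0-based); ties rank the earlier position lower.
#'
#' @param x Numeric vector (or [speed_series()]) segment.
#' @param m Embedding dimension.
#' @param tau Embedding delay in samples.
#' @return Object of class `symbol_series`: list with `symbols` (integers in
#'   `0..factorial(m)-1`, length `length(x) - (m-1)*tau`), `m`, `tau`.
#' @export
ordinal_symbolize <- function(x, m = 3, tau = 1) {
  if (inherits(x, "speed_series")) x <- x$values
  n <- length(x)
  span <- (m - 1) * tau
  if (n <= span)
    stop("segment too short for embedding: need > ", span, " samples",
         call. = FALSE)
  emb <- vapply(0:(m - 1), function(k) x[(1 + k * tau):(n - span + k * tau)],
                numeric(n - span))
  if (is.null(dim(emb))) emb <- matrix(emb, nrow = 1)
  syms <- apply(emb, 1, function(v) {
    perm <- order(v)  # ties: earlier position first (order() is stable)
    perm_index(perm, m)
  })
  structure(list(symbols = as.integer(syms), m = m, tau = tau),
            class = "symbol_series")
}

# Lexicographic index (0-based) of a permutation of 1..m (Lehmer code).
perm_index <- function(perm, m) {
  idx <- 0L
  for (i in seq_len(m - 1)) {
    idx <- idx + sum(perm[(i + 1):m] < perm[i]) * factorial(m - i)
  }
  as.integer(idx)
}

#' Plug-in symbolic transfer entropy
#'
#' Empirical estimate over the triplets `(tgt_{t+delta}, tgt_t, src_t)`:
#' `STE = sum p(yf, yn, x) * log2( p(yf | yn, x) / p(yf | yn) )` in bits.
#' Always nonnegative; 0 when the target has fewer than two distinct
#' symbols.
#'
#' @param src,tgt `symbol_series` (see [ordinal_symbolize()]) or plain
#'   integer symbol vectors, aligned and of equal length.
#' @param delta Prediction step in symbol samples.
#' @return STE in bits (scalar).
#' @export
ste <- function(src, tgt, delta) {
  s <- if (inherits(src, "symbol_series")) src$symbols else as.integer(src)
  y <- if (inherits(tgt, "symbol_series")) tgt$symbols else as.integer(tgt)
  if (length(s) != length(y))
    stop("source and target symbol series must be aligned", call. = FALSE)
  n <- length(y) - delta
  if (n < 1) stop("not enough symbols for prediction step ", delta,
                  call. = FALSE)
  ns <- max(s, y) + 1L
  yf <- y[(1 + delta):length(y)]
  yn <- y[1:n]
  x <- s[1:n]
  ste_fast(x, yn, yf, ns)
}

# Vectorized plug-in STE from aligned code vectors (0-based symbols).
ste_fast <- function(x, yn, yf, ns) {
  n <- length(x)
  joint <- tabulate(yf * ns * ns + yn * ns + x + 1L, nbins = ns^3)
  n_yn_x <- tabulate(yn * ns + x + 1L, nbins = ns^2)
  n_yf_yn <- tabulate(yf * ns + yn + 1L, nbins = ns^2)
  n_yn <- tabulate(yn + 1L, nbins = ns)
  idx <- which(joint > 0)
  v <- idx - 1L
  xi <- v %% ns
  yni <- (v %/% ns) %% ns
  yfi <- v %/% (ns * ns)
  c3 <- joint[idx]
  acc <- sum(c3 / n * log2((c3 * n_yn[yni + 1L]) /
                           (n_yn_x[yni * ns + xi + 1L] *
                            n_yf_yn[yfi * ns + yni + 1L])))
  max(acc, 0)
}

# Vectorized H(yf | yn) in bits from aligned code vectors.
cond_entropy_fast <- function(yn, yf, ns) {
  n <- length(yn)
  n_yf_yn <- tabulate(yf * ns + yn + 1L, nbins = ns^2)
  n_yn <- tabulate(yn + 1L, nbins = ns)
  idx <- which(n_yf_yn > 0)
  v <- idx - 1L
  yni <- v %% ns
  c2 <- n_yf_yn[idx]
  -sum(c2 / n * log2(c2 / n_yn[yni + 1L]))
}

#' STE from a joint count (or probability) table
#'
#' @param counts 3-D array indexed `[x, yn, yf]` of counts or joint
#'   probabilities of (source past, target past, target future).
#' @return STE in bits.
#' @export
ste_from_counts <- function(counts) {
  total <- sum(counts)
  if (total <= 0) return(0)
  p <- counts / total
  p_yn_x <- apply(p, c(1, 2), sum)    # marginal over yf -> [x, yn]
  p_yf_yn <- apply(p, c(2, 3), sum)   # marginal over x  -> [yn, yf]
  p_yn <- apply(p, 2, sum)
  acc <- 0
  nz <- which(p > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1]; j <- nz[r, 2]; k <- nz[r, 3]
    acc <- acc + p[i, j, k] *
      log2((p[i, j, k] * p_yn[j]) / (p_yn_x[i, j] * p_yf_yn[j, k]))
  }
  max(acc, 0)  # guard -0 rounding
}

#' Normalized symbolic transfer entropy of one window
#'
#' `NSTE = (STE - mean of STE over n_shuffles random permutations of the
#' source symbols) / H(target future | target past)`. A constant target
#' (zero conditional entropy) yields 0 by convention.
#'
#' @param src,tgt Numeric signal segments (or [speed_series()]), e.g. one
#'   analysis window of two hand speeds.
#' @param m Embedding dimension (default 3).
#' @param tau Embedding delay in samples.
#' @param delta Prediction step in samples (default `tau`).
#' @param n_shuffles Number of source shuffles for the bias term
#'   (default 10).
#' @param seed Optional RNG seed for the shuffles.
#' @return NSTE (unitless, in \[-1, 1\]).
#' @export
nste <- function(src, tgt, m = 3, tau, delta = tau, n_shuffles = 10,
                 seed = NULL) {
  ss <- ordinal_symbolize(src, m = m, tau = tau)
  ts <- ordinal_symbolize(tgt, m = m, tau = tau)
  nste_symbols(ss$symbols, ts$symbols, delta = delta,
               n_shuffles = n_shuffles, seed = seed)
}

# Core NSTE on aligned symbol vectors.
nste_symbols <- function(s, y, delta, n_shuffles = 10, seed = NULL) {
  n <- length(y) - delta
  if (n < 2) stop("window too short for prediction step ", delta,
                  call. = FALSE)
  ns <- max(s, y) + 1L
  yf <- y[(1 + delta):length(y)]
  yn <- y[1:n]
  x <- s[1:n]
  h <- cond_entropy_fast(yn, yf, ns)
  if (h <= 0) return(0)
  raw <- ste_fast(x, yn, yf, ns)
  bias <- with_seed(seed, {
    mean(vapply(seq_len(n_shuffles), function(i) {
      ste_fast(sample(s)[1:n], yn, yf, ns)
    }, numeric(1)))
  })
  (raw - bias) / h
}

#' Directional asymmetry of NSTE
#'
#' `(a - b) / (a + b)` after flooring both directed values at 0; `0/0` is 0.
#' Positive means information flow from A to B dominates (A leads).
#' Antisymmetric under argument swap, bounded in \[-1, 1\].
#'
#' @param nste_ab,nste_ba Directed NSTE values (vectors allowed).
#' @return Asymmetry index in \[-1, 1\].
#' @export
asymmetry <- function(nste_ab, nste_ba) {
  a <- pmax(nste_ab, 0)
  b <- pmax(nste_ba, 0)
  out <- rep(0, length(a))
  nz <- (a + b) > 0
  out[nz] <- (a[nz] - b[nz]) / (a[nz] + b[nz])
  out
}

# Window start times over a session of `span` seconds.
nste_window_starts <- function(span, window, step) {
  if (span < window) stop("series shorter than one window", call. = FALSE)
  seq(0, span - window, by = step)
}

#' Windowed directional NSTE over a session
#'
#' For each analysis window (2 s, stepped by 0.5 s by default), each of the
#' four between-participant hand pairings (the same pairings as the MCV)
#' and each tau in `tau_range` (with `delta = tau`), directed NSTE is
#' computed both ways; the A->B value of the window aggregates the A-hand
#' -> B-hand values over pairings and tau (max by default), likewise B->A,
#' and the asymmetry index is derived per window.
#'
#' @param speeds Named list of the four preprocessed [speed_series()].
#' @param params An [nste_params()] set.
#' @param seed Optional RNG seed for the shuffle bias terms.
#' @return Data frame of class `nste_result`: `center_s`, `nste_ab`,
#'   `nste_ba`, `asymmetry`, `pairing_ab`, `pairing_ba`, `tau_ab`,
#'   `tau_ba`.
#' @export
nste_windowed <- function(speeds, params = nste_params(), seed = NULL) {
  fps <- speeds[[1]]$fps
  n <- length(speeds[[1]]$values)
  span <- (n + 1) / fps  # session span in seconds (n+1 coordinate frames)
  starts <- nste_window_starts(span, params$window, params$step)
  t <- seq_len(n) / fps

  # Symbol series per (hand, tau) once; window slices index into them.
  sym <- lapply(speeds[MARKER_IDS], function(s)
    lapply(params$tau_range, function(tau)
      ordinal_symbolize(s$values, m = params$m, tau = tau)$symbols))

  with_seed(seed, {
    rows <- lapply(starts, function(t0) {
      lo <- which(t >= t0)[1]
      hi <- max(which(t < t0 + params$window))
      best <- list(ab = -Inf, ba = -Inf, p_ab = NA, p_ba = NA,
                   tau_ab = NA, tau_ba = NA)
      vals_ab <- c(); vals_ba <- c()
      for (p in PAIRINGS) {
        for (ti in seq_along(params$tau_range)) {
          tau <- params$tau_range[ti]
          span_smp <- (params$m - 1) * tau
          s_hi <- hi - lo + 1 - span_smp  # symbols fully inside the window
          if (s_hi - tau < 2) next
          sa <- sym[[p[1]]][[ti]][lo:(lo + s_hi - 1)]
          sb <- sym[[p[2]]][[ti]][lo:(lo + s_hi - 1)]
          v_ab <- nste_symbols(sa, sb, delta = tau,
                               n_shuffles = params$n_shuffles)
          v_ba <- nste_symbols(sb, sa, delta = tau,
                               n_shuffles = params$n_shuffles)
          vals_ab <- c(vals_ab, v_ab); vals_ba <- c(vals_ba, v_ba)
          if (v_ab > best$ab) {
            best$ab <- v_ab; best$p_ab <- pairing_label(p); best$tau_ab <- tau
          }
          if (v_ba > best$ba) {
            best$ba <- v_ba; best$p_ba <- pairing_label(p); best$tau_ba <- tau
          }
        }
      }
      if (!is.finite(best$ab)) return(NULL)
      if (params$tau_aggregate == "mean") {
        best$ab <- mean(vals_ab); best$ba <- mean(vals_ba)
      }
      data.frame(center_s = t0 + params$window / 2,
                 nste_ab = best$ab, nste_ba = best$ba,
                 asymmetry = asymmetry(best$ab, best$ba),
                 pairing_ab = best$p_ab, pairing_ba = best$p_ba,
                 tau_ab = best$tau_ab, tau_ba = best$tau_ba)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("nste_result", class(out))
    out
  })
}

#' Non-overlapping bin smoothing of a timestamped series
#'
#' Means over consecutive non-overlapping bins of `window` seconds
#' (anchored at the first timestamp), timestamped at the bin center; used
#' to de-noise NSTE and asymmetry traces for display.
#'
#' @param t Timestamps in seconds (or an `nste_result`, in which case all
#'   its value columns are smoothed).
#' @param v Values aligned with `t` (ignored when `t` is an `nste_result`).
#' @param window Bin width in seconds (default 3).
#' @return Data frame with `t` (bin centers) and `v` (bin means); for an
#'   `nste_result`, columns `center_s`, `nste_ab`, `nste_ba`, `asymmetry`.
#' @export
smooth_nonoverlapping <- function(t, v = NULL, window = 3) {
  if (inherits(t, "nste_result")) {
    res <- t
    ab <- smooth_nonoverlapping(res$center_s, res$nste_ab, window)
    ba <- smooth_nonoverlapping(res$center_s, res$nste_ba, window)
    as <- smooth_nonoverlapping(res$center_s, res$asymmetry, window)
    return(data.frame(center_s = ab$t, nste_ab = ab$v, nste_ba = ba$v,
                      asymmetry = as$v))
  }
  t0 <- min(t)
  bin <- floor((t - t0) / window)
  agg <- tapply(v, bin, mean)
  data.frame(t = t0 + (as.numeric(names(agg)) + 0.5) * window,
             v = as.numeric(agg))
}

#' Write a windowed NSTE result to CSV
#'
#' @param result An `nste_result` from [nste_windowed()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nste_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
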