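# Internal helpers shared across modules.

#' @useDynLib dyadcoord, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The four hand markers of a dyad, in canonical order.
MARKER_IDS <- c("A_left", "A_right", "B_left", "B_right")

# Between-participant hand pairings, in the canonical order
# A_left-B_left, A_left-B_right, A_right-B_left, A_right-B_right.
PAIRINGS <- list(
  c("A_left", "B_left"),
  c("A_left", "B_right"),
  c("A_right", "B_left"),
  c("A_right", "B_right")
)

pairing_label <- function(p) paste(p[1], p[2], sep = "-")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so seeded calls do not perturb callers.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), mode = "integer", inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Centered moving mean in the MATLAB movmean convention: a window of w samples
# covers kb = ceiling((w-1)/2) samples back and kf = floor((w-1)/2) forward
# (even windows weight one extra past sample); endpoints shrink.
moving_mean <- function(x, w) {
  stopifnot(w >= 1)
  n <- length(x)
  kb <- ceiling((w - 1) / 2)
  kf <- (w - 1) - kb
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - kb, 1L)
  hi <- pmin(i + kf, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Centered moving standard deviation (sample SD, N-1), same window convention.
moving_sd <- function(x, w) {
  stopifnot(w >= 1)
  n <- length(x)
  kb <- ceiling((w - 1) / 2)
  kf <- (w - 1) - kb
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  i <- seq_len(n)
  lo <- pmax(i - kb, 1L)
  hi <- pmin(i + kf, n)
  m <- hi - lo + 1
  s <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  v <- (s2 - s^2 / m) / pmax(m - 1, 1)
  v[v < 0] <- 0  # guard tiny negative rounding
  v[m < 2] <- 0
  sqrt(v)
}

# Linear interpolation over a logical mask of samples to replace; leading /
# trailing replaced samples take the nearest retained value.
interp_masked <- function(x, mask) {
  if (!any(mask)) return(x)
  keep <- which(!mask)
  if (length(keep) == 0)
    stop("no retained samples to interpolate from", call. = FALSE)
  if (length(keep) == 1) {
    x[] <- x[keep]
    return(x)
  }
  x[mask] <- stats::approx(keep, x[keep], xout = which(mask),
                           method = "linear", rule = 2)$y
  x
}
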