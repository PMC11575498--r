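test_that("ordinal symbolization maps rank patterns to distinct symbols", {
  # strictly increasing: always the identity pattern
  s <- ordinal_symbolize(1:20, m = 3, tau = 1)
  expect_equal(length(unique(s$symbols)), 1)
  expect_equal(s$symbols[1], 0)

  # the six m=3 patterns are distinct and stable
  pats <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
               c(3, 1, 2), c(2, 3, 1), c(3, 2, 1))
  syms <- vapply(pats, function(p)
    ordinal_symbolize(p, m = 3, tau = 1)$symbols, integer(1))
  expect_equal(sort(syms), 0:5)

  # worked example: (4, 1, 3) is "middle, lowest, highest"
  sym413 <- ordinal_symbolize(c(4, 1, 3), m = 3, tau = 1)$symbols
  expect_equal(sym413,
               ordinal_symbolize(c(20, 0, 10), m = 3, tau = 1)$symbols)
  expect_false(sym413 == ordinal_symbolize(c(1, 2, 3), 3, 1)$symbols)

  # length: n - (m-1)*tau symbols; too-short input errors
  expect_length(ordinal_symbolize(rnorm(100), m = 3, tau = 7)$symbols, 86)
  expect_error(ordinal_symbolize(rnorm(10), m = 3, tau = 5), "too short")

  # ties are broken by earlier position
  expect_equal(ordinal_symbolize(c(1, 1, 1), 3, 1)$symbols,
               ordinal_symbolize(c(1, 2, 3), 3, 1)$symbols)
})

test_that("symbolization is invariant under strictly increasing transforms", {
  set.seed(3)
  x <- rnorm(200)
  a <- ordinal_symbolize(x, 3, 5)$symbols
  expect_equal(ordinal_symbolize(exp(x), 3, 5)$symbols, a)
  expect_equal(ordinal_symbolize(2 * x + 7, 3, 5)$symbols, a)
})

test_that("STE matches analytic tables", {
  # independence: exact product distribution -> 0
  p_x <- c(0.5, 0.3, 0.2)
  p_yn <- c(0.6, 0.4)
  p_yf_given_yn <- matrix(c(0.7, 0.3, 0.2, 0.8), nrow = 2, byrow = TRUE)
  tab <- array(0, dim = c(3, 2, 2))
  for (i in 1:3) for (j in 1:2) for (k in 1:2)
    tab[i, j, k] <- p_x[i] * p_yn[j] * p_yf_given_yn[j, k]
  expect_equal(ste_from_counts(tab), 0)

  # deterministic copy: yf = x uniform over 6 patterns, yn independent
  tab <- array(0, dim = c(6, 6, 6))
  for (i in 1:6) for (j in 1:6) tab[i, j, i] <- 1 / 36
  expect_equal(ste_from_counts(tab), log2(6))
})

test_that("STE equals the triple-loop oracle on random symbol sequences", {
  set.seed(19)
  for (i in 1:10) {
    src <- sample(0:5, 300, TRUE)
    tgt <- sample(0:5, 300, TRUE)
    delta <- sample(1:10, 1)
    expect_equal(ste(src, tgt, delta), naive_ste(src, tgt, delta),
                 tolerance = 1e-12)
    expect_gte(ste(src, tgt, delta), 0)
  }
})

test_that("STE of a constant target is zero", {
  src <- sample(0:5, 100, TRUE)
  expect_equal(ste(src, rep(2L, 100), delta = 3), 0)
})

test_that("NSTE conventions and bounds hold", {
  # constant target segment: zero conditional entropy -> 0
  expect_equal(nste(rnorm(120), rep(1, 120), tau = 6, seed = 1), 0)

  # independent white-noise segments: mean near 0 over seeds
  set.seed(50)
  vals <- replicate(20, nste(rnorm(120), rnorm(120), tau = 8, seed = NULL))
  expect_lt(abs(mean(vals)), 0.05)
  expect_true(all(vals >= -1 & vals <= 1))
})

test_that("NSTE recovers the direction of a delayed copy", {
  set.seed(60)
  wins <- 0
  for (i in 1:100) {
    src <- as.numeric(stats::filter(rnorm(140), 0.7, method = "recursive"))
    tgt <- c(rep(0, 8), src[1:132]) + rnorm(140, 0, 0.05)
    ab <- nste(src, tgt, tau = 8, seed = NULL)
    ba <- nste(tgt, src, tau = 8, seed = NULL)
    wins <- wins + (ab > ba)
  }
  expect_gte(wins, 90)
})

test_that("asymmetry index follows its closed form", {
  expect_equal(asymmetry(0.2, 0.2), 0)
  expect_equal(asymmetry(0.3, 0.1), 0.5)
  expect_equal(asymmetry(0.1, 0.3), -0.5)
  expect_equal(asymmetry(0, 0), 0)
  # negative inputs are floored at zero before combining
  expect_equal(asymmetry(0.3, -0.2), 1)
  # antisymmetry and bounds on random values
  set.seed(5)
  a <- runif(50, -0.5, 1); b <- runif(50, -0.5, 1)
  expect_equal(asymmetry(a, b), -asymmetry(b, a))
  expect_true(all(abs(asymmetry(a, b)) <= 1))
})

test_that("windowed NSTE lays windows on the session time axis", {
  # 15-min session at 60 Hz: floor((900 - 2) / 0.5) + 1 = 1797 windows
  starts <- dyadcoord:::nste_window_starts(900, 2, 0.5)
  expect_length(starts, 1797)
  expect_equal(starts[1], 0)
  expect_equal(starts[1797], 898)

  # short series errors
  sp <- make_noise_speeds(60)
  expect_error(nste_windowed(sp, nste_params(window = 2)), "shorter")

  # actual run: 20 s session -> floor(18 / 0.5) + 1 = 37 windows
  sp <- make_noise_speeds(20 * 60 - 1, seed = 3)
  res <- nste_windowed(sp, nste_params(), seed = 2)
  expect_equal(nrow(res), 37)
  expect_equal(res$center_s[1], 1)
  expect_true(all(res$nste_ab >= -1 & res$nste_ab <= 1))
  expect_equal(res$asymmetry, asymmetry(res$nste_ab, res$nste_ba))
})

test_that("windowed NSTE is symmetric for a mirrored dyad", {
  sp <- make_noise_speeds(900, seed = 9)
  sp$B_left$values <- sp$A_left$values
  sp$B_right$values <- sp$A_right$values
  res <- nste_windowed(sp, nste_params(), seed = 4)
  # same signals either way: directed values agree up to shuffle noise
  expect_lt(mean(abs(res$nste_ab - res$nste_ba)), 0.1)
})

test_that("non-overlapping smoothing averages 3 s bins", {
  out <- smooth_nonoverlapping(c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5), 1:6)
  expect_equal(out$v, c(2, 5))
  expect_equal(out$t, c(2, 5))

  # constant stays constant; bin count is floor(span / 3)
  out <- smooth_nonoverlapping(seq(0.5, 29.5, by = 1), rep(7, 30), window = 3)
  expect_true(all(out$v == 7))
  expect_equal(nrow(out), 10)
})
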