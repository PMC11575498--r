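test_that("rolling Spearman handles monotone, inverted and worked examples", {
  set.seed(2)
  x <- make_speed(cumsum(runif(100, 0.1, 1)), fps = 1)
  y_same <- x
  r <- rolling_spearman(x, y_same, window = 7)
  expect_true(all(r$values[!is.na(r$values)] == 1))

  y_neg <- make_speed(-x$values, fps = 1, marker = "B_left")
  r <- rolling_spearman(x, y_neg, window = 7)
  expect_true(all(r$values[!is.na(r$values)] == -1))

  # single 5-sample window: rho = 1 - 6*sum(d^2)/(n(n^2-1)) = 0.8
  x5 <- make_speed(c(1, 2, 3, 4, 5), fps = 1)
  y5 <- make_speed(c(1, 3, 2, 5, 4), fps = 1, marker = "B_left")
  r <- rolling_spearman(x5, y5, window = 5)
  expect_equal(r$values[3], 0.8)
  expect_true(all(is.na(r$values[-3])))

  # length mismatch is an input error
  expect_error(rolling_spearman(x, make_speed(1:5, fps = 1)), "lengths")
})

test_that("rolling Spearman equals naive per-window recomputation", {
  set.seed(31)
  n <- 1000
  x <- make_speed(rnorm(n), fps = 60)
  y <- make_speed(rnorm(n), fps = 60, marker = "B_left")
  for (wsec in c(0.1, 0.25)) {  # 6- and 15-sample windows
    w <- round(wsec * 60)
    got <- rolling_spearman(x, y, window = wsec)$values
    want <- naive_rolling_spearman(x$values, y$values, w)
    expect_lt(max(abs(got - want), na.rm = TRUE), 1e-10)
    expect_identical(is.na(got), is.na(want))
  }
  # with heavy ties (average-rank handling)
  xt <- make_speed(sample(1:3, 200, TRUE), fps = 60)
  yt <- make_speed(sample(1:3, 200, TRUE), fps = 60, marker = "B_left")
  got <- rolling_spearman(xt, yt, window = 0.25)$values
  want <- naive_rolling_spearman(xt$values, yt$values, 15)
  expect_lt(max(abs(got - want), na.rm = TRUE), 1e-10)
})

test_that("rolling Spearman is invariant under monotone transforms", {
  set.seed(8)
  x <- make_speed(abs(rnorm(150)) + 0.1, fps = 60)
  y <- make_speed(abs(rnorm(150)) + 0.1, fps = 60, marker = "B_left")
  base <- rolling_spearman(x, y, window = 0.2)$values
  fx <- make_speed(exp(x$values), fps = 60)
  gy <- make_speed(y$values^3, fps = 60, marker = "B_left")
  expect_equal(rolling_spearman(fx, gy, window = 0.2)$values, base,
               tolerance = 1e-12)
})

test_that("zero-variance windows are undefined", {
  x <- make_speed(rep(1, 50), fps = 1)
  y <- make_speed(rnorm(50), fps = 1, marker = "B_left")
  r <- rolling_spearman(x, y, window = 5)
  expect_true(all(is.na(r$values)))
})

test_that("the MCV is the pointwise maximum over the four pairings", {
  sp <- make_noise_speeds(400, seed = 6)
  mcv <- compute_mcv(sp, window = 1)
  cvs <- attr(mcv, "cvs")
  m <- do.call(cbind, lapply(cvs, `[[`, "values"))
  for (t in which(!is.na(mcv$values))) {
    expect_equal(mcv$values[t], max(m[t, ], na.rm = TRUE))
    expect_true(all(mcv$values[t] >= m[t, !is.na(m[t, ])]))
  }
  expect_true(all(abs(mcv$values) <= 1, na.rm = TRUE))

  # identical series in all hands: MCV is 1 wherever defined
  one <- make_noise_speeds(200, seed = 7)
  for (id in names(one)) one[[id]]$values <- one$A_left$values
  m1 <- compute_mcv(one, window = 1)
  expect_true(all(m1$values[!is.na(m1$values)] == 1))
})

test_that("max_correlation_vector records the winning pairing", {
  cv <- function(vals, a, b) structure(
    list(values = vals, pairing = c(a, b), window = 5, fps = 60),
    class = "corr_vector")
  cvs <- list(cv(c(0.1, 0.3), "A_left", "B_left"),
              cv(c(-0.5, 0.3), "A_left", "B_right"),
              cv(c(0.9, 0.3), "A_right", "B_left"),
              cv(c(0.2, 0.3), "A_right", "B_right"))
  m <- max_correlation_vector(cvs)
  expect_equal(m$values, c(0.9, 0.3))
  expect_equal(m$source[1], "A_right-B_left")

  # wrong pairing set is an input error
  bad <- cvs
  bad[[4]] <- cv(c(0, 0), "A_left", "B_left")
  expect_error(max_correlation_vector(bad), "pairing")
})

test_that("data sliding rotates, preserves multisets and composes back", {
  x <- c(1, 2, 3, 4)
  expect_equal(slide_series(x, 2), c(3, 4, 1, 2))
  expect_equal(slide_series(x, 0), x)
  expect_equal(slide_series(x, 4), x)
  expect_error(slide_series(x, 5), "range")

  set.seed(12)
  for (i in 1:10) {
    v <- rnorm(50)
    cut <- sample(0:50, 1)
    s <- slide_series(v, cut)
    expect_equal(sort(s), sort(v))
    expect_equal(slide_series(s, 50 - cut), v)
  }

  s <- slide_series(make_speed(x, fps = 1), 2)
  expect_s3_class(s, "speed_series")
  expect_equal(s$values, c(3, 4, 1, 2))
})

test_that("the sliding kernel agrees with slide + rolling Spearman + max", {
  sp <- make_noise_speeds(240, seed = 40)
  w <- 30L
  for (cut in c(0L, 57L, 120L, 239L)) {
    pool <- dyadcoord:::cpp_slide_mcv_pool(
      sp$A_left$values, sp$A_right$values,
      sp$B_left$values, sp$B_right$values, w, cut)
    slid <- list(
      A_left = slide_series(sp$A_left, cut),
      A_right = slide_series(sp$A_right, cut),
      B_left = sp$B_left, B_right = sp$B_right)
    mcv <- compute_mcv(slid, window = w / 60)
    expect_equal(pool, mcv$values[!is.na(mcv$values)], tolerance = 1e-12)
  }
})

test_that("significance threshold is the percentile of the shuffled pool", {
  sp <- make_noise_speeds(1500, seed = 22)
  mom <- list(start = 2, end = 22)
  th <- significance_threshold(sp, mom, n_slides = 100, window = 2,
                               seed = 5, keep_pool = TRUE)
  expect_equal(th$threshold,
               unname(quantile(th$pool, 0.95, type = 7)))
  expect_true(th$threshold >= -1 && th$threshold <= 1)

  # two different seeds give stable thresholds on white noise
  th1 <- significance_threshold(sp, mom, n_slides = 300, window = 2, seed = 1)
  th2 <- significance_threshold(sp, mom, n_slides = 300, window = 2, seed = 2)
  expect_lt(abs(th1$threshold - th2$threshold), 0.05)

  # same seed reproduces exactly
  th1b <- significance_threshold(sp, mom, n_slides = 300, window = 2, seed = 1)
  expect_identical(th1$threshold, th1b$threshold)
})

test_that("constant-speed moments have no defined threshold", {
  sp <- lapply(dyadcoord:::MARKER_IDS, function(id)
    make_speed(rep(2, 1200), marker = id))
  names(sp) <- dyadcoord:::MARKER_IDS
  expect_error(
    significance_threshold(sp, list(start = 0, end = 20), n_slides = 10,
                           window = 2, seed = 1),
    "undefined threshold")
})
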