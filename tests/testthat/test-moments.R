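test_that("moments shorter than 10 s or outside the session are rejected", {
  expect_error(moment(0, 9.9), "10 s")
  expect_error(moment(890, 905), "session")
  m <- moment(10, 25, "high")
  expect_equal(m$end - m$start, 15)

  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(session = "s", start_s = c(0, 20), end_s = c(15, 28),
                       label = c("high", "low")), path, row.names = FALSE)
  expect_error(read_moments_csv(path), "10 s")
  write.csv(data.frame(session = "s", start_s = c(0, 20), end_s = c(15, 40),
                       label = c("high", "low")), path, row.names = FALSE)
  expect_equal(read_moments_csv(path)$label, c("high", "low"))
})

test_that("evidence integrates area about the threshold", {
  # MCV constantly 1 over a 10 s moment: e_high = 0.5 * 10
  mcv <- make_mcv(rep(1, 1200))
  ev <- evidence(mcv, list(start = 0, end = 10))
  expect_equal(ev$e_high, 5)
  expect_equal(ev$e_low, 0)
  expect_equal(ev$predicted, "high")

  # constantly 0: all evidence low
  ev <- evidence(make_mcv(rep(0, 1200)), list(start = 0, end = 10))
  expect_equal(ev$e_low, 5)
  expect_equal(ev$e_high, 0)
  expect_equal(ev$predicted, "low")

  # alternating 0.6 / 0.3 in equal measure: e_high 0.5, e_low 1.0 -> low
  ev <- evidence(make_mcv(rep(c(0.6, 0.3), 600)), list(start = 0, end = 10))
  expect_equal(ev$e_high, 0.5)
  expect_equal(ev$e_low, 1.0)
  expect_equal(ev$predicted, "low")

  # tie goes to high
  ev <- evidence(make_mcv(rep(c(0.6, 0.4), 600)), list(start = 0, end = 10))
  expect_equal(ev$e_high, ev$e_low)
  expect_equal(ev$predicted, "high")

  # undefined samples are skipped; all-undefined is unclassifiable
  v <- rep(NA_real_, 1200)
  expect_error(evidence(make_mcv(v), list(start = 0, end = 10)),
               "unclassifiable")
})

test_that("evidence is threshold-consistent and timescale-invariant", {
  set.seed(44)
  vals <- runif(1200, -0.2, 1)
  mcv <- make_mcv(vals)
  mom <- list(start = 2, end = 18)
  e1 <- evidence(mcv, mom, y = 0.4)
  e2 <- evidence(mcv, mom, y = 0.6)
  expect_lte(e2$e_high, e1$e_high)
  expect_gte(e2$e_low, e1$e_low)

  # halving fps doubles dt but scales both evidences equally
  mcv2 <- make_mcv(vals, fps = 30)
  mom2 <- list(start = 4, end = 36)
  ea <- evidence(mcv, mom)
  eb <- evidence(mcv2, mom2)
  expect_equal(eb$e_high / ea$e_high, 2)
  expect_equal(eb$e_low / ea$e_low, 2)
  expect_equal(ea$predicted, eb$predicted)
})

test_that("confusion-matrix metrics follow their definitions", {
  df <- data.frame(
    label = c(rep("high", 4), rep("low", 6)),
    predicted = c("high", "high", "high", "low",
                   "high", rep("low", 5)))
  ev <- evaluate_classification(df)
  expect_equal(unname(ev$confusion), c(3, 1, 1, 5))
  expect_equal(ev$accuracy, 0.8)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$sensitivity, 0.75)

  perfect <- data.frame(label = c("high", "low"), predicted = c("high", "low"))
  ev <- evaluate_classification(perfect)
  expect_equal(c(ev$accuracy, ev$precision, ev$sensitivity), c(1, 1, 1))

  # no positives at all: precision/sensitivity undefined
  neg <- data.frame(label = c("low", "low"), predicted = c("low", "low"))
  ev <- evaluate_classification(neg)
  expect_equal(ev$accuracy, 1)
  expect_true(is.na(ev$precision))
  expect_true(is.na(ev$sensitivity))
})

test_that("sample-level evaluation scores each defined MCV sample", {
  vals <- c(rep(0.9, 600), rep(0.1, 600))
  mcv <- make_mcv(vals)
  cl <- rbind(
    cbind(moment(0, 10, "high"), predicted = "high"),
    cbind(moment(10, 20, "high"), predicted = "high"))
  ev <- evaluate_classification(cl, granularity = "sample", mcv = mcv)
  # first moment's 600 samples right, second's 600 wrong
  expect_equal(unname(ev$confusion["tp"]), 600)
  expect_equal(unname(ev$confusion["fn"]), 600)
  expect_equal(ev$accuracy, 0.5)
})

test_that("block schedule maps moment midpoints to eye conditions", {
  expect_equal(condition_of(list(start = 190, end = 210)),
               list(block = 2, eyes_A = "open", eyes_B = "open"))
  expect_equal(condition_of(list(start = 80, end = 100))$block, 1)
  expect_equal(condition_of(list(start = 80, end = 100))$eyes_A, "closed")
  # midpoint exactly on a boundary belongs to the later block
  expect_equal(condition_of(list(start = 170, end = 190))$block, 2)
  # blocks 3 and 4 split the dyad's vision
  expect_equal(condition_of(list(start = 400, end = 420)),
               list(block = 3, eyes_A = "open", eyes_B = "closed"))
  expect_equal(condition_of(list(start = 580, end = 600)),
               list(block = 4, eyes_A = "closed", eyes_B = "open"))
})

test_that("co-occurrence uses the 90 s per-side expansion", {
  m <- moment(100, 120, "high")
  seg <- function(a, b) data.frame(participant = "A", start_s = a, end_s = b,
                                   rating = 5)
  expect_equal(nrow(cooccurring(m, seg(100, 120))), 1)   # identical
  expect_equal(nrow(cooccurring(m, seg(209, 250))), 1)   # gap 89 s
  expect_equal(nrow(cooccurring(m, seg(211, 250))), 0)   # gap 91 s
  expect_equal(nrow(cooccurring(m, seg(1, 11))), 1)      # gap 89 s before
  expect_equal(nrow(cooccurring(m, seg(1, 9))), 0)       # gap 91 s before
})

test_that("co-occurrence agrees with the brute-force interval check", {
  set.seed(33)
  starts <- runif(15, 0, 800)
  moms <- do.call(rbind, lapply(starts, function(s)
    moment(s, s + runif(1, 10, 60), "high", session_duration = 1000)))
  segs <- data.frame(participant = "A",
                     start_s = runif(20, 0, 900))
  segs$end_s <- segs$start_s + runif(20, 5, 120)
  segs$rating <- 5
  got <- cooccurring(moms, segs, tolerance = 90)
  brute <- NULL
  for (i in seq_len(nrow(moms))) for (j in seq_len(nrow(segs))) {
    a1 <- moms$start[i] - 90; a2 <- moms$end[i] + 90
    if (max(a1, segs$start_s[j]) <= min(a2, segs$end_s[j]))
      brute <- rbind(brute, data.frame(moment_idx = i, segment_idx = j))
  }
  expect_equal(nrow(got), nrow(brute))
  expect_equal(sort(got$moment_idx + 1000 * got$segment_idx),
               sort(brute$moment_idx + 1000 * brute$segment_idx))
})

test_that("segments CSV validation enforces the rating scale", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(participant = "A", start_s = 0, end_s = 30,
                       rating = 11, role = 1, connection = 0,
                       flag3 = 0, flag4 = 0, comment = "x"),
            path, row.names = FALSE)
  expect_error(read_segments_csv(path), "1..10")
  write.csv(data.frame(participant = c("A", "B"), start_s = c(0, 40),
                       end_s = c(30, 90), rating = c(7, 3),
                       role = c(1, 0), connection = c(1, 1),
                       flag3 = 0, flag4 = 0, comment = ""),
            path, row.names = FALSE)
  expect_equal(nrow(read_segments_csv(path)), 2)
})
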