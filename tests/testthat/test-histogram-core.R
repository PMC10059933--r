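test_that("moving-average smoothing behaves on uniform and delta PMFs", {
  u <- rep(1 / 180, 180)
  expect_equal(smoothenPmf(u, 5), u)

  d <- numeric(100); d[51] <- 1  # delta at interior bin 50 (0-based)
  s <- smoothenPmf(d, 5)
  expect_equal(s[49:53], rep(0.2, 5))
  expect_equal(sum(s > 0), 5)

  expect_error(smoothenPmf(u, 4), "odd")
})

test_that("smoothing stays within windowed min/max and never raises the max", {
  set.seed(52)
  for (rep in 1:25) {
    p <- randomPmf(180)
    s <- smoothenPmf(p, 5)
    expect_true(all(s >= 0))
    expect_lte(max(s), max(p))
    for (i in seq_along(p)) {
      w <- p[max(1, i - 2):min(length(p), i + 2)]
      expect_gte(s[i], min(w) - 1e-12)
      expect_lte(s[i], max(w) + 1e-12)
    }
  }
})

test_that("windowed area and gradient match direct summation", {
  u <- rep(1 / 180, 180)
  for (h in c(0, 1, 90, 178, 179))
    expect_equal(avgArea(u, h, 5), 1 / 180)
  expect_equal(avgGradient(u, 90, 5), 0)
  expect_equal(avgArea(numeric(50), 25, 5), 0)

  # step PMF: one jump of height c inside the window contributes atan(c) once
  c0 <- 0.02
  p <- c(rep(0, 50), rep(c0, 50))
  p <- p / sum(p)
  cstep <- p[51]
  expect_equal(avgGradient(p, 48, 5), atan(cstep) / 5)
  expect_equal(avgArea(p, 51, 5), sum(p[50:54]) / 5)

  set.seed(53)
  for (rep in 1:20) {
    p <- randomPmf(180)
    h <- sample(0:179, 1)
    lo <- max(0, h - 2); hi <- min(179, h + 2)
    expect_equal(avgArea(p, h, 5), mean(p[(lo:hi) + 1]))
  }
})

test_that("nomination covers a uniform PMF and skips flat zero regions", {
  # uniform PMF: every window's area equals the cutoff exactly and the
  # comparison is inclusive, so every bin is nominated
  u <- rep(1 / 180, 180)
  expect_identical(nominatedRange(smoothenPmf(u), cutoffArea = 1 / 180), 0:179)

  # single localized bump at bin 90: smoothing spreads it to 88..92 and the
  # gradient windows reach two bins beyond each smoothed edge, so the
  # nominated set is exactly 83..96; the flat zero regions contribute nothing
  p <- numeric(180); p[91] <- 1
  nom <- nominatedRange(smoothenPmf(p))
  expect_identical(nom, 83:96)

  # a single engineered jump nominates only windows that see it
  q <- rep(1e-5, 180); q[101:180] <- 2e-3; q <- q / sum(q)
  sm <- smoothenPmf(q)
  nom2 <- nominatedRange(sm, cutoffGradient = 0.001, cutoffArea = 1)
  expect_true(length(nom2) > 0)
  expect_true(all(nom2 >= 95 & nom2 <= 105))
})

test_that("nomination agrees with a literal transcription on random PMFs", {
  set.seed(54)
  for (rep in 1:40) {
    p <- smoothenPmf(randomPmf(180))
    expect_identical(nominatedRange(p), as.integer(oracleNominatedRange(p)))
  }
  # saturation-length histograms exercise the upper-boundary branch
  for (rep in 1:10) {
    p <- smoothenPmf(randomPmf(256))
    expect_identical(nominatedRange(p), as.integer(oracleNominatedRange(p)))
  }
})

test_that("max continuous range selects the largest gap-bounded run", {
  expect_identical(maxContinuousRange(c(18:35, 72:93, 116:130), 4), 72:93)
  expect_identical(maxContinuousRange(c(30:55, 75:90, 137:255), 4), 137:255)
  expect_identical(maxContinuousRange(42, 3), 42L)
  expect_identical(maxContinuousRange(integer(0), 2), integer(0))
  # tie toward the run with the smallest low bin
  expect_identical(maxContinuousRange(c(1:5, 50:54), 2), 1:5)
  # the gap comparison is inclusive
  expect_identical(maxContinuousRange(c(0, 4, 8), 4), c(0L, 4L, 8L))
  expect_identical(maxContinuousRange(c(0, 5, 8), 4), c(5L, 8L))
})

test_that("run selection matches exhaustive enumeration on random sets", {
  set.seed(55)
  for (rep in 1:60) {
    bins <- sort(sample(0:299, sample(1:60, 1)))
    limit <- sample(1:6, 1)
    run <- maxContinuousRange(bins, limit)
    expect_identical(run, oracleMaxRun(bins, limit))
    expect_true(all(run %in% bins))
    if (length(run) > 1)
      expect_true(all(diff(run) <= limit))
  }
})

test_that("peak-inclusive selection returns the run containing the peak", {
  expect_identical(
    maxContinuousRangeWithPeak(c(18:35, 72:93, 116:130), 83, 2), 72:93)
  expect_identical(maxContinuousRangeWithPeak(10:20, 15, 1), 10:20)
  # largest run lacks the peak: it is discarded and the peak's run returned
  expect_identical(maxContinuousRangeWithPeak(c(0:50, 100:110), 105, 2),
                   100:110)
  expect_error(maxContinuousRangeWithPeak(c(1:5), 40, 2), "not in the nominated")

  set.seed(56)
  for (rep in 1:40) {
    bins <- sort(unique(sample(0:179, sample(5:80, 1))))
    peak <- sample(bins, 1)
    run <- maxContinuousRangeWithPeak(bins, peak, sample(1:4, 1))
    expect_true(peak %in% run)
    expect_true(all(run %in% bins))
  }
})

test_that("saturation shortlisting keeps exactly the hue-matched pixels", {
  H <- matrix(80L, 4, 5)
  S <- matrix(7L * seq_len(20), 4, 5)
  expect_identical(sort(findSatValues(72, 93, H, S)), sort(as.integer(S)))
  expect_identical(findSatValues(72, 93, matrix(10L, 4, 5), S), integer(0))

  set.seed(57)
  H2 <- matrix(sample(0:179, 200, TRUE), 10, 20)
  S2 <- matrix(sample(0:255, 200, TRUE), 10, 20)
  got <- findSatValues(40, 90, H2, S2)
  expect_equal(length(got), sum(H2 >= 40 & H2 <= 90))
  expect_identical(sort(got), sort(as.integer(S2[H2 >= 40 & H2 <= 90])))
  expect_error(findSatValues(0, 10, H2, matrix(0L, 2, 2)), "identical")
})
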