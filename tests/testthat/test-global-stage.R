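constHsv <- function(hue, sat, val = 200L, m = 40, n = 40)
  hsvImage(matrix(hue, m, n), matrix(sat, m, n), matrix(val, m, n))

test_that("a constant-hue image yields a tight peak-containing hue range", {
  hsv <- constHsv(83L, 200L)
  hr <- globalHueRange(hsv, thresholdParams("pca"))
  # smoothing turns the delta into a 5-bin plateau; argmax ties break toward
  # the smallest bin, so the reported peak is the plateau's left edge
  expect_equal(hr$peak, 81L)
  expect_lte(rangeLow(hr$range), 83L)
  expect_gte(rangeHigh(hr$range), 83L)
  # a delta PMF nominates at most the windows that see the spike
  expect_lte(rangeHigh(hr$range) - rangeLow(hr$range), 14L)
})

test_that("minor hue populations are excluded from the global hue range", {
  # background band around 83 plus small populations near 25 and 123,
  # mirroring the nominated-run geography of a board image
  set.seed(61)
  m <- 80; n <- 80
  H <- matrix(sample(78:88, m * n, TRUE), m, n)
  H[1:12, 1:12] <- 25L
  H[60:71, 60:71] <- 123L
  hsv <- hsvImage(H, matrix(200L, m, n), matrix(128L, m, n))
  hr <- globalHueRange(hsv, thresholdParams("pca"))
  expect_true(rangeLow(hr$range) <= 83 && rangeHigh(hr$range) >= 83)
  expect_gt(rangeLow(hr$range), 31)   # beyond the hue-25 population + window
  expect_lt(rangeHigh(hr$range), 117) # below the hue-123 population - window
})

test_that("global saturation range covers the shortlisted mode and drops outliers", {
  hsv <- constHsv(80L, 200L)
  sr <- globalSatRange(hsv, binRange(72, 93), thresholdParams("pca"))
  expect_lte(rangeLow(sr), 200L)
  expect_gte(rangeHigh(sr), 200L)
  expect_lte(rangeHigh(sr) - rangeLow(sr), 14L)

  # dense band 137..255 plus sparse outliers at 40, separated by a gap > limit2
  set.seed(62)
  m <- 64; n <- 64
  S <- matrix(sample(137:255, m * n, TRUE), m, n)
  S[1, 1:8] <- 40L
  hsv2 <- hsvImage(matrix(80L, m, n), S, matrix(128L, m, n))
  sr2 <- globalSatRange(hsv2, binRange(72, 93), thresholdParams("pca"))
  # nomination windows can reach at most 7 bins below the band edge
  # (2 bins of smoothing spread + a window anchored 2 bins further out)
  expect_gte(rangeLow(sr2), 130L)
  expect_equal(rangeHigh(sr2), 255L)
  expect_gt(rangeLow(sr2), 50L)  # outliers excluded

  # no pixel inside the hue range -> empty shortlist error
  expect_error(globalSatRange(constHsv(10L, 100L), binRange(72, 93),
                              thresholdParams("pca")), "empty shortlist")
})

test_that("thresholding classifies each pixel by the joint inclusive ranges", {
  hr <- binRange(72, 93); sr <- binRange(137, 255)
  one <- function(h, s) applyThreshold(constHsv(h, s, m = 1, n = 1), hr, sr)[1, 1]
  expect_equal(one(80L, 200L), 0L)     # both in range
  expect_equal(one(80L, 50L), 255L)    # saturation outside
  expect_equal(one(10L, 200L), 255L)   # hue outside
  expect_equal(one(72L, 137L), 0L)     # inclusive boundaries
  expect_equal(one(93L, 255L), 0L)

  set.seed(63)
  for (rep in 1:30) {
    H <- matrix(sample(0:179, 150, TRUE), 10, 15)
    S <- matrix(sample(0:255, 150, TRUE), 10, 15)
    hLow <- sample(0:100, 1); hHigh <- hLow + sample(0:60, 1)
    sLow <- sample(0:150, 1); sHigh <- sLow + sample(0:100, 1)
    got <- applyThreshold(hsvImage(H, S, matrix(0L, 10, 15)),
                          binRange(hLow, hHigh), binRange(sLow, sHigh))
    expect_identical(got, oracleThreshold(H, S, hLow, hHigh, sLow, sHigh))
  }
})

test_that("widening a range only converts foreground to background", {
  set.seed(64)
  H <- matrix(sample(0:179, 400, TRUE), 20, 20)
  S <- matrix(sample(0:255, 400, TRUE), 20, 20)
  hsv <- hsvImage(H, S, matrix(100L, 20, 20))
  m1 <- applyThreshold(hsv, binRange(60, 100), binRange(100, 200))
  m2 <- applyThreshold(hsv, binRange(50, 110), binRange(80, 220))
  expect_true(all(m2 <= m1))  # 0 = background can only grow
})

test_that("global thresholding composes the steps and respects its contracts", {
  fx <- makeFixture(boardFixtureSpec(seed = 65))
  p <- thresholdParams("pca")
  gr <- globalThreshold(fx$hsv, p)

  expect_s4_class(gr, "GlobalResult")
  expect_identical(dim(globalMask(gr)), dim(fx$gt))
  expect_true(all(globalMask(gr) %in% c(0L, 255L)))
  expect_true(peakHue(gr) >= rangeLow(hueRange(gr)) &&
              peakHue(gr) <= rangeHigh(hueRange(gr)))
  expect_gte(diceIndex(fx$gt, globalMask(gr)), 0.95)

  # every pixel inside the derived ranges -> all-background mask
  flat <- constHsv(83L, 200L)
  grFlat <- globalThreshold(flat, p)
  expect_true(all(globalMask(grFlat) == 0L))

  # the RGB array route agrees with converting first
  grArr <- globalThreshold(fx$image, p)
  expect_identical(globalMask(grArr), globalMask(globalThreshold(
    rgbToHsv(fx$image), p)))
})

test_that("masks are invariant to uniform rescaling of the value plane", {
  fx <- makeFixture(boardFixtureSpec(seed = 66))
  p <- thresholdParams("pca")
  H <- hueChannel(fx$hsv); S <- satChannel(fx$hsv); V <- valChannel(fx$hsv)
  dimmed <- hsvImage(H, S, V %/% 2L)
  g1 <- globalThreshold(fx$hsv, p)
  g2 <- globalThreshold(dimmed, p)
  expect_identical(globalMask(g1), globalMask(g2))
  expect_identical(hueRange(g1), hueRange(g2))
  expect_identical(satRange(g1), satRange(g2))
})
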