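# Sliding-window domain localization and CWT hotspot mapping.

test_that("window profile is zero on a constant series and localizes a burst", {
  wp0 <- slidingWindowProfile(rawSeq(rep(1, 100)), 0.2, windowLength = 32L)
  expect_equal(wp0@responses, rep(0, length(wp0@responses)))
  fx <- makePlantedSequence(length = 300, f0 = 0.2, amplitude = 1,
                            noiseSd = 0.1, seed = 21, region = c(100, 200))
  wp <- slidingWindowProfile(fx$sequence, 0.2, windowLength = 64L)
  peakCenter <- wp@positions[which.max(wp@responses)]
  expect_gte(peakCenter, 100)
  expect_lte(peakCenter, 200)
})

test_that("a single window reproduces the whole-window amplitude", {
  set.seed(4)
  x <- rnorm(80)
  wp <- slidingWindowProfile(rawSeq(x), 0.25, windowLength = 80L,
                             step = 1L, gridLength = 128L)
  expect_length(wp@responses, 1)
  s <- dftSpectrum(rawSeq(x), 128L)
  bin <- matchFrequency(0.25, 128L)$bin
  expect_equal(wp@responses, amplitudes(s)[bin], tolerance = 1e-9)
  expect_error(slidingWindowProfile(rawSeq(rnorm(10)), 0.2, windowLength = 20L),
               "exceeds")
})

test_that("profile of a reversed sequence is the reversed profile", {
  fx <- makePlantedSequence(length = 200, f0 = 0.15, amplitude = 1,
                            noiseSd = 0.2, seed = 9, region = c(40, 90))
  x <- eiipValues(fx$sequence)
  wp <- slidingWindowProfile(rawSeq(x), 0.15, windowLength = 32L)
  wr <- slidingWindowProfile(rawSeq(rev(x)), 0.15, windowLength = 32L)
  expect_equal(wr@responses, rev(wp@responses), tolerance = 1e-9)
})

test_that("domain calls follow the supra-threshold run rule", {
  mk <- function(r) new("WindowProfile", proteinId = "p", frequency = 0.2,
                        windowLength = 10L, step = 1L,
                        positions = seq_along(r) + 4.5, responses = r,
                        seqLength = length(r) + 9L)
  # single above-threshold window starting at s spans (s, s + w - 1)
  r <- c(rep(0.1, 5), 1, rep(0.1, 5))
  d <- callDomain(mk(r), 0.7)
  expect_equal(c(d$start, d$end), c(6L, 15L))
  # two equal disjoint runs: the earlier wins
  r2 <- c(1, 1, 0, 0, 1, 1, 0)
  d2 <- callDomain(mk(r2), 0.7)
  expect_equal(d2$start, 1L)
  expect_error(callDomain(mk(rep(0, 6)), 0.7), "all-zero")
})

test_that("domain calls are invariant to positive scaling of the series", {
  fx <- makePlantedSequence(length = 300, f0 = 0.2, amplitude = 1,
                            noiseSd = 0.2, seed = 31, region = c(100, 200))
  x <- eiipValues(fx$sequence)
  d1 <- callDomain(slidingWindowProfile(rawSeq(x), 0.2, windowLength = 64L))
  d2 <- callDomain(slidingWindowProfile(rawSeq(37 * x), 0.2, windowLength = 64L))
  expect_equal(d1[c("start", "end")], d2[c("start", "end")])
})

test_that("FFT-based Morlet transform matches direct convolution away from edges", {
  set.seed(12)
  x <- rnorm(256)
  f0 <- 0.1
  wm <- cwtMap(rawSeq(x), f0, nScales = 5L, scaleSpan = 1)
  i <- wm@targetScaleIndex
  s <- wm@scales[i]
  direct <- naiveMorletRow(x - mean(x), s)
  interior <- ceiling(8 * s):floor(256 - 8 * s)
  expect_equal(wm@coefficients[i, interior], direct[interior],
               tolerance = 1e-6)
})

test_that("a full-length cosine lights up band 5 at its matched scale", {
  x <- cos(2 * pi * 0.125 * (0:255))
  wm <- cwtMap(rawSeq(x), 0.125)
  i <- wm@targetScaleIndex
  targetRow <- wm@bands[i, !wm@coi[i, ]]
  expect_gt(mean(targetRow == 5), 0.9)
  # a far-off scale carries little energy
  off <- if (i > 3) 1L else length(wm@scales)
  expect_gt(mean(wm@coefficients[i, ]), 5 * mean(wm@coefficients[off, ]))
})

test_that("quantile bands put ~20% of non-edge cells in each band on white noise", {
  set.seed(5)
  props <- replicate(20, {
    wm <- cwtMap(rawSeq(rnorm(256)), 0.2, nScales = 9L)
    mean(wm@bands[!wm@coi] == 5)
  })
  expect_equal(mean(props), 0.2, tolerance = 0.03)
})

test_that("degenerate series are rejected by the wavelet map", {
  expect_error(cwtMap(rawSeq(rep(1, 64)), 0.2), "degenerate|constant")
  expect_error(cwtMap(rawSeq(rnorm(8)), 0.2), "16")
})

test_that("hotspot calls merge intervals, sort them, and flag edges", {
  fx <- makePlantedSequence(length = 300, f0 = 0.2, amplitude = 1.5,
                            noiseSd = 0.2, seed = 41, region = c(100, 122))
  hs <- callHotspots(cwtMap(fx$sequence, 0.2), bandThreshold = 4L)
  expect_gt(nrow(hs), 0)
  expect_true(all(hs$start <= hs$end))
  expect_true(!is.unsorted(hs$start))
  covered <- unlist(Map(seq, hs$start, hs$end))
  expect_gte(mean(100:122 %in% covered), 0.8)
  # an all-low map yields no hotspots
  wm <- cwtMap(rawSeq(rnorm(64)), 0.2)
  wm@bands[] <- 1L
  expect_equal(nrow(callHotspots(wm, 4L)), 0)
})

test_that("two separated bursts give two sorted hotspot intervals", {
  set.seed(6)
  m <- 0:399
  x <- cos(2 * pi * 0.2 * m) * (m + 1 >= 80 & m + 1 <= 120) +
       cos(2 * pi * 0.2 * m) * (m + 1 >= 280 & m + 1 <= 320) +
       rnorm(400, sd = 0.05)
  hs <- callHotspots(cwtMap(rawSeq(x), 0.2), bandThreshold = 5L)
  expect_gte(nrow(hs), 2)
  covered <- unlist(Map(seq, hs$start, hs$end))
  expect_gt(mean(80:120 %in% covered), 0.5)
  expect_gt(mean(280:320 %in% covered), 0.5)
  expect_true(!is.unsorted(hs$start))
})

test_that("interval export round-trips CSV and converts BED coordinates", {
  d <- data.frame(proteinId = "p", start = 100L, end = 122L,
                  frequency = 0.2, peakResponse = 3.2)
  csv <- tempfile(fileext = ".csv"); bed <- tempfile(fileext = ".bed")
  writeIntervalsCsv(d, csv)
  back <- read.csv(csv)
  expect_equal(back$start, 100L)
  writeIntervalsBed(d, bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(99L, 122L))  # 0-based half-open
})
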