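# Informational spectra, cross-spectra, peaks, S/N and bin matching.

test_that("spectrum of a constant series is identically zero after mean-centering", {
  s <- dftSpectrum(rawSeq(rep(3.7, 20)), 32L)
  expect_equal(amplitudes(s), rep(0, 16))
})

test_that("an on-grid cosine concentrates amplitude L/2 in its bin", {
  L <- 32L
  x <- cos(2 * pi * 3 * (0:(L - 1)) / L)
  s <- dftSpectrum(rawSeq(x), L)
  a <- amplitudes(s)
  expect_equal(a[3], L / 2, tolerance = 1e-9)
  expect_lt(max(a[-3]), 1e-9)
  expect_equal(frequencies(s)[3], 3 / 32)
})

test_that("spectrum matches the brute-force DFT and is shift-invariant", {
  set.seed(101)
  for (i in 1:5) {
    n <- sample(20:64, 1)
    x <- rnorm(n)
    s <- dftSpectrum(rawSeq(x), 64L)
    expect_equal(amplitudes(s), naiveDftAmplitudes(x, 64L), tolerance = 1e-9)
    # adding a constant leaves amplitudes unchanged (mean-centering)
    s2 <- dftSpectrum(rawSeq(x + 42), 64L)
    expect_equal(amplitudes(s2), amplitudes(s), tolerance = 1e-9)
  }
})

test_that("half-spectrum energy obeys Parseval for mean-centered input", {
  set.seed(7)
  x <- rnorm(64)
  L <- 64L
  a <- amplitudes(dftSpectrum(rawSeq(x), L))
  xc <- x - mean(x)
  # X(0) = 0 after centering; Nyquist bin is self-conjugate
  expect_equal(2 * sum(a^2) - a[L / 2]^2, L * sum(xc^2), tolerance = 1e-9)
})

test_that("grid shorter than the series is rejected", {
  expect_error(dftSpectrum(rawSeq(rnorm(100)), 64L), "shorter")
  expect_error(dftSpectrum(rawSeq(rnorm(10)), 15L), "even")
})

test_that("cross-spectrum is the bin-wise product and permutation-invariant", {
  set.seed(3)
  s1 <- dftSpectrum(rawSeq(rnorm(30), "a"), 64L)
  s2 <- dftSpectrum(rawSeq(rnorm(40), "b"), 64L)
  expect_equal(amplitudes(crossSpectrum(list(s1))), amplitudes(s1))
  expect_equal(amplitudes(crossSpectrum(list(s1, s1))), amplitudes(s1)^2)
  cs12 <- crossSpectrum(list(s1, s2))
  cs21 <- crossSpectrum(list(s2, s1))
  expect_equal(amplitudes(cs12), amplitudes(s1) * amplitudes(s2))
  expect_equal(amplitudes(cs12), amplitudes(cs21))
  expect_setequal(memberIds(cs12), c("a", "b"))
  # a zero bin annihilates the product
  z <- amplitudes(s1); z[5] <- 0
  sz <- new("InformationalSpectrum", sourceId = "z", gridLength = 64L,
            amplitudes = z)
  expect_equal(amplitudes(crossSpectrum(list(sz, s2)))[5], 0)
})

test_that("mismatched grids are reported with the offending ids", {
  s1 <- dftSpectrum(rawSeq(rnorm(30), "a"), 64L)
  s2 <- dftSpectrum(rawSeq(rnorm(30), "b"), 128L)
  expect_error(crossSpectrum(list(s1, s2)), "a.*b|different grids")
})

test_that("S/N is peak over mean amplitude", {
  L <- 64L
  uni <- new("InformationalSpectrum", sourceId = "u", gridLength = L,
             amplitudes = rep(2, L / 2))
  expect_equal(signalToNoise(uni, 0.1), 1)
  expect_equal(signalToNoise(uni, 0.5), 1)
  single <- rep(0, L / 2); single[10] <- 5
  sp <- new("InformationalSpectrum", sourceId = "s", gridLength = L,
            amplitudes = single)
  expect_equal(signalToNoise(sp, 10 / L), L / 2)  # B bins, mean = peak/B
  zero <- new("InformationalSpectrum", sourceId = "z", gridLength = L,
              amplitudes = rep(0, L / 2))
  expect_error(signalToNoise(zero, 0.1), "all-zero")
})

test_that("peak extraction ranks by amplitude with low-frequency tie-break", {
  L <- 64L
  a <- rep(0, L / 2); a[c(5, 20)] <- 3
  sp <- new("InformationalSpectrum", sourceId = "t", gridLength = L,
            amplitudes = a)
  pk <- findPeaks(sp, k = 5)
  expect_equal(pk$bin, c(5, 20))  # equal amplitude: lower frequency first
  mono <- new("InformationalSpectrum", sourceId = "m", gridLength = L,
              amplitudes = rev(seq_len(L / 2)) / 10)
  expect_equal(findPeaks(mono, k = 5)$bin, 1L)  # boundary maximum only
  zero <- new("InformationalSpectrum", sourceId = "z", gridLength = L,
              amplitudes = rep(0, L / 2))
  expect_equal(nrow(findPeaks(zero, k = 3)), 0)
})

test_that("minimum peak separation is enforced greedily", {
  L <- 64L
  a <- rep(0, L / 2); a[10] <- 5; a[11] <- 4; a[20] <- 3
  sp <- new("InformationalSpectrum", sourceId = "t", gridLength = L,
            amplitudes = a)
  pk <- findPeaks(sp, k = 3, minSeparationBins = 3L)
  expect_equal(pk$bin, c(10, 20))
})

test_that("frequency-to-bin matching is nearest-bin with tolerance flag", {
  m <- matchFrequency(0.333, 512L)
  expect_equal(m$bin, 170L)
  expect_equal(m$frequency, 170 / 512)
  expect_true(m$within)
  exact <- matchFrequency(8 / 64, 64L)
  expect_equal(exact$bin, 8L)
  expect_equal(exact$distance, 0)
  expect_equal(matchFrequency(0.5, 64L)$bin, 32L)
  expect_equal(matchFrequency(0.5, 512L)$bin, 256L)
})
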