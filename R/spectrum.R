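# Informational spectra: DFT of mean-centered, zero-padded EIIP series;
# cross-spectra as bin-wise amplitude products.

#' Default shared frequency grid length
#'
#' All spectra entering one cross-spectrum must live on a common grid; the
#' default is the next power of two at or above the longest series, but never
#' below \code{minimum} (512, which comfortably holds the longest tau
#' isoform, 758 residues, at the next power of two 1024).
#'
#' @param lengths integer vector of series lengths entering the analysis.
#' @param minimum smallest admissible grid.
#' @return single even integer grid length.
#' @export
defaultGridLength <- function(lengths, minimum = 512L) {
  stopifnot(length(lengths) >= 1L, all(lengths >= 1))
  as.integer(2^ceiling(log2(max(max(lengths), minimum))))
}

#' Informational spectrum of an EIIP series
#'
#' The series is mean-centered (EIIP series carry large DC offsets that would
#' otherwise leak into the low bins), zero-padded to \code{gridLength}, and
#' transformed with the DFT; amplitudes |X(n)| are reported on the normalized
#' frequency grid n/L for n = 1..L/2.
#'
#' @param seq an [EncodedSequence-class].
#' @param gridLength even DFT length L >= length(seq); default via
#'   [defaultGridLength()].
#' @return an [InformationalSpectrum-class].
#' @examples
#' fx <- makePlantedSequence(length = 128, f0 = 0.25, seed = 1)
#' dftSpectrum(fx$sequence, 128L)
#' @export
dftSpectrum <- function(seq, gridLength = defaultGridLength(length(seq))) {
  stopifnot(is(seq, "EncodedSequence"))
  L <- as.integer(gridLength)
  n <- length(seq)
  if (L %% 2L != 0L) stop("'gridLength' must be even")
  if (L < n)
    stop(sprintf("gridLength (%d) is shorter than the series '%s' (%d)",
                 L, seqId(seq), n))
  x <- eiipValues(seq)
  x <- x - mean(x)
  amps <- Mod(stats::fft(c(x, rep(0, L - n))))[2:(L %/% 2L + 1L)]
  new("InformationalSpectrum", sourceId = seqId(seq),
      gridLength = L, amplitudes = amps)
}

#' Cross-spectrum of informational spectra
#'
#' Bin-wise product C(j) = prod_i S(i, j) over the member spectra; a high
#' product marks a frequency component present in every member.
#'
#' @param spectra list of [InformationalSpectrum-class] (>= 1), all on the
#'   same grid.
#' @return a [CrossSpectrum-class].
#' @export
crossSpectrum <- function(spectra) {
  if (is(spectra, "InformationalSpectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, is, logical(1), "InformationalSpectrum")))
  Ls <- vapply(spectra, gridLength, integer(1))
  if (length(unique(Ls)) != 1L) {
    ids <- vapply(spectra, sourceId, character(1))
    stop("member spectra are on different grids: ",
         paste(sprintf("%s (L=%d)", ids, Ls), collapse = ", "))
  }
  amps <- Reduce(`*`, lapply(spectra, amplitudes))
  new("CrossSpectrum",
      memberIds = vapply(spectra, sourceId, character(1)),
      gridLength = Ls[1L], amplitudes = amps)
}

#' Match a frequency to its nearest grid bin
#'
#' @param f normalized frequency in (0, 0.5].
#' @param gridLength grid length L.
#' @param toleranceBins bin tolerance for the \code{within} flag.
#' @return list with \code{bin}, \code{frequency} (= bin/L),
#'   \code{distance} (|f - bin/L|), and logical \code{within}.
#' @examples
#' matchFrequency(0.333, 512L)  # bin 170 (0.33203)
#' @export
matchFrequency <- function(f, gridLength, toleranceBins = 1L) {
  stopifnot(length(f) == 1L, f > 0, f <= 0.5)
  L <- as.integer(gridLength)
  bin <- max(1L, min(L %/% 2L, as.integer(round(f * L))))
  list(bin = bin, frequency = bin / L, distance = abs(f - bin / L),
       within = abs(f - bin / L) <= toleranceBins / L)
}

#' @rdname signalToNoise
#' @export
setMethod("signalToNoise", "Spectrum", function(x, frequency) {
  amps <- amplitudes(x)
  m <- mean(amps)
  if (m == 0) stop("S/N undefined for an all-zero spectrum")
  amps[matchFrequency(frequency, gridLength(x))$bin] / m
})

# local maxima (boundaries included) of a non-negative vector; zero bins are
# never peaks so an all-zero spectrum yields none
.localMaxima <- function(a) {
  B <- length(a)
  if (B == 1L) return(which(a > 0))
  left <- c(TRUE, a[-1L] >= a[-B])
  right <- c(a[-B] >= a[-1L], TRUE)
  which(left & right & a > 0)
}

#' @rdname findPeaks
#' @export
setMethod("findPeaks", "Spectrum", function(x, k = 5L, minSeparationBins = 1L) {
  stopifnot(k >= 1L, minSeparationBins >= 1L)
  amps <- amplitudes(x)
  L <- gridLength(x)
  cand <- .localMaxima(amps)
  # amplitude descending, ties to the lower frequency
  cand <- cand[order(-amps[cand], cand)]
  chosen <- integer(0)
  for (b in cand) {
    if (length(chosen) >= k) break
    if (!length(chosen) || all(abs(chosen - b) >= minSeparationBins))
      chosen <- c(chosen, b)
  }
  meanAmp <- mean(amps)
  data.frame(bin = chosen, frequency = chosen / L,
             amplitude = amps[chosen],
             snr = if (meanAmp > 0) amps[chosen] / meanAmp
                   else rep(NA_real_, length(chosen)))
})

#' Export a spectrum as CSV
#'
#' Columns \code{frequency}, \code{amplitude}, \code{snr}.
#'
#' @param x an [InformationalSpectrum-class] or [CrossSpectrum-class].
#' @param path output file.
#' @return invisible path.
#' @export
writeSpectrumCsv <- function(x, path) {
  amps <- amplitudes(x)
  m <- mean(amps)
  utils::write.csv(data.frame(frequency = frequencies(x), amplitude = amps,
                              snr = if (m > 0) amps / m else NA_real_),
                   path, row.names = FALSE)
  invisible(path)
}
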