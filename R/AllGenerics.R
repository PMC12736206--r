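#' @rdname EncodedSequence-class
#' @param object,x an object.
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))
#' @rdname EncodedSequence-class
#' @export
setGeneric("seqKind", function(x) standardGeneric("seqKind"))
#' @rdname EncodedSequence-class
#' @export
setGeneric("eiipValues", function(x) standardGeneric("eiipValues"))
#' @rdname EncodedSequence-class
#' @export
setGeneric("seqTokens", function(x) standardGeneric("seqTokens"))

#' @rdname Spectrum-class
#' @param x a [Spectrum-class] derivative.
#' @export
setGeneric("gridLength", function(x) standardGeneric("gridLength"))
#' @rdname Spectrum-class
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))
#' @rdname Spectrum-class
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname InformationalSpectrum-class
#' @param x an [InformationalSpectrum-class].
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname CrossSpectrum-class
#' @param x a [CrossSpectrum-class].
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))

#' Signal-to-noise ratio at a frequency
#'
#' Amplitude at the bin nearest \code{frequency} divided by the mean amplitude
#' over all bins of the (cross-)spectrum; the standard ISM specificity
#' measure. Errors on an all-zero spectrum, where the ratio is undefined.
#'
#' @param x an [InformationalSpectrum-class] or [CrossSpectrum-class].
#' @param frequency normalized frequency in (0, 0.5].
#' @return a single non-negative number (unitless).
#' @examples
#' s <- dftSpectrum(makePlantedSequence(length = 128, f0 = 0.25, seed = 1)$sequence, 128L)
#' signalToNoise(s, 0.25)
#' @export
setGeneric("signalToNoise", function(x, frequency) standardGeneric("signalToNoise"))

#' Extract top spectral peaks
#'
#' Local maxima (boundary bins included) of the amplitude spectrum, ranked by
#' amplitude with ties broken toward the lower frequency, greedily enforcing a
#' minimum bin separation. Each peak is annotated with its S/N.
#'
#' @param x an [InformationalSpectrum-class] or [CrossSpectrum-class].
#' @param k maximum number of peaks to report.
#' @param minSeparationBins minimum bin distance between reported peaks.
#' @return data.frame with columns \code{bin}, \code{frequency},
#'   \code{amplitude}, \code{snr}; possibly fewer than \code{k} rows.
#' @export
setGeneric("findPeaks", function(x, k = 5L, minSeparationBins = 1L)
  standardGeneric("findPeaks"))
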