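#' @rdname EncodedSequence-class
#' @export
setMethod("seqId", "EncodedSequence", function(x) x@id)
#' @rdname EncodedSequence-class
#' @export
setMethod("seqKind", "EncodedSequence", function(x) x@kind)
#' @rdname EncodedSequence-class
#' @export
setMethod("eiipValues", "EncodedSequence", function(x) x@values)
#' @rdname EncodedSequence-class
#' @export
setMethod("seqTokens", "EncodedSequence", function(x) x@tokens)
#' @rdname EncodedSequence-class
#' @export
setMethod("length", "EncodedSequence", function(x) length(x@values))

setMethod("show", "EncodedSequence", function(object) {
  cat(sprintf("EncodedSequence '%s' (%s), %d positions\n",
              object@id, object@kind, length(object@values)))
  cat(sprintf("  EIIP range [%.4f, %.4f] Ry\n",
              min(object@values), max(object@values)))
})

#' @rdname Spectrum-class
#' @export
setMethod("gridLength", "Spectrum", function(x) x@gridLength)
#' @rdname Spectrum-class
#' @export
setMethod("amplitudes", "Spectrum", function(x) x@amplitudes)
#' @rdname Spectrum-class
#' @export
setMethod("frequencies", "Spectrum", function(x)
  seq_len(x@gridLength %/% 2L) / x@gridLength)
#' @rdname InformationalSpectrum-class
#' @export
setMethod("sourceId", "InformationalSpectrum", function(x) x@sourceId)
#' @rdname CrossSpectrum-class
#' @export
setMethod("memberIds", "CrossSpectrum", function(x) x@memberIds)

setMethod("show", "InformationalSpectrum", function(object) {
  cat(sprintf("InformationalSpectrum of '%s': L = %d, %d bins in (0, 0.5]\n",
              object@sourceId, object@gridLength, length(object@amplitudes)))
  i <- which.max(object@amplitudes)
  if (any(object@amplitudes > 0))
    cat(sprintf("  top bin %d, F(%.3f), amplitude %.4g\n",
                i, i / object@gridLength, object@amplitudes[i]))
})

setMethod("show", "CrossSpectrum", function(object) {
  cat(sprintf("CrossSpectrum of %d spectra (L = %d)\n",
              length(object@memberIds), object@gridLength))
  i <- which.max(object@amplitudes)
  if (any(object@amplitudes > 0))
    cat(sprintf("  top bin %d, F(%.3f), amplitude %.4g\n",
                i, i / object@gridLength, object@amplitudes[i]))
})

setMethod("show", "WindowProfile", function(object) {
  cat(sprintf(
    "WindowProfile of '%s' at F(%.3f): window %d, step %d, %d windows\n",
    object@proteinId, object@frequency, object@windowLength, object@step,
    length(object@positions)))
})

setMethod("show", "WaveletMap", function(object) {
  cat(sprintf(
    "WaveletMap of '%s' at F(%.3f): %d scales x %d positions (target row %d)\n",
    object@proteinId, object@frequency, length(object@scales),
    ncol(object@coefficients), object@targetScaleIndex))
})
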