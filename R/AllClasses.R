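#' @import methods
NULL

#' EncodedSequence: a biomolecule as an EIIP series
#'
#' An ordered series of electron-ion interaction potential (EIIP) values, in
#' Rydbergs, one per residue (proteins) or per atomic group / atom (small
#' molecules). This is the numerical signal all spectral analysis operates on.
#'
#' @slot id single identifier string.
#' @slot kind \code{"protein"} or \code{"ligand"}.
#' @slot values numeric EIIP series (Ry), finite, length >= 2.
#' @slot tokens source labels (residue codes or atomic-group keys), parallel
#'   to \code{values}.
#' @seealso [encodeProtein()], [encodeSmiles()], [dftSpectrum()]
#' @export
setClass("EncodedSequence",
  representation(id = "character", kind = "character",
                 values = "numeric", tokens = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@id) != 1L || is.na(object@id))
      msg <- c(msg, "'id' must be a single non-NA string")
    if (length(object@kind) != 1L || !object@kind %in% c("protein", "ligand"))
      msg <- c(msg, "'kind' must be \"protein\" or \"ligand\"")
    if (length(object@values) < 2L)
      msg <- c(msg, "EIIP series must have length >= 2")
    if (length(object@values) != length(object@tokens))
      msg <- c(msg, "'values' and 'tokens' must have equal length")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "EIIP values must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Virtual parent of single- and cross-spectra
#'
#' Holds a half-spectrum of non-negative amplitudes on the normalized
#' frequency grid f_n = n/L, n = 1..L/2, together with the grid length L.
#'
#' @slot gridLength even integer L (DFT length after zero-padding).
#' @slot amplitudes non-negative amplitudes, one per bin 1..L/2.
#' @export
setClass("Spectrum", representation("VIRTUAL",
  gridLength = "integer", amplitudes = "numeric"),
  validity = function(object) {
    msg <- NULL
    L <- object@gridLength
    if (length(L) != 1L || is.na(L) || L < 2L || L %% 2L != 0L)
      msg <- c(msg, "'gridLength' must be a single even integer >= 2")
    else if (length(object@amplitudes) != L %/% 2L)
      msg <- c(msg, "'amplitudes' must have length gridLength/2")
    if (!all(is.finite(object@amplitudes)) || any(object@amplitudes < 0))
      msg <- c(msg, "amplitudes must be finite and non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' InformationalSpectrum: amplitude spectrum of one EIIP series
#'
#' @slot sourceId id of the encoded sequence the spectrum was computed from.
#' @seealso [dftSpectrum()], [crossSpectrum()], [findPeaks()]
#' @export
setClass("InformationalSpectrum", contains = "Spectrum",
  representation(sourceId = "character"),
  validity = function(object) {
    if (length(object@sourceId) != 1L) "'sourceId' must be a single string"
    else TRUE
  })

#' CrossSpectrum: bin-wise product of informational spectra
#'
#' High cross-spectrum bins flag normalized frequencies shared by all members,
#' interpreted as common long-range interaction information.
#'
#' @slot memberIds ids of the member spectra (>= 1).
#' @seealso [crossSpectrum()], [signalToNoise()]
#' @export
setClass("CrossSpectrum", contains = "Spectrum",
  representation(memberIds = "character"),
  validity = function(object) {
    if (length(object@memberIds) < 1L) "need at least one member id" else TRUE
  })

#' WindowProfile: sliding-window response at one frequency
#'
#' Amplitude of the target-frequency bin for each window position along a
#' protein, used to localize the region contributing to a cross-spectrum peak.
#'
#' @slot proteinId id of the profiled sequence.
#' @slot frequency target normalized frequency.
#' @slot windowLength,step window size and stride, in residues.
#' @slot positions window-center residue indices (1-based).
#' @slot responses amplitude at the matched frequency bin per window.
#' @slot seqLength length of the profiled sequence.
#' @export
setClass("WindowProfile",
  representation(proteinId = "character", frequency = "numeric",
                 windowLength = "integer", step = "integer",
                 positions = "numeric", responses = "numeric",
                 seqLength = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@positions) != length(object@responses))
      msg <- c(msg, "'positions' and 'responses' must have equal length")
    if (length(object@positions) && any(diff(object@positions) <= 0))
      msg <- c(msg, "'positions' must be strictly increasing")
    if (any(!is.finite(object@responses)) || any(object@responses < 0))
      msg <- c(msg, "responses must be finite and non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' WaveletMap: |CWT| coefficients of an EIIP series
#'
#' Morlet continuous-wavelet-transform magnitude over a scale ladder
#' bracketing the scale equivalent to a target ISM frequency, with
#' coefficients binned into five quantile bands (band 5 = top quintile,
#' quantiles computed outside the cone of influence).
#'
#' @slot proteinId id of the transformed sequence.
#' @slot frequency target normalized frequency the ladder brackets.
#' @slot scales scale ladder (residues per wavelet oscillation unit).
#' @slot coefficients |CWT| matrix, scales x positions.
#' @slot bands integer quantile band (1-5) per cell.
#' @slot coi logical matrix flagging cone-of-influence (edge-effect) cells.
#' @slot targetScaleIndex row of \code{scales} matched to \code{frequency}.
#' @export
setClass("WaveletMap",
  representation(proteinId = "character", frequency = "numeric",
                 scales = "numeric", coefficients = "matrix",
                 bands = "matrix", coi = "matrix",
                 targetScaleIndex = "integer"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@coefficients)
    if (d[1L] != length(object@scales))
      msg <- c(msg, "one coefficient row per scale required")
    if (!identical(dim(object@bands), d) || !identical(dim(object@coi), d))
      msg <- c(msg, "'bands' and 'coi' must match 'coefficients' in shape")
    if (any(object@coefficients < 0))
      msg <- c(msg, "coefficients must be non-negative magnitudes")
    if (object@targetScaleIndex < 1L || object@targetScaleIndex > d[1L])
      msg <- c(msg, "'targetScaleIndex' out of range")
    if (is.null(msg)) TRUE else msg
  })
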