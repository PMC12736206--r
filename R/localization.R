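# Domain localization: sliding-window spectral response at a target
# frequency, and Morlet CWT hotspot mapping.

#' Sliding-window spectral response at one frequency
#'
#' Slides a window along the EIIP series; each window is mean-centered,
#' zero-padded to the analysis grid and transformed, and the amplitude at the
#' bin matched to \code{frequency} is recorded. High-response windows mark the
#' protein region carrying the periodicity behind a cross-spectrum peak.
#'
#' @param seq an [EncodedSequence-class].
#' @param frequency target normalized frequency in (0, 0.5].
#' @param windowLength window size in residues (default 64, resolving
#'   periodicities down to F ~ 0.08 while retaining residue-level
#'   localization).
#' @param step window stride in residues.
#' @param gridLength DFT grid for each window (default via
#'   [defaultGridLength()]).
#' @return a [WindowProfile-class]; positions are window centers, 1-based.
#' @export
slidingWindowProfile <- function(seq, frequency, windowLength = 64L,
                                 step = 1L,
                                 gridLength = defaultGridLength(windowLength)) {
  stopifnot(is(seq, "EncodedSequence"), step >= 1L)
  n <- length(seq)
  w <- as.integer(windowLength)
  if (w > n)
    stop(sprintf("windowLength (%d) exceeds sequence length (%d)", w, n))
  L <- as.integer(gridLength)
  bin <- matchFrequency(frequency, L)$bin
  x <- eiipValues(seq)
  starts <- seq.int(1L, n - w + 1L, by = as.integer(step))
  ang <- -2 * pi * bin * (seq_len(w) - 1L) / L
  kernel <- complex(real = cos(ang), imaginary = sin(ang))
  responses <- vapply(starts, function(s) {
    win <- x[s:(s + w - 1L)]
    Mod(sum((win - mean(win)) * kernel))
  }, numeric(1))
  new("WindowProfile", proteinId = seqId(seq), frequency = frequency,
      windowLength = w, step = as.integer(step),
      positions = starts + (w - 1) / 2, responses = responses,
      seqLength = as.integer(n))
}

#' Call the domain contributing to a frequency
#'
#' Windows with response >= \code{thresholdFraction} times the maximum
#' response are grouped into contiguous runs; the run containing the highest
#' response (ties broken toward the earlier run) is converted to a residue
#' interval spanning the first window's start to the last window's end.
#'
#' @param profile a [WindowProfile-class].
#' @param thresholdFraction fraction of the peak response in (0, 1].
#' @return one-row data.frame: \code{proteinId}, \code{start}, \code{end}
#'   (1-based inclusive), \code{frequency}, \code{peakResponse},
#'   \code{thresholdUsed}.
#' @export
callDomain <- function(profile, thresholdFraction = 0.7) {
  stopifnot(is(profile, "WindowProfile"),
            thresholdFraction > 0, thresholdFraction <= 1)
  r <- profile@responses
  if (!length(r)) stop("empty window profile")
  if (max(r) == 0) stop("all-zero window profile: no domain at this frequency")
  above <- r >= thresholdFraction * max(r)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  # run containing the highest response; ties -> earlier run
  best <- keep[which.max(vapply(keep, function(i)
    max(r[starts[i]:ends[i]]), numeric(1)))]
  w <- profile@windowLength
  firstWin <- profile@positions[starts[best]] - (w - 1) / 2
  lastWin <- profile@positions[ends[best]] + (w - 1) / 2
  data.frame(proteinId = profile@proteinId,
             start = as.integer(max(1, floor(firstWin))),
             end = as.integer(min(profile@seqLength, ceiling(lastWin))),
             frequency = profile@frequency,
             peakResponse = max(r),
             thresholdUsed = thresholdFraction)
}

# Morlet mother wavelet in the Fourier domain (Torrence-Compo normalization):
# psi_hat(s*w) = pi^(-1/4) * H(w) * exp(-(s*w - omega0)^2 / 2)
.morletCwt <- function(x, scales, omega0 = 6) {
  n <- length(x)
  w <- 2 * pi * c(0, seq_len(n %/% 2), -rev(seq_len((n - 1) %/% 2))) / n
  fx <- stats::fft(x)
  out <- matrix(0, nrow = length(scales), ncol = n)
  norm <- pi^(-0.25)
  for (i in seq_along(scales)) {
    s <- scales[i]
    psi <- norm * sqrt(2 * pi * s / 1) * exp(-((s * w - omega0)^2) / 2)
    psi[w <= 0] <- 0
    out[i, ] <- Mod(stats::fft(fx * psi, inverse = TRUE)) / n
  }
  out
}

# scale whose Morlet Fourier period equals 1/f (Torrence-Compo conversion)
.scaleForFrequency <- function(f, omega0 = 6)
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi * f)

#' Wavelet map of an EIIP series at a target frequency
#'
#' Morlet (omega0 = 6) continuous wavelet transform of the mean-centered
#' series over a logarithmic scale ladder bracketing the scale equivalent to
#' \code{frequency} (Fourier-period conversion). Absolute coefficients are
#' binned into five quantile bands; cells inside the cone of influence are
#' flagged and excluded from the quantile computation.
#'
#' @param seq an [EncodedSequence-class], length >= 16.
#' @param frequency target normalized frequency in (0, 0.5].
#' @param nScales number of scales on the ladder.
#' @param scaleSpan half-width of the ladder, in octaves around the target
#'   scale.
#' @param omega0 Morlet center angular frequency.
#' @return a [WaveletMap-class].
#' @export
cwtMap <- function(seq, frequency, nScales = 25L, scaleSpan = 2,
                   omega0 = 6) {
  stopifnot(is(seq, "EncodedSequence"))
  n <- length(seq)
  if (n < 16L) stop("sequence too short for a wavelet map (length >= 16)")
  x <- eiipValues(seq)
  if (stats::sd(x) == 0)
    stop("degenerate (constant) EIIP series: wavelet map undefined")
  x <- x - mean(x)
  sTarget <- .scaleForFrequency(frequency, omega0)
  # odd ladder so the middle row sits exactly on the target scale
  nScales <- as.integer(nScales)
  if (nScales %% 2L == 0L) nScales <- nScales + 1L
  expo <- seq(-scaleSpan, scaleSpan, length.out = nScales)
  scales <- sTarget * 2^expo
  coefs <- .morletCwt(x, scales, omega0)
  # cone of influence: e-folding distance sqrt(2)*s from either edge
  pos <- seq_len(n)
  coi <- t(vapply(scales, function(s)
    pos - 1 < sqrt(2) * s | n - pos < sqrt(2) * s, logical(n)))
  valid <- coefs[!coi]
  if (!length(valid)) stop("cone of influence covers the whole map; sequence too short for these scales")
  cuts <- stats::quantile(valid, probs = seq(0.2, 0.8, by = 0.2),
                          names = FALSE, type = 7)
  bands <- matrix(1L + findInterval(coefs, cuts, left.open = TRUE),
                  nrow = nrow(coefs))
  new("WaveletMap", proteinId = seqId(seq), frequency = frequency,
      scales = scales, coefficients = coefs, bands = bands, coi = coi,
      targetScaleIndex = which.min(abs(scales - sTarget)))
}

#' Call hotspot residues from a wavelet map
#'
#' At the scale matched to the map's target frequency, residues whose
#' quantile band is at least \code{bandThreshold} are merged into sorted,
#' non-overlapping intervals; intervals touching the cone of influence are
#' flagged as edge-affected.
#'
#' @param map a [WaveletMap-class].
#' @param bandThreshold minimum band, 1..5.
#' @return data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive), \code{scale}, \code{edgeAffected}; zero rows if no cell
#'   reaches the threshold.
#' @export
callHotspots <- function(map, bandThreshold = 4L) {
  stopifnot(is(map, "WaveletMap"), bandThreshold %in% 1:5)
  i <- map@targetScaleIndex
  hot <- map@bands[i, ] >= bandThreshold
  empty <- data.frame(start = integer(0), end = integer(0),
                      scale = numeric(0), edgeAffected = logical(0))
  if (!any(hot)) return(empty)
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  data.frame(start = starts[keep], end = ends[keep],
             scale = map@scales[i],
             edgeAffected = vapply(which(keep), function(j)
               any(map@coi[i, starts[j]:ends[j]]), logical(1)))
}

#' Export domain or hotspot intervals
#'
#' CSV keeps the package's 1-based inclusive residue coordinates; BED uses
#' 0-based half-open intervals (start - 1, end).
#'
#' @param intervals data.frame with \code{start}, \code{end} and optionally
#'   \code{proteinId}, \code{frequency}, score columns.
#' @param path output file.
#' @param proteinId chromosome/sequence name for BED when the data.frame has
#'   no \code{proteinId} column.
#' @return invisible path.
#' @export
writeIntervalsCsv <- function(intervals, path) {
  utils::write.csv(intervals, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIntervalsCsv
#' @export
writeIntervalsBed <- function(intervals, path, proteinId = "protein") {
  ids <- if ("proteinId" %in% names(intervals)) intervals$proteinId
         else rep(proteinId, nrow(intervals))
  score <- if ("peakResponse" %in% names(intervals)) intervals$peakResponse
           else rep(0, nrow(intervals))
  bed <- data.frame(chrom = ids, chromStart = intervals$start - 1L,
                    chromEnd = intervals$end,
                    name = sprintf("F%.3f", if ("frequency" %in% names(intervals))
                      intervals$frequency else rep(0, nrow(intervals))),
                    score = score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
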