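# Seeded synthetic fixtures with planted spectral ground truth: single
# sequences, ortholog-like families, decoy SMILES libraries, and ADMET blobs.
# Signals are injected directly in EIIP space for exact ground truth; a
# residue-quantized mode maps the sinusoid onto the nearest tabulated
# amino-acid EIIP values to emulate realistic protein input.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.plantedValues <- function(length, f0, amplitude, noiseSd, region = NULL) {
  m <- seq_len(length)
  signal <- amplitude * cos(2 * pi * f0 * (m - 1))
  if (!is.null(region)) {
    mask <- m >= region[1] & m <= region[2]
    signal[!mask] <- 0
  }
  signal + stats::rnorm(length, sd = noiseSd)
}

#' Synthetic EIIP series with a planted periodicity
#'
#' values(m) = amplitude * cos(2*pi*f0*(m-1)) + N(0, noiseSd^2), seeded. With
#' \code{region = c(start, end)} the cosine is present only inside the region
#' (a localized "burst"; noise everywhere). The generator's SNR is
#' amplitude / noiseSd. With \code{quantize = TRUE} the series is snapped to
#' the nearest tabulated amino-acid EIIP values and returned as a protein
#' built from the corresponding residues.
#'
#' @param length series length.
#' @param f0 planted normalized frequency in (0, 0.5].
#' @param amplitude cosine amplitude (EIIP units, Ry).
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed RNG seed (mandatory).
#' @param region optional \code{c(start, end)} burst region, 1-based
#'   inclusive.
#' @param id identifier of the generated sequence.
#' @param quantize snap values to the tabulated amino-acid EIIP alphabet.
#' @return list with \code{sequence} (an [EncodedSequence-class]), and ground
#'   truth \code{f0}, \code{region}, \code{snr}.
#' @export
makePlantedSequence <- function(length = 512L, f0 = 0.25, amplitude = 1,
                                noiseSd = 0, seed, region = NULL,
                                id = "planted", quantize = FALSE) {
  if (missing(seed)) stop("'seed' is mandatory for fixture generation")
  if (f0 <= 0 || f0 > 0.5) stop("'f0' must lie in (0, 0.5]")
  if (!is.null(region))
    stopifnot(length(region) == 2L, region[1] >= 1, region[2] <= length,
              region[1] <= region[2])
  vals <- .withSeed(seed, .plantedValues(length, f0, amplitude, noiseSd, region))
  if (quantize) {
    tab <- eiipTable()
    # center the alphabet so the sinusoid spans it
    centered <- tab - mean(range(tab))
    scaled <- vals * (diff(range(tab)) / 2) / max(abs(vals), 1e-12)
    tok <- names(tab)[apply(abs(outer(scaled, centered, "-")), 1, which.min)]
    seq <- encodeProtein(paste(tok, collapse = ""), id = id)
  } else {
    seq <- new("EncodedSequence", id = id, kind = "protein",
               values = vals, tokens = rep("*", length))
  }
  list(sequence = seq, f0 = f0, region = region,
       snr = if (noiseSd > 0) amplitude / noiseSd else Inf)
}

#' Synthetic ortholog-like family sharing one periodicity
#'
#' n sequences carrying the same planted frequency with independent noise and
#' uniform length jitter of +/- \code{jitter} (fraction of \code{length}),
#' emulating a set of mammalian orthologs with a conserved spectral region.
#'
#' @inheritParams makePlantedSequence
#' @param n family size.
#' @param jitter relative length jitter (0.1 = +/-10 percent).
#' @return list with \code{sequences} (list of [EncodedSequence-class]) and
#'   \code{f0}.
#' @export
makeOrthologFamily <- function(n = 12L, length = 512L, f0 = 0.25,
                               amplitude = 1, noiseSd = 0, jitter = 0.1,
                               seed) {
  if (missing(seed)) stop("'seed' is mandatory for fixture generation")
  if (n < 2L) stop("a family needs n >= 2 members")
  if (f0 <= 0 || f0 > 0.5) stop("'f0' must lie in (0, 0.5]")
  sequences <- .withSeed(seed, {
    lens <- round(length * stats::runif(n, 1 - jitter, 1 + jitter))
    lapply(seq_len(n), function(i)
      new("EncodedSequence", id = sprintf("ortholog_%02d", i),
          kind = "protein",
          values = .plantedValues(lens[i], f0, amplitude, noiseSd),
          tokens = rep("*", lens[i])))
  })
  list(sequences = sequences, f0 = f0)
}

# a matched ligand whose per-group EIIP series is periodic with period
# p = round(1/f0): a repeating C/N/O chain unit. N and O are interleaved so
# the fundamental dominates the p/2 harmonic; dominance holds for p <= ~6.
.matchedLigandSmiles <- function(f0, nUnits = 16L) {
  p <- max(2L, as.integer(round(1 / f0)))
  unit <- if (p == 2L) "CO"
    else if (p %% 2L == 0L)
      paste0(strrep("C", p %/% 2L - 1L), "N", strrep("C", p %/% 2L - 1L), "O")
    else
      paste0(strrep("C", (p - 1L) %/% 2L), "N",
             strrep("C", (p - 1L) %/% 2L - 1L), "O")
  paste(rep(unit, nUnits), collapse = "")
}

#' Random decoy SMILES library
#'
#' Small random molecules from a tiny chain-and-branch grammar over C/N/O/S
#' (always valid SMILES), optionally with one planted "matched ligand" whose
#' per-group EIIP series is periodic at \code{f0} (a poly-ether chain with
#' heavy-atom period round(1/f0), id \code{"LIG_MATCHED"}).
#'
#' @param n number of decoys.
#' @param seed RNG seed (mandatory).
#' @param matchedLigand also plant the frequency-matched ligand.
#' @param f0 target normalized frequency for the matched ligand.
#' @param sizeRange heavy-atom count range of the decoys.
#' @return data.frame with columns \code{id}, \code{smiles}.
#' @export
makeDecoyLibrary <- function(n = 50L, seed, matchedLigand = FALSE,
                             f0 = 0.25, sizeRange = c(5L, 14L)) {
  if (missing(seed)) stop("'seed' is mandatory for fixture generation")
  stopifnot(n >= 1L)
  atoms <- c("C", "C", "C", "N", "O", "S")
  smiles <- .withSeed(seed, vapply(seq_len(n), function(i) {
    sz <- sample(sizeRange[1]:sizeRange[2], 1L)
    toks <- sample(atoms, sz, replace = TRUE)
    toks[1] <- "C"  # keep terminal chemistry tame
    # sprinkle branches on interior carbons
    out <- toks[1]
    for (j in 2:sz) {
      if (j < sz && toks[j] == "C" && stats::runif(1) < 0.2)
        out <- c(out, "C(C)")
      else out <- c(out, toks[j])
    }
    paste(out, collapse = "")
  }, character(1)))
  lib <- data.frame(id = sprintf("DECOY_%04d", seq_len(n)), smiles = smiles)
  if (matchedLigand)
    lib <- rbind(data.frame(id = "LIG_MATCHED",
                            smiles = .matchedLigandSmiles(f0)), lib)
  lib
}

#' Gaussian-blob ADMET feature table
#'
#' k well-separated Gaussian clusters in feature space, for exercising
#' [clusterAdmet()] with known labels.
#'
#' @param nPerCluster rows per cluster.
#' @param k number of clusters.
#' @param nFeatures feature count (36 mirrors a full ADMET panel).
#' @param separation distance between cluster centers in units of the
#'   within-cluster standard deviation.
#' @param seed RNG seed (mandatory).
#' @return list with \code{table} (data.frame: \code{compound_id} +
#'   features) and \code{labels}.
#' @export
makeAdmetBlobs <- function(nPerCluster = 20L, k = 2L, nFeatures = 36L,
                           separation = 10, seed) {
  if (missing(seed)) stop("'seed' is mandatory for fixture generation")
  stopifnot(k <= nFeatures)
  .withSeed(seed, {
    # orthonormal center directions guarantee every pairwise distance equals
    # `separation` exactly
    q <- qr.Q(qr(matrix(stats::rnorm(nFeatures * k), ncol = k)))
    centers <- t(q) * separation / sqrt(2)
    rows <- do.call(rbind, lapply(seq_len(k), function(ci)
      matrix(stats::rnorm(nPerCluster * nFeatures,
                          mean = rep(centers[ci, ], each = nPerCluster)),
             nrow = nPerCluster)))
    colnames(rows) <- sprintf("feat%02d", seq_len(nFeatures))
    list(table = data.frame(compound_id = sprintf("cmp%03d", seq_len(k * nPerCluster)),
                            rows),
         labels = rep(seq_len(k), each = nPerCluster))
  })
}
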