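# End-to-end screening: derive target frequencies from known ligands and
# ortholog conservation, scan a compound library at those frequencies, rank
# by S/N or Total Score.

.emptyFrequencySet <- function() {
  data.frame(frequency = numeric(0), bin = integer(0),
             gridLength = integer(0), provenance = character(0),
             supporting = character(0), snr = numeric(0))
}

# add peaks to a frequency set, deduplicating within a bin tolerance;
# supporting ids are accumulated on merge and the stronger peak kept
.addFrequencies <- function(fs, peaks, gridLength, provenance, supporting,
                            toleranceBins = 1L) {
  for (i in seq_len(nrow(peaks))) {
    hit <- which(fs$gridLength == gridLength &
                   abs(fs$bin - peaks$bin[i]) <= toleranceBins)
    if (length(hit)) {
      h <- hit[1L]
      ids <- union(strsplit(fs$supporting[h], ";", fixed = TRUE)[[1]],
                   supporting)
      fs$supporting[h] <- paste(ids, collapse = ";")
      if (peaks$snr[i] > fs$snr[h]) {
        fs$frequency[h] <- peaks$frequency[i]
        fs$bin[h] <- peaks$bin[i]
        fs$snr[h] <- peaks$snr[i]
      }
    } else {
      fs <- rbind(fs, data.frame(frequency = peaks$frequency[i],
                                 bin = peaks$bin[i],
                                 gridLength = gridLength,
                                 provenance = provenance,
                                 supporting = paste(supporting, collapse = ";"),
                                 snr = peaks$snr[i]))
    }
  }
  fs
}

#' Characteristic frequencies from known ligands
#'
#' For each ligand, the cross-spectrum with the protein is computed and its
#' top \code{topK} peaks extracted; the union over ligands, deduplicated
#' within \code{toleranceBins}, is the candidate frequency set.
#'
#' @param protein the target's [EncodedSequence-class].
#' @param ligands list of ligand [EncodedSequence-class] (>= 1).
#' @param topK peaks per ligand cross-spectrum.
#' @param gridLength shared DFT grid; default spans all members via
#'   [defaultGridLength()].
#' @param toleranceBins dedup tolerance, in bins.
#' @return a frequency-set data.frame (columns \code{frequency}, \code{bin},
#'   \code{gridLength}, \code{provenance}, \code{supporting}, \code{snr}).
#' @export
deriveLigandFrequencies <- function(protein, ligands, topK = 1L,
                                    gridLength = NULL, toleranceBins = 1L) {
  stopifnot(is(protein, "EncodedSequence"), length(ligands) >= 1L)
  if (is.null(gridLength))
    gridLength <- defaultGridLength(c(length(protein),
                                      vapply(ligands, length, integer(1))))
  ps <- dftSpectrum(protein, gridLength)
  fs <- .emptyFrequencySet()
  for (lig in ligands) {
    cs <- crossSpectrum(list(ps, dftSpectrum(lig, gridLength)))
    peaks <- findPeaks(cs, k = topK)
    fs <- .addFrequencies(fs, peaks, gridLength, "ligand-CS",
                          c(seqId(protein), seqId(lig)), toleranceBins)
  }
  fs[order(-fs$snr, fs$bin), , drop = FALSE]
}

#' Joint frequency over protein plus all ligands
#'
#' One cross-spectrum over the protein and every ligand together; its top
#' peak(s) are frequencies shared by all members simultaneously.
#'
#' @inheritParams deriveLigandFrequencies
#' @export
deriveJointFrequency <- function(protein, ligands, topK = 1L,
                                 gridLength = NULL) {
  stopifnot(is(protein, "EncodedSequence"), length(ligands) >= 2L)
  if (is.null(gridLength))
    gridLength <- defaultGridLength(c(length(protein),
                                      vapply(ligands, length, integer(1))))
  spectra <- c(list(dftSpectrum(protein, gridLength)),
               lapply(ligands, dftSpectrum, gridLength = gridLength))
  cs <- crossSpectrum(spectra)
  peaks <- findPeaks(cs, k = topK)
  .addFrequencies(.emptyFrequencySet(), peaks, gridLength, "joint-CS",
                  vapply(spectra, sourceId, character(1)))
}

#' Evolutionarily conserved frequency from orthologs
#'
#' Cross-spectrum over a set of ortholog sequences; a dominant shared peak
#' indicates a conserved spectral region.
#'
#' @param orthologs list of [EncodedSequence-class] (>= 2).
#' @inheritParams deriveLigandFrequencies
#' @export
deriveOrthologFrequency <- function(orthologs, topK = 1L,
                                    gridLength = NULL) {
  stopifnot(length(orthologs) >= 2L)
  if (is.null(gridLength))
    gridLength <- defaultGridLength(vapply(orthologs, length, integer(1)))
  spectra <- lapply(orthologs, dftSpectrum, gridLength = gridLength)
  cs <- crossSpectrum(spectra)
  peaks <- findPeaks(cs, k = topK)
  .addFrequencies(.emptyFrequencySet(), peaks, gridLength, "ortholog-CS",
                  vapply(spectra, sourceId, character(1)))
}

#' Screen a compound library at target frequencies
#'
#' Each compound is EIIP-encoded, its cross-spectrum with the protein
#' computed, and amplitude and S/N read at every target frequency. A
#' compound qualifies as a hit through its best frequency (S/N >=
#' \code{snrCutoff}). With a descriptor table, Total Score = dS * best S/N
#' drives the ranking; otherwise the best S/N does. Ties break by
#' \code{compound_id}, making the ranking independent of library order.
#'
#' @param protein the target's [EncodedSequence-class].
#' @param library data.frame with \code{id}, \code{smiles} (see
#'   [readSmilesTable()]).
#' @param freqs frequency-set data.frame (see [deriveLigandFrequencies()]) or
#'   a numeric vector of normalized frequencies.
#' @param descriptors optional descriptor table for [computeDrugScores()].
#' @param gridLength shared DFT grid; default spans protein and library.
#' @param snrCutoff hit threshold on the best-frequency S/N (the observed
#'   S/N of mid-ranked true hits spans roughly 20-40, hence the default 20).
#' @param mode SMILES encoding mode, see [encodeSmiles()].
#' @return list with \code{summary} (one ranked row per compound:
#'   \code{compound_id}, \code{bestFrequency}, \code{bestSnr}, \code{hit},
#'   optionally \code{dS} and \code{totalScore}, \code{rank}),
#'   \code{perFrequency} (compound x frequency long table), and
#'   \code{skipped} (ids of unparseable compounds).
#' @export
screenLibrary <- function(protein, library, freqs, descriptors = NULL,
                          gridLength = NULL, snrCutoff = 20,
                          mode = c("per-group", "per-atom")) {
  mode <- match.arg(mode)
  stopifnot(is(protein, "EncodedSequence"), nrow(library) >= 1L)
  if (is.numeric(freqs)) freqs <- data.frame(frequency = freqs)
  if (!nrow(freqs)) stop("empty frequency set")
  enc <- encodeSmilesBatch(library$smiles, library$id, mode = mode)
  skipped <- names(enc$errors)
  if (length(skipped))
    message(sprintf("screenLibrary: skipped %d unparseable compound(s): %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  if (!length(enc$sequences))
    stop("no library compound could be encoded")
  if (is.null(gridLength))
    gridLength <- defaultGridLength(c(length(protein),
                                      vapply(enc$sequences, length, integer(1))))
  ps <- dftSpectrum(protein, gridLength)
  bins <- vapply(freqs$frequency, function(f)
    matchFrequency(f, gridLength)$bin, integer(1))
  rows <- lapply(enc$sequences, function(lig) {
    cs <- crossSpectrum(list(ps, dftSpectrum(lig, gridLength)))
    amps <- amplitudes(cs)
    m <- mean(amps)
    snr <- if (m > 0) amps[bins] / m else rep(0, length(bins))
    data.frame(compound_id = seqId(lig), frequency = freqs$frequency,
               bin = bins, amplitude = amps[bins], snr = snr)
  })
  perFrequency <- do.call(rbind, rows)
  rownames(perFrequency) <- NULL
  best <- do.call(rbind, lapply(rows, function(r) {
    i <- which.max(r$snr)
    data.frame(compound_id = r$compound_id[1], bestFrequency = r$frequency[i],
               bestSnr = r$snr[i])
  }))
  best$hit <- best$bestSnr >= snrCutoff
  if (!is.null(descriptors)) {
    ds <- computeDrugScores(descriptors)
    best$dS <- ds$dS[match(best$compound_id, ds$compound_id)]
    if (anyNA(best$dS))
      stop("descriptor table is missing compound(s): ",
           paste(best$compound_id[is.na(best$dS)], collapse = ", "))
    best$totalScore <- totalScore(best$dS, best$bestSnr)
    ord <- order(-best$totalScore, best$compound_id)
  } else {
    ord <- order(-best$bestSnr, best$compound_id)
  }
  best <- best[ord, , drop = FALSE]
  best$rank <- seq_len(nrow(best))
  rownames(best) <- NULL
  perFrequency <- perFrequency[order(perFrequency$compound_id,
                                     perFrequency$frequency), , drop = FALSE]
  rownames(perFrequency) <- NULL
  list(summary = best, perFrequency = perFrequency, skipped = skipped)
}

#' Write screening results and a run manifest
#'
#' \code{writeHitsCsv} writes the ranked per-compound summary;
#' \code{writeRunManifest} records the run parameters (grid length, encoding
#' mode, cutoffs, seed) as JSON for reproducibility.
#'
#' @param screen result of [screenLibrary()].
#' @param path output file.
#' @return invisible path.
#' @export
writeHitsCsv <- function(screen, path) {
  utils::write.csv(screen$summary, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHitsCsv
#' @param params named list of run parameters.
#' @export
writeRunManifest <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
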