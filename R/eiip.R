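# EIIP encoding: AQVN and EIIP pseudopotential, protein and SMILES encoders.
# Z_i is the valence-ELECTRON count of the element (AQVN convention), not the
# bonding valence.
.VALENCE_ELECTRONS <- c(
  H = 1, B = 3, C = 4, Si = 4, N = 5, P = 5, As = 5,
  O = 6, S = 6, Se = 6, F = 7, Cl = 7, Br = 7, I = 7)

#' Average quasi-valence number (AQVN)
#'
#' Z* = (1/N) * sum(n_i * Z_i) over the elements of a molecule or atomic
#' group, where Z_i is the valence-electron count of element i and N the
#' total atom count.
#'
#' @param composition named vector (or table) of non-negative atom counts,
#'   names being element symbols, e.g. \code{c(C = 1, H = 4)} for methane.
#' @return the AQVN, a single unitless real.
#' @examples
#' computeAQVN(c(C = 1, H = 4))  # 1.6
#' computeAQVN(c(C = 6, H = 6))  # 2.5
#' @export
computeAQVN <- function(composition) {
  composition <- unclass(composition)
  counts <- as.numeric(composition)
  elements <- names(composition)
  if (is.null(elements) || !length(counts))
    stop("'composition' must be a non-empty named vector of atom counts")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("atom counts must be non-negative integers")
  if (sum(counts) < 1) stop("total atom count must be >= 1")
  unknown <- setdiff(elements[counts > 0], names(.VALENCE_ELECTRONS))
  if (length(unknown))
    stop("no valence-electron count defined for element(s): ",
         paste(unknown, collapse = ", "))
  sum(counts * .VALENCE_ELECTRONS[elements]) / sum(counts)
}

#' Electron-ion interaction potential (EIIP)
#'
#' W = 0.25 * Z* * sin(1.04 * pi * Z*) / (2 * pi), in Rydbergs. Vectorized.
#'
#' @param aqvn AQVN value(s), see [computeAQVN()].
#' @return EIIP value(s) in Ry.
#' @examples
#' computeEIIP(2.5)   # ~0.0946 (aromatic CH group)
#' computeEIIP(1.6)   # ~-0.0554 (methane)
#' @export
computeEIIP <- function(aqvn) {
  stopifnot(is.numeric(aqvn), all(is.finite(aqvn)))
  0.25 * aqvn * sin(1.04 * pi * aqvn) / (2 * pi)
}

#' Amino-acid EIIP lookup table
#'
#' The per-residue EIIP values (Ry) used to encode protein sequences.
#' \code{mode = "tabulated"} (default) returns the classical tabulated set of
#' the EIIP literature, shipped as package data. \code{mode = "computed"}
#' derives values from residue atomic composition via [computeAQVN()] and
#' [computeEIIP()]; the two sets do not coincide (e.g. Leu is tabulated as
#' 0.0000 but has a nonzero composition-derived value), so the provenance is
#' attached as an attribute.
#'
#' @param mode \code{"tabulated"} or \code{"computed"}.
#' @return named numeric vector over the 20 standard one-letter codes, with
#'   attribute \code{provenance}.
#' @export
eiipTable <- function(mode = c("tabulated", "computed")) {
  mode <- match.arg(mode)
  if (mode == "tabulated") {
    f <- system.file("extdata", "eiip_amino_acids.csv", package = "ismsm",
                     mustWork = TRUE)
    tab <- utils::read.csv(f, stringsAsFactors = FALSE)
    out <- stats::setNames(tab$value, tab$token)
  } else {
    f <- system.file("extdata", "residue_composition.csv", package = "ismsm",
                     mustWork = TRUE)
    comp <- utils::read.csv(f, stringsAsFactors = FALSE)
    vals <- vapply(seq_len(nrow(comp)), function(i) {
      counts <- unlist(comp[i, c("C", "H", "N", "O", "S")])
      computeEIIP(computeAQVN(counts))
    }, numeric(1))
    out <- stats::setNames(vals, comp$token)
  }
  attr(out, "provenance") <- mode
  out
}

#' Read or write a token -> EIIP table as two-column CSV
#'
#' @param path file path; columns \code{token,value}.
#' @return named numeric vector (read) or invisible path (write).
#' @export
readEiipTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("token", "value") %in% names(tab)))
    stop("EIIP table must have columns 'token' and 'value'; found: ",
         paste(names(tab), collapse = ", "))
  stats::setNames(as.numeric(tab$value), as.character(tab$token))
}

#' @rdname readEiipTable
#' @param table named numeric vector.
#' @export
writeEiipTable <- function(table, path) {
  utils::write.csv(data.frame(token = names(table),
                              value = as.numeric(table)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode a protein sequence as an EIIP series
#'
#' Maps each residue of an amino-acid string to its EIIP value, preserving
#' order.
#'
#' @param sequence amino-acid string (one-letter codes); length >= 2.
#' @param id identifier for the resulting series.
#' @param table named EIIP lookup, see [eiipTable()].
#' @param policy what to do with residues absent from \code{table}
#'   (e.g. X/B/Z): \code{"strict"} errors listing the positions,
#'   \code{"skip"} drops them with a message.
#' @return an [EncodedSequence-class] with \code{kind = "protein"}.
#' @examples
#' encodeProtein("MAEPRQEF", id = "demo")
#' @export
encodeProtein <- function(sequence, id = "protein", table = eiipTable(),
                          policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  tokens <- strsplit(toupper(sequence), "")[[1]]
  if (length(tokens) < 2L)
    stop("protein sequence must have length >= 2")
  known <- tokens %in% names(table)
  if (!all(known)) {
    pos <- which(!known)
    if (policy == "strict")
      stop(sprintf("unknown residue(s) in '%s' at position(s) %s: %s", id,
                   paste(pos, collapse = ", "),
                   paste(unique(tokens[pos]), collapse = ", ")))
    message(sprintf("encodeProtein: skipping %d unknown residue(s) in '%s' at position(s) %s",
                    length(pos), id, paste(pos, collapse = ", ")))
    tokens <- tokens[known]
    if (length(tokens) < 2L)
      stop("fewer than 2 residues remain after skipping unknowns")
  }
  new("EncodedSequence", id = id, kind = "protein",
      values = unname(table[tokens]), tokens = tokens)
}

.smilesToSdfset <- function(smiles, ids) {
  txt <- paste0(paste(smiles, ids), collapse = "\n")
  out <- suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "SDF", txt, options = data.frame(names = "h", args = "")))
  if (!nzchar(trimws(out))) return(list(sdfset = list(), got = character(0)))
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(
    ChemmineR::read.SDFstr(strsplit(out, "\n", fixed = TRUE)[[1]])))
  list(sdfset = sdfset, got = ChemmineR::sdfid(sdfset))
}

.sdfToGroups <- function(sdf) {
  ab <- rownames(ChemmineR::atomblock(sdf))
  elements <- sub("_.*$", "", ab)
  bb <- ChemmineR::bondblock(sdf)
  isH <- elements == "H"
  hPerHeavy <- integer(sum(!isH))
  if (nrow(bb)) {
    a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
    heavyIdx <- which(!isH)
    for (b in seq_along(a1)) {
      if (isH[a1[b]] && !isH[a2[b]])
        hPerHeavy[match(a2[b], heavyIdx)] <-
          hPerHeavy[match(a2[b], heavyIdx)] + 1L
      else if (isH[a2[b]] && !isH[a1[b]])
        hPerHeavy[match(a1[b], heavyIdx)] <-
          hPerHeavy[match(a1[b], heavyIdx)] + 1L
    }
  }
  list(elements = elements, hPerHeavy = hPerHeavy)
}

# Parse a batch of SMILES through openbabel into explicit-hydrogen atom and
# bond tables. Returns a list (one element per input) of
# list(elements, hPerHeavy) or a condition for unparseable entries.
# openbabel aborts a multi-record conversion at the first bad record, so
# inputs missing from the batch result are retried one at a time.
.parseSmilesBatch <- function(smiles, ids) {
  stopifnot(length(smiles) == length(ids))
  batch <- .smilesToSdfset(smiles, ids)
  res <- vector("list", length(smiles))
  names(res) <- ids
  for (i in seq_along(ids)) {
    j <- match(ids[i], batch$got)
    if (is.na(j)) {
      single <- .smilesToSdfset(smiles[i], ids[i])
      j2 <- match(ids[i], single$got)
      res[[i]] <- if (is.na(j2))
        simpleError(sprintf("unparseable SMILES for id '%s': %s",
                            ids[i], smiles[i]))
      else .sdfToGroups(single$sdfset[[j2]])
    } else {
      res[[i]] <- .sdfToGroups(batch$sdfset[[j]])
    }
  }
  res
}

# package-level cache of encoded SMILES (keyed by smiles + mode)
.smilesCache <- new.env(parent = emptyenv())

.encodeParsedSmiles <- function(parsed, id, mode) {
  elements <- parsed$elements
  heavy <- elements[elements != "H"]
  if (length(heavy) < 2L)
    stop(sprintf("molecule '%s' has fewer than 2 heavy atoms; series too short for a spectrum", id))
  if (mode == "per-group") {
    hs <- parsed$hPerHeavy
    vals <- vapply(seq_along(heavy), function(i) {
      comp <- c(1, hs[i])
      names(comp) <- c(heavy[i], "H")
      computeEIIP(computeAQVN(comp[comp > 0 | names(comp) != "H"]))
    }, numeric(1))
    tokens <- ifelse(parsed$hPerHeavy > 0,
                     paste0(heavy, "H", parsed$hPerHeavy), heavy)
  } else {
    z <- .VALENCE_ELECTRONS[elements]
    if (anyNA(z))
      stop("no valence-electron count defined for element(s): ",
           paste(unique(elements[is.na(z)]), collapse = ", "))
    vals <- computeEIIP(unname(z))
    tokens <- elements
  }
  new("EncodedSequence", id = id, kind = "ligand",
      values = vals, tokens = tokens)
}

#' Encode a SMILES-described molecule as an EIIP series
#'
#' The structure is expanded to explicit-hydrogen form and traversed in the
#' parser's canonical atom order. In \code{"per-group"} mode (default) each
#' heavy atom together with its bonded hydrogens forms one atomic group whose
#' AQVN (via [computeAQVN()]) gives one EIIP series element — e.g. every CH
#' group of benzene contributes \code{computeEIIP(2.5)}. In \code{"per-atom"}
#' mode every atom, hydrogens included, contributes
#' \code{computeEIIP(Z)} of its own valence-electron count.
#'
#' @param smiles SMILES string for one molecule (>= 2 heavy atoms).
#' @param id identifier carried into errors and the result.
#' @param mode \code{"per-group"} or \code{"per-atom"}.
#' @return an [EncodedSequence-class] with \code{kind = "ligand"}.
#' @examples
#' encodeSmiles("C1=CC=CC=C1", id = "benzene")
#' @export
encodeSmiles <- function(smiles, id = "ligand",
                         mode = c("per-group", "per-atom")) {
  mode <- match.arg(mode)
  out <- encodeSmilesBatch(smiles, id, mode = mode)
  if (length(out$errors))
    stop(conditionMessage(out$errors[[1]]))
  out$sequences[[1]]
}

#' Encode many SMILES at once
#'
#' Batch form of [encodeSmiles()]: one parser invocation for the whole
#' library, with per-molecule failures collected instead of thrown. Encodings
#' are cached per (SMILES, mode) within the session.
#'
#' @param smiles character vector of SMILES.
#' @param ids parallel identifiers (must be unique).
#' @inheritParams encodeSmiles
#' @return list with \code{sequences} (named list of [EncodedSequence-class])
#'   and \code{errors} (named list of conditions for skipped inputs).
#' @export
encodeSmilesBatch <- function(smiles, ids,
                              mode = c("per-group", "per-atom")) {
  mode <- match.arg(mode)
  stopifnot(length(smiles) == length(ids), !anyDuplicated(ids))
  keys <- paste0(mode, "\r", smiles)
  miss <- !vapply(keys, exists, logical(1), envir = .smilesCache)
  if (any(miss)) {
    # parse with positional ids so cache keys stay SMILES-based
    umiss <- !duplicated(keys) & miss
    pid <- paste0("q", seq_len(sum(umiss)))
    parsed <- .parseSmilesBatch(smiles[umiss], pid)
    for (i in seq_along(parsed)) {
      p <- parsed[[i]]
      key <- keys[umiss][i]
      val <- if (inherits(p, "error")) p else
        tryCatch(.encodeParsedSmiles(p, id = "x", mode = mode),
                 error = function(e) e)
      assign(key, val, envir = .smilesCache)
    }
  }
  sequences <- list(); errors <- list()
  for (i in seq_along(ids)) {
    v <- get(keys[i], envir = .smilesCache)
    if (inherits(v, "error")) {
      errors[[ids[i]]] <- simpleError(
        sub("id '[^']*'|molecule '[^']*'",
            sprintf("'%s'", ids[i]), conditionMessage(v)))
    } else {
      v@id <- ids[i]
      sequences[[ids[i]]] <- v
    }
  }
  list(sequences = sequences, errors = errors)
}
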