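# Readers/writers for the standard inputs: multi-record FASTA and headered
# SMILES tables.

#' Read a multi-record FASTA file
#'
#' Record ids are truncated at the first whitespace; sequences are uppercased.
#' Gap characters ('-', '.') and empty files are rejected.
#'
#' @param path FASTA file.
#' @return data.frame with columns \code{id}, \code{sequence}, in file order.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (!length(set)) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  gap <- grepl("[-.]", seqs)
  if (any(gap))
    stop("gap characters in record(s): ", paste(ids[gap], collapse = ", "))
  data.frame(id = ids, sequence = unname(seqs))
}

#' Write records to FASTA
#'
#' @param records data.frame with \code{id}, \code{sequence}.
#' @param path output file.
#' @return invisible path.
#' @export
writeFasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records)))
    writeLines(c(paste0(">", records$id[i]), records$sequence[i]), con)
  invisible(path)
}

#' Read a SMILES table
#'
#' Headered CSV or TSV (delimiter sniffed from the header line) with columns
#' \code{id} and \code{smiles}. Duplicate ids and blank SMILES cells are
#' rejected.
#'
#' @param path input file.
#' @return data.frame with columns \code{id}, \code{smiles}, in file order.
#' @export
readSmilesTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (!all(c("id", "smiles") %in% names(tab)))
    stop("SMILES table must have columns 'id' and 'smiles'; found: ",
         paste(names(tab), collapse = ", "))
  tab$id <- as.character(tab$id)
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup))
    stop("duplicate compound id(s): ", paste(unique(dup), collapse = ", "))
  blank <- which(is.na(tab$smiles) | !nzchar(trimws(tab$smiles)))
  if (length(blank))
    stop("blank SMILES in row(s): ", paste(blank, collapse = ", "))
  tab[c("id", "smiles")]
}

#' @rdname readSmilesTable
#' @param table data.frame with \code{id}, \code{smiles}.
#' @export
writeSmilesTable <- function(table, path) {
  utils::write.csv(table[c("id", "smiles")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
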