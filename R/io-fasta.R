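#' Read a FASTA file into a DNAStringSet
#'
#' Sequence names are truncated at the first whitespace, sequences are
#' normalized to upper case. Duplicate ids and empty sequences are errors.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by sequence id.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    abort(paste0("duplicate sequence ids in ", basename(path), ": ",
                 paste(unique(names(x)[duplicated(names(x))]), collapse = ", ")))
  }
  if (any(Biostrings::width(x) == 0L)) {
    abort(paste0("empty sequence in ", basename(path), ": ",
                 paste(names(x)[Biostrings::width(x) == 0L], collapse = ", ")))
  }
  Biostrings::DNAStringSet(toupper(x))
}

#' Write sequences to FASTA
#'
#' @param records A named [Biostrings::DNAStringSet] (or named character
#'   vector of sequences).
#' @param path Output path.
#' @param line_width Characters per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    abort("all records must be named")
  }
  Biostrings::writeXStringSet(records, path, width = line_width)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
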