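#' Read a BLAT PSL file into a tibble of alignment hits
#'
#' Parses the 21-column PSL layout (optionally preceded by the `psLayout`
#' header block) and converts each row to one alignment hit. Per-cent
#' identity is computed as `matches / (matches + misMatches)` and query
#' coverage as `(qEnd - qStart) / qSize`. Target coordinates in PSL are
#' already 0-based half-open and are kept that way. The reader never
#' filters: every row becomes a hit, duplicates included.
#'
#' @param path Path to a PSL file.
#' @return A tibble with one row per alignment and columns `query_id`,
#'   `target_id`, `identity`, `coverage`, `target_start`, `target_end`
#'   (0-based half-open) and `strand` (`"+"` or `"-"`).
#' @export
read_psl <- function(path) {
  lines <- readr::read_lines(path)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  # skip psLayout header block: lines until the first line whose first field
  # is an integer (data rows always start with the match count)
  is_data <- grepl("^[0-9]+\t", lines)
  if (any(!is_data)) {
    first_data <- match(TRUE, is_data)
    if (is.na(first_data)) first_data <- length(lines) + 1L
    if (any(!is_data[seq_len(length(lines)) >= first_data])) {
      bad <- lineno[which(!is_data & seq_along(lines) >= first_data)[1]]
      abort(sprintf("PSL parse error at line %d: row does not start with a match count", bad))
    }
    lines <- lines[is_data]
    lineno <- lineno[is_data]
  }
  if (length(lines) == 0L) {
    return(empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L)) {
    bad <- which(nf != 21L)[1]
    abort(sprintf("PSL parse error at line %d: expected 21 columns, found %d",
                  lineno[bad], nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 21L, byrow = TRUE)
  matches <- as.numeric(m[, 1]); mism <- as.numeric(m[, 2])
  q_size <- as.numeric(m[, 11]); q_start <- as.numeric(m[, 12]); q_end <- as.numeric(m[, 13])
  if (any(q_size == 0)) {
    bad <- which(q_size == 0)[1]
    abort(sprintf("PSL record error at line %d: qSize is 0", lineno[bad]))
  }
  denom <- matches + mism
  tibble(
    query_id = m[, 10],
    target_id = m[, 14],
    identity = ifelse(denom > 0, matches / denom, NA_real_),
    coverage = (q_end - q_start) / q_size,
    target_start = as.numeric(m[, 16]),
    target_end = as.numeric(m[, 17]),
    strand = substr(m[, 9], 1L, 1L)
  )
}

empty_hits <- function() {
  tibble(
    query_id = character(), target_id = character(),
    identity = numeric(), coverage = numeric(),
    target_start = numeric(), target_end = numeric(),
    strand = character()
  )
}

#' Read BLAST tabular (outfmt 6) alignments into a tibble of hits
#'
#' Parses the standard 12-column BLAST tabular layout. Identity is
#' `pident / 100`; coverage is alignment `length` divided by the query
#' length, which must be supplied externally because outfmt 6 lacks it.
#' A subject start greater than subject end encodes a minus-strand hit and
#' is normalized to 0-based half-open forward coordinates.
#'
#' @param path Path to a 12-column BLAST tabular file.
#' @param query_lengths Either a two-column data frame (`id`, `length`) as
#'   returned by [read_query_lengths()], or a named numeric vector. Every
#'   query id in the file must be present.
#' @return A tibble of alignment hits in the same shape as [read_psl()].
#' @export
read_blast6 <- function(path, query_lengths) {
  qlen <- as_query_lengths(query_lengths)
  cols <- c("query_id", "target_id", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                       col_types = readr::cols(
                         query_id = "c", target_id = "c",
                         .default = readr::col_double()
                       ), progress = FALSE)
  if (nrow(x) == 0L) return(empty_hits())
  missing_ids <- setdiff(unique(x$query_id), names(qlen))
  if (length(missing_ids) > 0L) {
    abort(paste0("query ids absent from query_lengths: ",
                 paste(missing_ids, collapse = ", ")))
  }
  minus <- x$sstart > x$send
  tibble(
    query_id = x$query_id,
    target_id = x$target_id,
    identity = x$pident / 100,
    coverage = x$length / unname(qlen[x$query_id]),
    target_start = ifelse(minus, x$send, x$sstart) - 1,
    target_end = ifelse(minus, x$sstart, x$send),
    strand = ifelse(minus, "-", "+")
  )
}

as_query_lengths <- function(query_lengths) {
  if (is.data.frame(query_lengths)) {
    if (!all(c("id", "length") %in% names(query_lengths))) {
      abort("query_lengths data frame needs columns 'id' and 'length'")
    }
    qlen <- setNames(as.numeric(query_lengths$length), query_lengths$id)
  } else {
    qlen <- query_lengths
  }
  if (is.null(names(qlen)) || any(!nzchar(names(qlen)))) {
    abort("query_lengths must be named by query id")
  }
  if (any(qlen <= 0)) abort("query lengths must be positive")
  qlen
}

#' Read a query-length table (TSV with columns `id`, `length`)
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `id` and `length`.
#' @export
read_query_lengths <- function(path) {
  x <- read_tsv_checked(path, c("id", "length"),
                        readr::cols(id = "c", length = "d"))
  if (anyDuplicated(x$id)) abort("duplicate ids in query length table")
  if (any(x$length <= 0)) abort("query lengths must be positive")
  x
}

# shared strict TSV reader: exact header, CRLF tolerated
read_tsv_checked <- function(path, expected, col_types) {
  hdr <- strsplit(sub("\r$", "", readr::read_lines(path, n_max = 1)), "\t")[[1]]
  unknown <- setdiff(hdr, expected)
  if (length(unknown) > 0L) {
    abort(paste0("unknown column in ", basename(path), ": ",
                 paste(unknown, collapse = ", ")))
  }
  miss <- setdiff(expected, hdr)
  if (length(miss) > 0L) {
    abort(paste0("missing column in ", basename(path), ": ",
                 paste(miss, collapse = ", ")))
  }
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)[, expected]
}
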