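#' Read a FASTA file into a record table
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that returns a plain
#' data frame and enforces a minimal structural check with line numbers, so
#' malformed files fail with an actionable message rather than deep inside
#' the parser. Reading is agnostic to line wrapping.
#'
#' @param path Path to a FASTA file (nucleotide or amino acid).
#' @return A data frame with columns `id` (first whitespace-delimited token
#'   of each header) and `sequence`. An empty file yields a zero-row frame.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA in ", path, ": line ", first,
         " precedes any '>' header")
  }
  empty_hdr <- nonblank[vapply(lines[nonblank], function(l) {
    l <- trimws(l)
    startsWith(l, ">") && !nzchar(sub("^>\\s*", "", l))
  }, logical(1))]
  if (length(empty_hdr)) {
    stop("malformed FASTA in ", path, ": empty header at line ", empty_hdr[1L])
  }
  set <- Biostrings::readBStringSet(path)
  data.frame(
    id = vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L),
    sequence = as.character(set),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write records to a FASTA file
#'
#' Sequences are wrapped at 60 columns. Round-trips with [read_fasta()] on
#' `id` and `sequence`.
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) {
    stop("duplicate record ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  set <- Biostrings::BStringSet(setNames(as.character(records$sequence),
                                         records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
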