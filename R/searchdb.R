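# Search-database construction: six-frame translation of transcriptome
# contigs into stop-free, nonredundant protein entries suitable for a
# spectral search engine.

#' Construct a transcript record table
#'
#' Validates identifiers and nucleotide alphabet ({A,C,G,T,N},
#' case-insensitive) and returns a normalised (upper-case) record table.
#'
#' @param id Character vector of transcript identifiers.
#' @param sequence Character vector of nucleotide sequences.
#' @param source Single label (or vector) naming the originating
#'   transcriptome set; becomes part of database entry ids.
#' @return Data frame with columns `id`, `sequence`, `source`.
#' @export
transcript_records <- function(id, sequence, source = "set1") {
  stopifnot(length(id) == length(sequence))
  if (length(id) == 0L) stop("no transcripts supplied")
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(sequence))) {
    stop("empty sequence for transcript: ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  }
  bad <- regexpr("[^ACGTN]", sequence)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("invalid nucleotide symbol '",
         substr(sequence[i], bad[i], bad[i]),
         "' in transcript '", id[i], "' at position ", bad[i])
  }
  data.frame(id = as.character(id), sequence = sequence,
             source = rep_len(as.character(source), length(id)),
             stringsAsFactors = FALSE)
}

frame_set <- c(1L, 2L, 3L, -1L, -2L, -3L)

frame_label <- function(frame) sprintf("%+d", frame)

#' Six-frame translation of a transcript into stop-free segments
#'
#' Translates a nucleotide sequence in all three forward frames and the
#' three frames of its reverse complement using the standard genetic code.
#' Stop codons split each frame's translation into segments; segments
#' shorter than `min_len` are discarded (their ordinal position within the
#' frame is retained for the survivors). Codons containing `N` translate to
#' `X`; trailing partial codons are dropped.
#'
#' @param transcript One-row data frame as produced by
#'   [transcript_records()] (columns `id`, `sequence`, `source`).
#' @param min_len Minimum retained segment length in residues; the default
#'   of 6 matches the shortest peptide a search engine will typically
#'   report.
#' @return Data frame of database entries with columns `id`
#'   (`source|transcript|frame|segment-index`), `sequence`, `frame`
#'   (integer in \{+1,+2,+3,-1,-2,-3\}) and `segment_index`.
#' @examples
#' tr <- transcript_records("tig1", "ATGGCTTAAGCT", source = "demo")
#' six_frame_translate(tr, min_len = 2)
#' @export
six_frame_translate <- function(transcript, min_len = 6L) {
  stopifnot(is.data.frame(transcript), nrow(transcript) == 1L,
            min_len >= 1L)
  transcript <- transcript_records(transcript$id, transcript$sequence,
                                   transcript$source)
  fwd <- Biostrings::DNAString(transcript$sequence)
  rev <- Biostrings::reverseComplement(fwd)
  out <- vector("list", 6L)
  n_segments_total <- 0L
  for (k in seq_along(frame_set)) {
    fr <- frame_set[k]
    d <- if (fr > 0L) fwd else rev
    off <- abs(fr)
    n_codon <- (length(d) - off + 1L) %/% 3L
    if (n_codon < 1L) next
    codons <- Biostrings::subseq(d, start = off, width = 3L * n_codon)
    aa <- as.character(Biostrings::translate(codons, if.fuzzy.codon = "X",
                                             no.init.codon = TRUE))
    segments <- strsplit(aa, "*", fixed = TRUE)[[1]]
    if (length(segments) == 0L) next
    n_segments_total <- n_segments_total + sum(nzchar(segments))
    keep <- nchar(segments) >= min_len
    if (!any(keep)) next
    idx <- which(keep)
    out[[k]] <- data.frame(
      id = sprintf("%s|%s|%s|%d", transcript$source, transcript$id,
                   frame_label(fr), idx),
      sequence = segments[idx],
      frame = fr,
      segment_index = idx,
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out) == 0L) {
    data.frame(id = character(0), sequence = character(0),
               frame = integer(0), segment_index = integer(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  rownames(res) <- NULL
  attr(res, "n_segments_total") <- n_segments_total
  res
}

#' Build a nonredundant protein search database from transcript sets
#'
#' Concatenates six-frame translations of one or more transcript sets and
#' removes exact duplicate amino-acid sequences, keeping the first
#' occurrence. "Nonredundant" here means exact full-sequence identity;
#' no similarity clustering is performed.
#'
#' @param sets A list of transcript record tables ([transcript_records()]),
#'   or a single table.
#' @param min_len Minimum retained segment length (residues).
#' @return A list of class `protein_db` with elements:
#'   \describe{
#'     \item{records}{data frame of retained entries (`id`, `sequence`,
#'       `frame`, `segment_index`)}
#'     \item{duplicates}{data frame logging dropped duplicates
#'       (`dropped_id`, `kept_id`)}
#'     \item{summary}{named list: `n_contigs`, `n_frame_translations`
#'       (contigs x 6), `n_raw_segments` (non-empty stop-split segments
#'       across all frames, before the length filter),
#'       `n_length_filtered` (segments of length >= `min_len`, before
#'       deduplication), `n_retained`}
#'   }
#' @export
build_database <- function(sets, min_len = 6L) {
  if (is.data.frame(sets)) sets <- list(sets)
  if (length(sets) == 0L || all(vapply(sets, nrow, integer(1)) == 0L)) {
    stop("at least one non-empty transcript set is required")
  }
  n_contigs <- 0L
  n_raw_segments <- 0L
  pieces <- list()
  for (s in seq_along(sets)) {
    set <- sets[[s]]
    dup <- unique(set$id[duplicated(set$id)])
    if (length(dup)) {
      stop("duplicate transcript ids within set ", s, ": ",
           paste(dup, collapse = ", "))
    }
    n_contigs <- n_contigs + nrow(set)
    for (i in seq_len(nrow(set))) {
      tr <- six_frame_translate(set[i, , drop = FALSE], min_len = min_len)
      n_raw_segments <- n_raw_segments + attr(tr, "n_segments_total")
      pieces[[length(pieces) + 1L]] <- tr
    }
  }
  raw <- do.call(rbind, pieces)
  if (is.null(raw)) {
    raw <- data.frame(id = character(0), sequence = character(0),
                      frame = integer(0), segment_index = integer(0),
                      stringsAsFactors = FALSE)
  }
  dup_mask <- duplicated(raw$sequence)
  kept <- raw[!dup_mask, , drop = FALSE]
  dropped <- raw[dup_mask, , drop = FALSE]
  kept_for <- kept$id[match(dropped$sequence, kept$sequence)]
  structure(list(
    records = kept,
    duplicates = data.frame(dropped_id = dropped$id, kept_id = kept_for,
                            stringsAsFactors = FALSE),
    summary = list(
      n_contigs = n_contigs,
      n_frame_translations = n_contigs * 6L,
      n_raw_segments = n_raw_segments,
      n_length_filtered = nrow(raw),
      n_retained = nrow(kept)
    )
  ), class = "protein_db")
}

#' @export
print.protein_db <- function(x, ...) {
  s <- x$summary
  cat("Nonredundant protein search database\n")
  cat(sprintf("  contigs: %d (%d frame translations)\n",
              s$n_contigs, s$n_frame_translations))
  cat(sprintf("  raw segments: %d, retained nonredundant: %d\n",
              s$n_raw_segments, s$n_retained))
  invisible(x)
}
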