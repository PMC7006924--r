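# Reporter-ion quantification for an iTRAQ 8-plex run: PSM-level filtering
# on the study's quantifiability rules, then per-protein channel ratios
# against the mean of the two ambient-control channels.

#' Default iTRAQ 8-plex channel labels
#'
#' The 8-plex reporter ions used here: 113, 114, 115, 116, 117, 118, 119
#' and 121 (120 is skipped in the 8-plex chemistry).
#' @export
itraq8_channels <- c("113", "114", "115", "116", "117", "118", "119", "121")

#' Construct an 8-plex experimental design
#'
#' Maps each reporter channel of one run to a treatment and biological
#' replicate, and records which two channels carry the ambient-seawater
#' controls that all ratios are computed against.
#'
#' @param run_id Run identifier.
#' @param channels Character vector of exactly 8 channel labels.
#' @param treatments Treatment per channel.
#' @param replicates Biological replicate id per channel.
#' @param control_channels The two ambient-control channel labels.
#' @return An object of class `plex_design` with a `map` data frame
#'   (`channel`, `treatment`, `replicate`) plus `run_id` and
#'   `control_channels`.
#' @export
plex_design <- function(run_id, channels = itraq8_channels, treatments,
                        replicates, control_channels = c("113", "117")) {
  channels <- as.character(channels)
  if (length(channels) != 8L || anyDuplicated(channels)) {
    stop("a plex design requires exactly 8 distinct channels")
  }
  stopifnot(length(treatments) == 8L, length(replicates) == 8L)
  if (!all(control_channels %in% channels) || length(control_channels) != 2L) {
    stop("control_channels must name two of the design's channels")
  }
  if (!all(treatments[match(control_channels, channels)] == "control")) {
    stop("control channels must carry the 'control' treatment")
  }
  key <- paste(treatments, replicates)
  if (anyDuplicated(key)) {
    stop("each (treatment, replicate) pair may appear at most once per run: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  structure(list(
    run_id = as.character(run_id),
    map = data.frame(channel = channels,
                     treatment = as.character(treatments),
                     replicate = as.character(replicates),
                     stringsAsFactors = FALSE),
    control_channels = as.character(control_channels)
  ), class = "plex_design")
}

#' The study's two-run tetraplicate design
#'
#' Two 8-plex runs covering four treatments in biological tetraplicate:
#' in each run, ambient-seawater controls on channels 113 and 117,
#' methanol carrier controls on 114 and 118, purified brevetoxins on 115
#' and 119, and live *K. brevis* on 116 and 121. Run 1 carries replicates
#' 1-2 and run 2 replicates 3-4.
#'
#' @return A named list of two `plex_design` objects.
#' @export
default_plex_designs <- function() {
  treatments <- c("control", "MeOH", "PbTx", "Kbrevis",
                  "control", "MeOH", "PbTx", "Kbrevis")
  mk <- function(run, reps) {
    plex_design(run_id = run, treatments = treatments,
                replicates = as.character(reps))
  }
  list(run1 = mk("run1", c(1, 1, 1, 1, 2, 2, 2, 2)),
       run2 = mk("run2", c(3, 3, 3, 3, 4, 4, 4, 4)))
}

intensity_cols <- function(channels) paste0("intensity_", channels)
sn_cols <- function(channels) paste0("sn_", channels)

design_for_run <- function(designs, run_id) {
  if (inherits(designs, "plex_design")) designs <- list(designs)
  ids <- vapply(designs, function(d) d$run_id, character(1))
  i <- match(run_id, ids)
  if (is.na(i)) stop("no plex design for run '", run_id, "'")
  designs[[i]]
}

check_psm_columns <- function(psms, design) {
  need <- c("spectrum_id", "run_id", "peptide", "proteins", "score",
            intensity_cols(design$map$channel), sn_cols(design$map$channel))
  missing <- setdiff(need, names(psms))
  if (length(missing)) {
    stop("PSM table lacks columns required by the design of run '",
         design$run_id, "': ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Filter PSMs on the study's quantifiability rules
#'
#' Retains exactly those peptide-spectrum matches that satisfy all four
#' predicates: identification confidence `score >= min_score` (ProteinPilot
#' "unused" semantics; 1.3 corresponds to 95% confidence), peptide unique
#' to a single protein, peptide length `>= min_pep_len` residues, and sum
#' of the per-channel reporter signal-to-noise values strictly greater
#' than `sn_sum_threshold`. Input order is preserved; a tally of rejection
#' reasons (a PSM failing several predicates is counted under each) is
#' attached as attribute `"tally"`.
#'
#' @param psms PSM table: columns `spectrum_id`, `run_id`, `peptide`,
#'   `proteins` (protein ids, `;`-separated when shared), `score`, and
#'   per-channel `intensity_<ch>` / `sn_<ch>` columns.
#' @param designs A `plex_design` or list of them covering all runs in
#'   `psms`.
#' @param min_score Minimum identification score (default 1.3).
#' @param sn_sum_threshold Summed reporter S/N must strictly exceed this
#'   (default 9).
#' @param min_pep_len Minimum peptide length in residues (default 6).
#' @return The retained rows of `psms`, with attribute `"tally"`: named
#'   counts `n_input`, `low_score`, `shared_peptide`, `short_peptide`,
#'   `low_sn`, `n_retained`.
#' @export
filter_psms <- function(psms, designs = default_plex_designs(),
                        min_score = 1.3, sn_sum_threshold = 9,
                        min_pep_len = 6L) {
  stopifnot(min_score >= 0, sn_sum_threshold >= 0, min_pep_len >= 0)
  runs <- unique(psms$run_id)
  for (r in runs) check_psm_columns(psms, design_for_run(designs, r))
  d1 <- design_for_run(designs, runs[1L])
  for (r in runs[-1L]) {
    if (!setequal(design_for_run(designs, r)$map$channel, d1$map$channel)) {
      stop("runs use different channel sets; filter them separately")
    }
  }
  sn_sum <- rowSums(as.matrix(psms[, sn_cols(d1$map$channel)]))
  n_prot <- lengths(strsplit(as.character(psms$proteins), ";", fixed = TRUE))
  ok_score <- psms$score >= min_score
  ok_unique <- n_prot == 1L
  ok_len <- nchar(as.character(psms$peptide)) >= min_pep_len
  ok_sn <- sn_sum > sn_sum_threshold
  keep <- ok_score & ok_unique & ok_len & ok_sn
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tally") <- c(
    n_input = nrow(psms),
    low_score = sum(!ok_score),
    shared_peptide = sum(!ok_unique),
    short_peptide = sum(!ok_len),
    low_sn = sum(!ok_sn),
    n_retained = sum(keep)
  )
  out
}

#' Per-protein reporter-channel ratios against the control mean
#'
#' For each protein and run, reporter intensities are aggregated across
#' the protein's PSMs per channel (sum by default, median optionally); the
#' denominator is the arithmetic mean of the two control-channel
#' aggregates, and each channel's ratio is aggregate / denominator.
#' Per-peptide log2 ratios (each peptide's channel aggregate over the mean
#' of that peptide's own control aggregates) are retained for downstream
#' replicate-level testing; channels with zero intensity for a peptide are
#' excluded from the log-ratio lists and counted.
#'
#' @param psms A filtered PSM table (see [filter_psms()]); every retained
#'   PSM must map to exactly one protein.
#' @param designs A `plex_design` or list of them.
#' @param aggregate `"sum"` (default, intensity-weighted) or `"median"`.
#' @return An object of class `protein_quant`:
#'   \describe{
#'     \item{table}{data frame, one row per protein x run: `protein_id`,
#'       `run_id`, `n_spectra`, `n_peptides`, and `ratio_<ch>` columns}
#'     \item{pep_log2}{nested list `[[run]][[protein]][[channel]]` of
#'       per-peptide log2 ratios}
#'     \item{excluded}{data frame of proteins dropped because both control
#'       aggregates were zero}
#'     \item{n_zero_dropped}{count of zero-intensity peptide-channel
#'       entries excluded from log-ratio lists}
#'   }
#' @export
protein_channel_ratios <- function(psms, designs = default_plex_designs(),
                                   aggregate = c("sum", "median")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "sum") sum else median
  if (nrow(psms) == 0L) stop("no PSMs to quantify")
  if (any(grepl(";", psms$proteins, fixed = TRUE))) {
    stop("shared-peptide PSMs present; run filter_psms() first")
  }
  rows <- list()
  pep_log2 <- list()
  excluded <- list()
  n_zero_dropped <- 0L
  for (run in unique(psms$run_id)) {
    design <- design_for_run(designs, run)
    channels <- design$map$channel
    ctrl <- design$control_channels
    prun <- psms[psms$run_id == run, , drop = FALSE]
    imat <- as.matrix(prun[, intensity_cols(channels)])
    colnames(imat) <- channels
    pep_log2[[run]] <- list()
    for (prot in unique(prun$proteins)) {
      sel <- prun$proteins == prot
      sub <- imat[sel, , drop = FALSE]
      aggs <- apply(sub, 2L, agg_fun)
      denom <- mean(aggs[ctrl])
      if (denom == 0) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          protein_id = prot, run_id = run,
          reason = "both control aggregates zero", stringsAsFactors = FALSE)
        next
      }
      peptides <- unique(prun$peptide[sel])
      plist <- setNames(vector("list", length(channels)), channels)
      for (pep in peptides) {
        pa <- colSums(sub[prun$peptide[sel] == pep, , drop = FALSE])
        pdenom <- mean(pa[ctrl])
        if (pdenom == 0) {
          n_zero_dropped <- n_zero_dropped + length(channels)
          next
        }
        for (ch in channels) {
          if (pa[[ch]] > 0) {
            plist[[ch]] <- c(plist[[ch]], log2(pa[[ch]] / pdenom))
          } else {
            n_zero_dropped <- n_zero_dropped + 1L
          }
        }
      }
      pep_log2[[run]][[prot]] <- plist
      row <- data.frame(protein_id = prot, run_id = run,
                        n_spectra = sum(sel),
                        n_peptides = length(peptides),
                        stringsAsFactors = FALSE)
      for (ch in channels) row[[paste0("ratio_", ch)]] <- aggs[[ch]] / denom
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) stop("no quantifiable proteins (all excluded)")
  structure(list(
    table = do.call(rbind, rows),
    pep_log2 = pep_log2,
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(protein_id = character(0), run_id = character(0),
                 reason = character(0), stringsAsFactors = FALSE),
    n_zero_dropped = n_zero_dropped,
    designs = if (inherits(designs, "plex_design")) list(designs) else designs,
    aggregate = aggregate
  ), class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("Protein reporter quantification: %d protein x run rows (%s aggregation)\n",
              nrow(x$table), x$aggregate))
  if (nrow(x$excluded)) {
    cat(sprintf("  excluded (zero control signal): %d\n", nrow(x$excluded)))
  }
  invisible(x)
}

#' Concordance of the duplicate ambient-control channels
#'
#' For each protein x run, computes |log2(aggregate(control 1) /
#' aggregate(control 2))| and flags proteins whose control channels
#' disagree by more than `tol_log2`. A pre-analysis sanity check that the
#' two ambient controls behave as technical duplicates; it reports and
#' never drops data.
#'
#' @param quant A `protein_quant` object.
#' @param tol_log2 Flagging tolerance on the absolute log2 control ratio
#'   (default 1, i.e. a two-fold disagreement).
#' @return List with `table` (`protein_id`, `run_id`, `abs_log2`),
#'   `flagged` (rows exceeding `tol_log2`) and `fraction_flagged`.
#' @export
control_concordance <- function(quant, tol_log2 = 1) {
  stopifnot(inherits(quant, "protein_quant"), tol_log2 >= 0)
  tab <- quant$table
  out <- list()
  for (run in unique(tab$run_id)) {
    design <- design_for_run(quant$designs, run)
    ctrl <- design$control_channels
    sub <- tab[tab$run_id == run, , drop = FALSE]
    r1 <- sub[[paste0("ratio_", ctrl[1L])]]
    r2 <- sub[[paste0("ratio_", ctrl[2L])]]
    out[[run]] <- data.frame(protein_id = sub$protein_id, run_id = run,
                             abs_log2 = abs(log2(r1 / r2)),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  flagged <- res[is.finite(res$abs_log2) & res$abs_log2 > tol_log2, ,
                 drop = FALSE]
  list(table = res, flagged = flagged,
       fraction_flagged = nrow(flagged) / max(1L, nrow(res)))
}

#' Read / write PSM tables and quantification tables as TSV
#'
#' @param path File path.
#' @return `read_psm_table()` returns the PSM data frame;
#'   `write_psm_table()` and `write_quant_table()` return the path,
#'   invisibly.
#' @export
read_psm_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_psm_table
#' @param psms PSM data frame.
#' @export
write_psm_table <- function(psms, path) {
  write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_psm_table
#' @param quant A `protein_quant` object.
#' @export
write_quant_table <- function(quant, path) {
  stopifnot(inherits(quant, "protein_quant"))
  write.table(quant$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
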