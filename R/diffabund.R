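# Differential protein abundance: per-replicate tests on peptide-level
# log2 ratios, pooled across the biological tetraplicate with Fisher's
# combined probability, then fold-change and support gates and the
# between-treatment set partitions.

#' Fisher's combined probability
#'
#' Pools k independent p-values: chi2 = -2 * sum(ln p_i) on 2k degrees of
#' freedom; the combined p is the upper chi-square tail. A single p-value
#' is returned unchanged (the k = 1 identity).
#'
#' @param pvalues Numeric vector of p-values, each in (0, 1].
#' @return List with `chi2`, `df` and `p`.
#' @examples
#' fisher_combined(c(0.5, 0.5))
#' @export
fisher_combined <- function(pvalues) {
  if (length(pvalues) == 0L) stop("at least one p-value is required")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  chi2 <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Per-replicate tests of peptide-level log2 ratios
#'
#' For every protein x treatment x replicate channel, tests the protein's
#' peptide-level log2 ratios (treatment channel over the peptide's own
#' control mean) against zero. The default is a two-sided one-sample
#' t-test; a Wilcoxon signed-rank alternative is available. Degenerate
#' inputs never crash: identical ratios (zero variance) give p = 1 with
#' flag `"degenerate"`, a single ratio gives a descriptive mean with
#' flag `"untestable"` and no p-value.
#'
#' @param quant A `protein_quant` object ([protein_channel_ratios()]).
#' @param test `"t_one_sample"` (default) or `"wilcoxon"`.
#' @return Data frame: `protein_id`, `treatment`, `replicate`, `run_id`,
#'   `channel`, `n_peptides`, `mean_log2`, `pvalue`, `flag`.
#' @export
replicate_pvalues <- function(quant, test = c("t_one_sample", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(inherits(quant, "protein_quant"))
  rows <- list()
  for (run in names(quant$pep_log2)) {
    design <- design_for_run(quant$designs, run)
    map <- design$map
    noncontrol <- map[map$treatment != "control", , drop = FALSE]
    for (prot in names(quant$pep_log2[[run]])) {
      plist <- quant$pep_log2[[run]][[prot]]
      for (i in seq_len(nrow(noncontrol))) {
        ch <- noncontrol$channel[i]
        x <- plist[[ch]]
        n <- length(x)
        if (n == 0L) next
        flag <- "ok"
        if (n == 1L) {
          p <- NA_real_
          flag <- "untestable"
        } else if (isTRUE(all.equal(var(x), 0)) || all(x == x[1L])) {
          p <- 1
          flag <- "degenerate"
        } else if (test == "t_one_sample") {
          p <- t.test(x, mu = 0)$p.value
        } else {
          p <- suppressWarnings(wilcox.test(x, mu = 0, exact = n <= 25)$p.value)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = prot, treatment = noncontrol$treatment[i],
          replicate = noncontrol$replicate[i], run_id = run, channel = ch,
          n_peptides = n, mean_log2 = mean(x), pvalue = p, flag = flag,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    stop("no testable protein/replicate combinations")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Status of a fold change / p-value pair under the study's gates
#'
#' Strict inequalities exactly as stated: `up` if `fold_change > fc_up`
#' and `p < alpha`; `down` if `fold_change < fc_down` and `p < alpha`;
#' otherwise `ns`.
#'
#' @param fold_change Linear-scale fold change (treatment vs control).
#' @param p Combined probability.
#' @param alpha Significance gate (default 0.05).
#' @param fc_up,fc_down Fold-change gates (defaults 1.5 and 0.5).
#' @return Character vector over \{"up", "down", "ns"\}.
#' @export
call_status <- function(fold_change, p, alpha = 0.05, fc_up = 1.5,
                        fc_down = 0.5) {
  stopifnot(fc_down < 1, fc_up > 1)
  ifelse(p < alpha & fold_change > fc_up, "up",
         ifelse(p < alpha & fold_change < fc_down, "down", "ns"))
}

#' Differential-abundance calls per protein and treatment
#'
#' Pools the replicate-level tests of [replicate_pvalues()]: the fold
#' change is the geometric mean of the replicate ratios (mean in log2
#' space, then 2^.), the combined probability is Fisher's method over the
#' replicate p-values, and the status is assigned by [call_status()].
#' Support gates are eligibility filters applied before significance: a
#' protein must carry at least `min_peptides` peptides in each tested
#' replicate and have `min_replicates` testable replicates, otherwise it
#' is reported `ns` with reason `"insufficient_support"`.
#'
#' @param tests Data frame from [replicate_pvalues()].
#' @param alpha,fc_up,fc_down Gates as in [call_status()].
#' @param min_peptides Minimum peptides per replicate (default 3).
#' @param min_replicates Minimum testable replicates (default 4, the
#'   biological tetraplicate).
#' @return Data frame of calls: `protein_id`, `treatment`, `fold_change`,
#'   `combined_p`, `n_peptides` (minimum across replicates),
#'   `n_replicates`, `status`, `reason`.
#' @export
classify_calls <- function(tests, alpha = 0.05, fc_up = 1.5, fc_down = 0.5,
                           min_peptides = 3L, min_replicates = 4L) {
  stopifnot(fc_down < 1, fc_up > 1, alpha > 0, alpha < 1)
  key <- interaction(tests$protein_id, tests$treatment, drop = TRUE)
  rows <- lapply(split(tests, key), function(g) {
    ok <- !is.na(g$pvalue)
    n_rep <- sum(ok)
    n_pep <- min(g$n_peptides)
    fc <- 2^mean(g$mean_log2)
    if (n_pep < min_peptides || n_rep < min_replicates) {
      return(data.frame(
        protein_id = g$protein_id[1L], treatment = g$treatment[1L],
        fold_change = fc, combined_p = NA_real_, n_peptides = n_pep,
        n_replicates = n_rep, status = "ns",
        reason = "insufficient_support", stringsAsFactors = FALSE))
    }
    comb <- fisher_combined(g$pvalue[ok])
    data.frame(
      protein_id = g$protein_id[1L], treatment = g$treatment[1L],
      fold_change = fc, combined_p = comb$p, n_peptides = n_pep,
      n_replicates = n_rep,
      status = call_status(fc, comb$p, alpha, fc_up, fc_down),
      reason = "evaluated", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Venn-style partition of two treatments' differential calls
#'
#' @param callsA,callsB Call tables (one treatment each) with columns
#'   `protein_id` and `status`; `up`/`down` count as significant.
#' @return An object of class `set_partition`: per-treatment significant
#'   id sets, `shared`, `union`, and per-treatment uniquely-up /
#'   uniquely-down sets (significant in that treatment, not significant
#'   in the other), plus a `counts` named integer vector.
#' @export
partition_calls <- function(callsA, callsB) {
  for (calls in list(callsA, callsB)) {
    if (anyDuplicated(calls$protein_id)) {
      stop("duplicate protein ids within a treatment: ",
           paste(unique(calls$protein_id[duplicated(calls$protein_id)]),
                 collapse = ", "))
    }
  }
  sig <- function(calls) calls$protein_id[calls$status %in% c("up", "down")]
  dir <- function(calls, s) calls$protein_id[calls$status == s]
  A <- sig(callsA); B <- sig(callsB)
  shared <- intersect(A, B)
  res <- list(
    significant_a = A, significant_b = B,
    shared = shared,
    union = union(A, B),
    unique_up_a = setdiff(dir(callsA, "up"), B),
    unique_down_a = setdiff(dir(callsA, "down"), B),
    unique_up_b = setdiff(dir(callsB, "up"), A),
    unique_down_b = setdiff(dir(callsB, "down"), A)
  )
  res$counts <- vapply(res, length, integer(1))
  stopifnot(res$counts[["union"]] ==
              length(A) + length(B) - length(shared))
  structure(res, class = "set_partition")
}

#' @export
print.set_partition <- function(x, ...) {
  cat("Differential-call partition\n")
  print(x$counts)
  invisible(x)
}

#' Re-derive the study's headline counts from the packaged 61-protein table
#'
#' Applies the printed gates (combined p < 0.05; fold change > 1.5 or
#' < 0.5, all strict) to the packaged table of 61 differentially
#' concentrated proteins (fold change and p per treatment, brevetoxin and
#' live *K. brevis*, plus the Symbiodiniaceae flag), then partitions the
#' two treatments' significant sets.
#'
#' @param fixture The fixture table ([table1_fixture()] by default).
#' @param alpha,fc_up,fc_down Gates as in [call_status()].
#' @return List with `calls` (per-treatment status columns added),
#'   `partition` (a `set_partition`) and `counts`, a named list:
#'   `pbtx_significant`, `pbtx_up`, `pbtx_down`, `kb_significant`,
#'   `kb_up`, `kb_down`, `shared`, `union_total`, `kb_unique_up`,
#'   `kb_unique_down`, `pbtx_unique_up`, `pbtx_unique_down`,
#'   `symbiont_significant`.
#' @export
table1_reanalysis <- function(fixture = table1_fixture(), alpha = 0.05,
                              fc_up = 1.5, fc_down = 0.5) {
  fixture$pbtx_status <- call_status(fixture$pbtx_fc, fixture$pbtx_p,
                                     alpha, fc_up, fc_down)
  fixture$kb_status <- call_status(fixture$kb_fc, fixture$kb_p,
                                   alpha, fc_up, fc_down)
  callsA <- data.frame(protein_id = fixture$gene_id,
                       status = fixture$pbtx_status,
                       stringsAsFactors = FALSE)
  callsB <- data.frame(protein_id = fixture$gene_id,
                       status = fixture$kb_status,
                       stringsAsFactors = FALSE)
  part <- partition_calls(callsA, callsB)
  sym_ids <- fixture$gene_id[fixture$symbiont == 1]
  counts <- list(
    pbtx_significant = length(part$significant_a),
    pbtx_up = sum(fixture$pbtx_status == "up"),
    pbtx_down = sum(fixture$pbtx_status == "down"),
    kb_significant = length(part$significant_b),
    kb_up = sum(fixture$kb_status == "up"),
    kb_down = sum(fixture$kb_status == "down"),
    shared = length(part$shared),
    union_total = length(part$union),
    kb_unique_up = length(part$unique_up_b),
    kb_unique_down = length(part$unique_down_b),
    pbtx_unique_up = length(part$unique_up_a),
    pbtx_unique_down = length(part$unique_down_a),
    symbiont_significant = length(intersect(sym_ids, part$union))
  )
  list(calls = fixture, partition = part, counts = counts)
}
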