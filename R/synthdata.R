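# Seeded synthetic-data generators emulating the study design (2 runs x
# 8-plex, four treatments in biological tetraplicate, spiked fold changes,
# log-normal reporter noise), so the whole pipeline is testable without
# raw LC-MS/MS or field data.

#' Generate random transcript contigs
#'
#' Uniform-length nucleotide contigs with independent bases at a target GC
#' content (A and T share (1-gc), G and C share gc).
#'
#' @param n Number of contigs.
#' @param length_range Integer range of contig lengths (inclusive).
#' @param gc Target GC fraction in \[0, 1\].
#' @param seed Integer seed; generation is reproducible.
#' @param source Label for the transcriptome set.
#' @return A transcript record table ([transcript_records()]).
#' @export
gen_transcripts <- function(n, length_range = c(300L, 900L), gc = 0.45,
                            seed = 1L, source = "synthetic") {
  stopifnot(n >= 1L, length(length_range) == 2L,
            length_range[1L] >= 1L, length_range[1L] <= length_range[2L])
  if (!is.finite(gc) || gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  lens <- sample(seq(length_range[1L], length_range[2L]), n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(probs), L, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  transcript_records(sprintf("tig%05d", seq_len(n)), seqs, source = source)
}

#' Specification of a synthetic spike-in experiment
#'
#' Defaults encode the emulated study conditions: 500 proteins, 10% of
#' proteins spiked per toxin treatment at |log2 FC| = log2(1.5) with
#' random sign (none for the carrier control), 1-12 peptides per protein,
#' 20% peptide-level measurement CV, 0.1 log2-sd biological replicate
#' noise, 5% of peptides shared between two proteins, log-normal baseline
#' intensities around 2e4 with a run noise floor of 200 intensity units
#' (so typical summed reporter S/N passes the > 9 gate while a weak tail
#' does not).
#'
#' @param n_proteins Number of simulated proteins.
#' @param fraction_spiked Named fractions of spiked proteins per
#'   non-control treatment.
#' @param log2_effect Magnitude of the spiked log2 fold change (sign is
#'   drawn at random per protein x treatment).
#' @param peptide_range Integer range of peptides per protein.
#' @param peptide_cv Linear-scale coefficient of variation of the
#'   multiplicative measurement noise.
#' @param biorep_sd Log2-scale standard deviation of the biological
#'   replicate noise.
#' @param shared_peptide_fraction Fraction of peptides assigned to two
#'   proteins (exercises the uniqueness filter).
#' @param intensity_meanlog,intensity_sdlog Parameters of the log-normal
#'   baseline intensity (natural-log scale).
#' @param noise_floor Run noise floor; S/N = intensity / noise_floor.
#' @param seed Integer seed.
#' @return A list of class `spike_spec`.
#' @export
spike_spec <- function(n_proteins = 500L,
                       fraction_spiked = c(MeOH = 0, PbTx = 0.1,
                                           Kbrevis = 0.1),
                       log2_effect = log2(1.5),
                       peptide_range = c(1L, 12L),
                       peptide_cv = 0.20,
                       biorep_sd = 0.1,
                       shared_peptide_fraction = 0.05,
                       intensity_meanlog = log(2e4),
                       intensity_sdlog = 0.8,
                       noise_floor = 200,
                       seed = 1L) {
  stopifnot(n_proteins >= 1L, all(fraction_spiked >= 0),
            all(fraction_spiked <= 1), peptide_cv >= 0, biorep_sd >= 0,
            shared_peptide_fraction >= 0, shared_peptide_fraction <= 1,
            noise_floor > 0)
  structure(list(
    n_proteins = as.integer(n_proteins),
    fraction_spiked = fraction_spiked,
    log2_effect = log2_effect,
    peptide_range = as.integer(peptide_range),
    peptide_cv = peptide_cv,
    biorep_sd = biorep_sd,
    shared_peptide_fraction = shared_peptide_fraction,
    intensity_meanlog = intensity_meanlog,
    intensity_sdlog = intensity_sdlog,
    noise_floor = noise_floor,
    seed = as.integer(seed)
  ), class = "spike_spec")
}

#' Simulate a PSM-level spike-in experiment
#'
#' Draws, per protein, a log-normal baseline intensity and 1-12 peptides
#' with log-normal ionization offsets; per channel, the reporter intensity
#' is baseline x peptide offset x treatment fold change (spiked proteins
#' only) x biological replicate noise x multiplicative measurement noise
#' at the stated CV. S/N is intensity over the run noise floor. A stated
#' fraction of peptides is assigned to two proteins; identification
#' scores are drawn so that a minority fall below the 1.3 confidence
#' cutoff.
#'
#' @param spec A [spike_spec()].
#' @param designs Plex designs for the runs ([default_plex_designs()]).
#' @return List: `psms` (PSM table across runs), `truth` (data frame
#'   `protein_id`, `treatment`, `true_log2fc`, `true_status`),
#'   `designs`.
#' @export
gen_psm_experiment <- function(spec = spike_spec(),
                               designs = default_plex_designs()) {
  stopifnot(inherits(spec, "spike_spec"))
  if (inherits(designs, "plex_design")) designs <- list(designs)
  set.seed(spec$seed)
  treatments <- setdiff(unique(designs[[1L]]$map$treatment), "control")
  prot_ids <- sprintf("prot%04d", seq_len(spec$n_proteins))
  # spiked effects per protein x treatment (log2; 0 when unspiked)
  effects <- matrix(0, nrow = spec$n_proteins, ncol = length(treatments),
                    dimnames = list(prot_ids, treatments))
  for (tr in treatments) {
    frac <- if (tr %in% names(spec$fraction_spiked)) {
      spec$fraction_spiked[[tr]]
    } else 0
    if (frac == 0) next
    n_sp <- round(frac * spec$n_proteins)
    if (n_sp == 0L) next
    idx <- sample(spec$n_proteins, n_sp)
    effects[idx, tr] <- sample(c(-1, 1), n_sp, replace = TRUE) *
      spec$log2_effect
  }
  baseline <- rlnorm(spec$n_proteins, spec$intensity_meanlog,
                     spec$intensity_sdlog)
  n_pep <- sample(seq(spec$peptide_range[1L], spec$peptide_range[2L]),
                  spec$n_proteins, replace = TRUE)
  meas_sdlog <- if (spec$peptide_cv > 0) {
    sqrt(log(1 + spec$peptide_cv^2))
  } else 0
  # biological replicate noise: one multiplicative factor per protein x
  # treatment-or-control x replicate id (shared by a replicate's channel
  # across peptides, as biology is)
  all_reps <- unique(do.call(rbind, lapply(designs, function(d) {
    d$map[, c("treatment", "replicate")]
  })))
  bio <- array(rnorm(spec$n_proteins * nrow(all_reps), 0, spec$biorep_sd),
               dim = c(spec$n_proteins, nrow(all_reps)))
  rep_key <- paste(all_reps$treatment, all_reps$replicate)
  # peptide identity, ionization offset and protein assignment are
  # properties of the peptide, drawn once and reused in every run
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pep_counter <- 0L
  peptides <- vector("list", spec$n_proteins)
  for (i in seq_len(spec$n_proteins)) {
    np <- n_pep[i]
    tag <- vapply(pep_counter + seq_len(np), function(m) {
      # base-20 encoding of the global peptide index guarantees
      # distinct sequences
      digs <- integer(5)
      for (q in 5:1) { digs[q] <- m %% 20L; m <- m %/% 20L }
      paste(aa[digs + 1L], collapse = "")
    }, character(1))
    pep_counter <- pep_counter + np
    # tail length 0 yields the occasional 5-residue peptide, exercising
    # the minimum-length filter
    tail_len <- sample(0:12, np, replace = TRUE)
    seqs <- vapply(seq_len(np), function(j) {
      paste0(tag[j], paste(sample(aa, tail_len[j], replace = TRUE),
                           collapse = ""))
    }, character(1))
    shared <- runif(np) < spec$shared_peptide_fraction
    prot_field <- rep(prot_ids[i], np)
    if (any(shared) && spec$n_proteins > 1L) {
      others <- sample(setdiff(seq_len(spec$n_proteins), i), sum(shared),
                       replace = TRUE)
      prot_field[shared] <- paste(prot_ids[i], prot_ids[others], sep = ";")
    }
    peptides[[i]] <- data.frame(
      peptide = seqs, proteins = prot_field,
      offset = rlnorm(np, 0, 0.7),
      n_spectra = 1L + rpois(np, 0.3),
      stringsAsFactors = FALSE)
  }
  psm_rows <- list()
  for (d in designs) {
    channels <- d$map$channel
    bio_col <- match(paste(d$map$treatment, d$map$replicate), rep_key)
    for (i in seq_len(spec$n_proteins)) {
      spike_ch <- vapply(seq_along(channels), function(k) {
        tr <- d$map$treatment[k]
        if (tr %in% treatments) effects[i, tr] else 0
      }, numeric(1))
      pp <- peptides[[i]]
      for (j in seq_len(nrow(pp))) {
        mu <- baseline[i] * pp$offset[j]
        expected <- mu * 2^(spike_ch + bio[i, bio_col])
        for (sc in seq_len(pp$n_spectra[j])) {
          intens <- expected * exp(rnorm(length(channels), 0, meas_sdlog))
          sn <- intens / spec$noise_floor
          row <- data.frame(
            spectrum_id = sprintf("%s_%s_p%d_sc%d", d$run_id,
                                  prot_ids[i], j, sc),
            run_id = d$run_id,
            peptide = pp$peptide[j],
            proteins = pp$proteins[j],
            score = stats::rexp(1, rate = 1 / 5),
            stringsAsFactors = FALSE)
          for (k in seq_along(channels)) {
            row[[paste0("intensity_", channels[k])]] <- intens[k]
            row[[paste0("sn_", channels[k])]] <- sn[k]
          }
          psm_rows[[length(psm_rows) + 1L]] <- row
        }
      }
    }
  }
  truth <- do.call(rbind, lapply(treatments, function(tr) {
    data.frame(protein_id = prot_ids, treatment = tr,
               true_log2fc = effects[, tr],
               true_status = ifelse(effects[, tr] > 0, "up",
                                    ifelse(effects[, tr] < 0, "down",
                                           "ns")),
               stringsAsFactors = FALSE)
  }))
  list(psms = do.call(rbind, psm_rows), truth = truth, designs = designs)
}

#' Simulate choice-flume trials
#'
#' Each larva completes two 2-minute periods with the cue side swapped;
#' each of the 24 observations per period is on the cue side with
#' probability `p_cue`, independently.
#'
#' @param n_larvae Number of larvae.
#' @param p_cue Probability of being observed on the cue side.
#' @param seed Integer seed.
#' @param cue Label of the cue water source.
#' @return Data frame of observations: `larva_id`, `cue`, `period`,
#'   `cue_side`, `position`.
#' @export
gen_flume <- function(n_larvae = 10L, p_cue = 0.5, seed = 1L,
                      cue = "Kbrevis") {
  stopifnot(n_larvae >= 1L, p_cue >= 0, p_cue <= 1)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_larvae)) {
    first_side <- sample(c("left", "right"), 1L)
    for (p in 1:2) {
      cue_side <- if (p == 1L) first_side else
        setdiff(c("left", "right"), first_side)
      on_cue <- runif(24L) < p_cue
      other <- setdiff(c("left", "right"), cue_side)
      rows[[length(rows) + 1L]] <- data.frame(
        larva_id = sprintf("larva%03d", i), cue = cue, period = p,
        cue_side = cue_side,
        position = ifelse(on_cue, cue_side, other),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a treatment x time phenotype table
#'
#' Gaussian draws around stated cell means; when `logit = TRUE` the draws
#' are made on the logit scale and back-transformed (for proportion
#' responses), otherwise responses are optionally clipped to \[0, 1\].
#'
#' @param cell_means Data frame with columns `treatment`, `time`, `mean`.
#' @param sd Within-cell standard deviation (response scale, or logit
#'   scale when `logit = TRUE`).
#' @param n Replicates per cell (default 5, as in the emulated assays).
#' @param seed Integer seed.
#' @param logit Draw on the logit scale.
#' @param clip Clip responses to \[0, 1\].
#' @return Data frame: `unit_id`, `treatment`, `time`, `response`.
#' @export
gen_phenotypes <- function(cell_means, sd = 0.05, n = 5L, seed = 1L,
                           logit = FALSE, clip = TRUE) {
  stopifnot(is.data.frame(cell_means),
            all(c("treatment", "time", "mean") %in% names(cell_means)),
            sd >= 0, n >= 1L)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(cell_means)), function(i) {
    m <- cell_means$mean[i]
    if (logit) {
      stopifnot(m > 0, m < 1)
      y <- 1 / (1 + exp(-(log(m / (1 - m)) + rnorm(n, 0, sd))))
    } else {
      y <- rnorm(n, m, sd)
      if (clip) y <- pmin(1, pmax(0, y))
    }
    data.frame(
      unit_id = sprintf("%s_%s_r%d", cell_means$treatment[i],
                        cell_means$time[i], seq_len(n)),
      treatment = cell_means$treatment[i], time = cell_means$time[i],
      response = y, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

table1_md5 <- "9ed8363481239cf2b291b083d048226a"

#' The packaged 61-protein differential-abundance table
#'
#' Loads the packaged table of the 61 proteins called differentially
#' concentrated in at least one toxin treatment: per protein, the printed
#' fold change and combined probability for the brevetoxin (`pbtx_*`) and
#' live *K. brevis* (`kb_*`) treatments, plus a flag for the three
#' Symbiodiniaceae-derived entries. Integrity is verified at load time
#' (row count and md5 checksum).
#'
#' @return Data frame with columns `gene_id`, `accession`, `description`,
#'   `pbtx_fc`, `pbtx_p`, `kb_fc`, `kb_p`, `symbiont`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_porites.tsv",
                      package = "coralprot", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, table1_md5)) {
    stop("fixture integrity failure: md5 ", md5, " != ", table1_md5)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) != 61L) {
    stop("fixture integrity failure: ", nrow(tab), " rows, expected 61")
  }
  tab
}
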