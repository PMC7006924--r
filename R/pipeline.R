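# Pipeline orchestration: run the simulate -> quantify -> differential
# stages (plus the packaged-table reanalysis) from a validated config,
# writing diffable TSV artifacts and a reproducibility manifest.

pipeline_defaults <- function() {
  list(
    stages = c("simulate", "quantify", "differential"),
    outdir = ".",
    seed = 1L,
    min_score = 1.3,
    sn_sum_threshold = 9,
    min_pep_len = 6L,
    aggregate = "sum",
    test = "t_one_sample",
    alpha = 0.05,
    fc_up = 1.5,
    fc_down = 0.5,
    min_peptides = 3L,
    min_replicates = 4L,
    n_proteins = 500L,
    psms = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys. `config` may be a named list
#' or the path of a YAML file.
#'
#' @param config Named list or YAML file path.
#' @return The validated, completed config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  known_stages <- c("simulate", "quantify", "differential", "table1")
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$fc_down < 1, cfg$fc_up > 1)
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order (`simulate` generates a seeded
#' spike-in PSM experiment; `quantify` filters PSMs and computes reporter
#' ratios; `differential` runs the replicate tests, Fisher combination and
#' gates; `table1` re-derives the packaged-table counts). All artifacts
#' are plain TSV; a JSON manifest records parameters, artifact checksums
#' and the package version. Rerunning with the same config reproduces the
#' artifacts byte for byte.
#'
#' @param config Named list or YAML path (see [pipeline_config()]).
#' @return List with the stage results (`truth`, `quant`, `calls`,
#'   `table1`, as applicable) and `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  designs <- default_plex_designs()
  artifacts <- character(0)
  out <- list()
  psms <- NULL
  if (!is.null(cfg$psms)) psms <- read_psm_table(cfg$psms)
  for (stage in cfg$stages) {
    if (stage == "simulate") {
      sim <- gen_psm_experiment(
        spike_spec(n_proteins = cfg$n_proteins, seed = cfg$seed), designs)
      psms <- sim$psms
      out$truth <- sim$truth
      p1 <- file.path(cfg$outdir, "psms.tsv")
      p2 <- file.path(cfg$outdir, "truth.tsv")
      write_psm_table(round_numeric(psms), p1)
      write.table(sim$truth, p2, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      artifacts <- c(artifacts, p1, p2)
    } else if (stage == "quantify") {
      if (is.null(psms)) {
        stop("stage 'quantify' failed: no PSM table (simulate first or ",
             "set config$psms)")
      }
      kept <- filter_psms(psms, designs, min_score = cfg$min_score,
                          sn_sum_threshold = cfg$sn_sum_threshold,
                          min_pep_len = cfg$min_pep_len)
      out$filter_tally <- attr(kept, "tally")
      out$quant <- protein_channel_ratios(kept, designs,
                                          aggregate = cfg$aggregate)
      p <- file.path(cfg$outdir, "quant.tsv")
      write_quant_table(round_quant(out$quant), p)
      artifacts <- c(artifacts, p)
    } else if (stage == "differential") {
      if (is.null(out$quant)) {
        stop("stage 'differential' failed: no quantification ",
             "(run 'quantify' first)")
      }
      tests <- replicate_pvalues(out$quant, test = cfg$test)
      out$calls <- classify_calls(tests, alpha = cfg$alpha,
                                  fc_up = cfg$fc_up, fc_down = cfg$fc_down,
                                  min_peptides = cfg$min_peptides,
                                  min_replicates = cfg$min_replicates)
      p <- file.path(cfg$outdir, "calls.tsv")
      write.table(round_numeric(out$calls), p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      artifacts <- c(artifacts, p)
    } else if (stage == "table1") {
      out$table1 <- table1_reanalysis(alpha = cfg$alpha, fc_up = cfg$fc_up,
                                      fc_down = cfg$fc_down)
      p <- file.path(cfg$outdir, "table1_counts.tsv")
      counts <- out$table1$counts
      write.table(data.frame(quantity = names(counts),
                             count = unlist(counts)),
                  p, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts <- c(artifacts, p)
    }
  }
  manifest <- list(
    package = "coralprot",
    version = as.character(packageVersion("coralprot")),
    config = cfg[setdiff(names(cfg), "psms")],
    input_psms = if (is.null(cfg$psms)) NULL else
      list(path = cfg$psms, md5 = unname(tools::md5sum(cfg$psms))),
    artifacts = lapply(artifacts, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  mpath <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  out$manifest <- manifest
  out
}

# fixed-precision rounding so TSV artifacts are byte-stable across
# platforms' printf idiosyncrasies
round_numeric <- function(df, digits = 6L) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  df
}

round_quant <- function(quant, digits = 6L) {
  quant$table <- round_numeric(quant$table, digits)
  quant
}
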