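# PSM filtering on the quantifiability rules and control-normalised
# reporter ratios.

channels <- itraq8_channels

make_psm <- function(spectrum_id, peptide = "PEPTIDEK",
                     proteins = "protA", score = 5, run_id = "run1",
                     intensity = rep(100, 8), sn = rep(10, 8)) {
  row <- data.frame(spectrum_id = spectrum_id, run_id = run_id,
                    peptide = peptide, proteins = proteins, score = score,
                    stringsAsFactors = FALSE)
  for (k in seq_along(channels)) {
    row[[paste0("intensity_", channels[k])]] <- intensity[k]
    row[[paste0("sn_", channels[k])]] <- sn[k]
  }
  row
}

test_that("each quantifiability predicate rejects on its own", {
  psms <- rbind(
    make_psm("ok"),
    make_psm("sum8", sn = rep(1, 8)),           # S/N sum 8, not > 9
    make_psm("sum10", sn = rep(10, 8) / 8),     # S/N sum exactly 10
    make_psm("shared", proteins = "protA;protB"),
    make_psm("lowscore", score = 1.2),
    make_psm("edge_score", score = 1.3),        # inclusive cutoff kept
    make_psm("short", peptide = "PEPK"))
  kept <- filter_psms(psms)
  expect_identical(kept$spectrum_id, c("ok", "sum10", "edge_score"))
  tally <- attr(kept, "tally")
  expect_identical(unname(tally["n_input"]), 7L)
  expect_identical(unname(tally["low_sn"]), 1L)
  expect_identical(unname(tally["shared_peptide"]), 1L)
  expect_identical(unname(tally["low_score"]), 1L)
  expect_identical(unname(tally["short_peptide"]), 1L)
  # order preserved and filtering idempotent
  expect_identical(filter_psms(kept)$spectrum_id, kept$spectrum_id)
})

test_that("a mixed batch matches the brute-force four-predicate oracle", {
  set.seed(20)
  psms <- do.call(rbind, lapply(1:20, function(i) {
    make_psm(paste0("s", i),
             peptide = paste(sample(LETTERS[1:20], sample(4:12, 1),
                                    replace = TRUE), collapse = ""),
             proteins = if (runif(1) < 0.3) "pA;pB" else "pA",
             score = runif(1, 0, 4),
             sn = runif(8, 0, 3))
  }))
  kept <- filter_psms(psms)
  keep_oracle <- oracle_filter_psms(psms, paste0("sn_", channels),
                                    1.3, 9, 6)
  expect_identical(kept$spectrum_id, psms$spectrum_id[keep_oracle])
})

test_that("channel ratios normalise to the mean of the two controls", {
  intens <- rep(50, 8)
  names(intens) <- channels
  intens[c("113", "117")] <- 100
  intens["116"] <- 200
  psms <- make_psm("s1", intensity = unname(intens))
  q <- protein_channel_ratios(filter_psms(psms),
                              default_plex_designs()$run1)
  expect_equal(q$table$ratio_116, 2.0)
  expect_equal(q$table$ratio_113, 1.0)
  expect_equal(q$table$ratio_117, 1.0)
  expect_equal(q$table$ratio_114, 0.5)
})

test_that("ratios are invariant under global scaling and equivariant per channel", {
  set.seed(31)
  psms <- do.call(rbind, lapply(1:6, function(i) {
    make_psm(paste0("s", i), peptide = paste0("PEPTIDE", LETTERS[i]),
             proteins = sample(c("pA", "pB"), 1),
             intensity = runif(8, 50, 500))
  }))
  d <- default_plex_designs()$run1
  q1 <- protein_channel_ratios(psms, d)
  scaled <- psms
  icols <- paste0("intensity_", channels)
  scaled[icols] <- scaled[icols] * 7
  q2 <- protein_channel_ratios(scaled, d)
  rcols <- paste0("ratio_", channels)
  expect_equal(q2$table[rcols], q1$table[rcols], tolerance = 1e-12)
  # multiplying one non-control channel by c scales its ratio by c
  scaled2 <- psms
  scaled2[["intensity_115"]] <- scaled2[["intensity_115"]] * 3
  q3 <- protein_channel_ratios(scaled2, d)
  expect_equal(q3$table$ratio_115, 3 * q1$table$ratio_115,
               tolerance = 1e-12)
  expect_equal(q3$table$ratio_114, q1$table$ratio_114, tolerance = 1e-12)
})

test_that("aggregates and ratios match a hand-computed spreadsheet oracle", {
  # three PSMs, two peptides, one protein; sums worked out by hand
  i1 <- c(100, 50, 80, 200, 120, 60, 90, 110)
  i2 <- c(10, 20, 30, 40, 30, 20, 10, 40)
  i3 <- c(200, 100, 100, 100, 180, 80, 120, 90)
  psms <- rbind(make_psm("a", peptide = "PEPTIDEA", intensity = i1),
                make_psm("b", peptide = "PEPTIDEA", intensity = i2),
                make_psm("c", peptide = "PEPTIDEB", intensity = i3))
  q <- protein_channel_ratios(psms, default_plex_designs()$run1)
  agg <- i1 + i2 + i3
  denom <- mean(c(agg[1], agg[5]))  # channels 113 and 117
  expect_equal(unlist(q$table[paste0("ratio_", channels)],
                      use.names = FALSE), agg / denom)
  expect_identical(q$table$n_spectra, 3L)
  expect_identical(q$table$n_peptides, 2L)
  # peptide-level log2 ratios for peptide A, channel 114:
  pepA <- i1 + i2
  expect_equal(
    q$pep_log2$run1$protA[["114"]][1],
    log2(pepA[2] / mean(c(pepA[1], pepA[5]))))
  # control channels' own ratios average to 1 by construction
  expect_equal((q$table$ratio_113 + q$table$ratio_117) / 2, 1)
})

test_that("zero control signal excludes with a reason, not silently", {
  z <- rep(100, 8); z[c(1, 5)] <- 0
  psms <- rbind(make_psm("s1", proteins = "pZ", intensity = z),
                make_psm("s2", proteins = "pA"))
  q <- protein_channel_ratios(psms, default_plex_designs()$run1)
  expect_identical(q$excluded$protein_id, "pZ")
  expect_match(q$excluded$reason, "control")
  expect_identical(q$table$protein_id, "pA")
})

test_that("control concordance flags two-fold control disagreement", {
  even <- make_psm("s1", proteins = "pEven")
  skew <- rep(100, 8); skew[1] <- 400  # channel 113 = 4 x channel 117
  psms <- rbind(even, make_psm("s2", proteins = "pSkew",
                               intensity = skew))
  q <- protein_channel_ratios(psms, default_plex_designs()$run1)
  cc <- control_concordance(q, tol_log2 = 1)
  expect_identical(cc$flagged$protein_id, "pSkew")
  expect_equal(cc$table$abs_log2[cc$table$protein_id == "pEven"], 0)
  expect_equal(cc$fraction_flagged, 0.5)
  # random log-normal controls: flag fraction equals the oracle count
  set.seed(77)
  n <- 40
  psms2 <- do.call(rbind, lapply(seq_len(n), function(i) {
    intens <- rep(100, 8)
    intens[c(1, 5)] <- rlnorm(2, log(100), 0.6)
    make_psm(paste0("r", i), proteins = paste0("p", i),
             intensity = intens)
  }))
  q2 <- protein_channel_ratios(psms2, default_plex_designs()$run1)
  cc2 <- control_concordance(q2, tol_log2 = 1)
  ic <- paste0("intensity_", c("113", "117"))
  manual <- abs(log2(psms2[[ic[1]]] / psms2[[ic[2]]]))
  expect_equal(nrow(cc2$flagged), sum(manual > 1))
})

test_that("PSM tables round-trip through TSV", {
  psms <- rbind(make_psm("s1"), make_psm("s2", proteins = "pA;pB"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, path)
  back <- read_psm_table(path)
  expect_equal(back$score, psms$score)
  expect_identical(back$proteins, psms$proteins)
  expect_equal(back[[paste0("intensity_", channels[1])]],
               psms[[paste0("intensity_", channels[1])]])
})
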