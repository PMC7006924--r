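# Fisher's combined probability, replicate-level tests, the fold-change /
# support gates and the between-treatment set partitions.

test_that("Fisher combination satisfies its closed-form identities", {
  r <- fisher_combined(c(1, 1))
  expect_equal(r$chi2, 0)
  expect_identical(r$df, 4L)
  expect_equal(r$p, 1)
  # a single p-value is returned unchanged
  expect_equal(fisher_combined(0.05)$p, 0.05)
  # chi-square survival on 4 df has closed form exp(-x/2) * (1 + x/2)
  r2 <- fisher_combined(c(0.5, 0.5))
  expect_equal(r2$chi2, -4 * log(0.5), tolerance = 1e-10)
  expect_equal(r2$chi2, 2.7726, tolerance = 1e-4)
  expect_equal(r2$p, exp(-r2$chi2 / 2) * (1 + r2$chi2 / 2),
               tolerance = 1e-12)
  expect_error(fisher_combined(numeric(0)), "at least one")
  expect_error(fisher_combined(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("combining k copies of a small p0 is non-increasing in k", {
  # accumulation of same-side evidence: holds whenever each copy's
  # chi-square contribution -2 ln p0 exceeds its 2-df expectation (for
  # weak p0 near 1 the combined p rises instead, e.g. two 0.5s -> 0.597)
  for (p0 in c(0.01, 0.05, 0.1, 0.2)) {
    ps <- vapply(1:8, function(k) fisher_combined(rep(p0, k))$p,
                 numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
  # k = 1 identity bound: adding a p < 1 never worsens past the identity
  expect_lte(fisher_combined(c(0.04, 0.99))$p, 1)
})

# a protein_quant with hand-set peptide log2 ratios on one run
mock_quant <- function(pep_log2_by_channel, protein = "pA") {
  d <- default_plex_designs()$run1
  q <- structure(list(
    table = data.frame(protein_id = protein, run_id = "run1",
                       n_spectra = 6L, n_peptides = 3L,
                       stringsAsFactors = FALSE),
    pep_log2 = list(run1 = setNames(list(pep_log2_by_channel), protein)),
    excluded = data.frame(), n_zero_dropped = 0L,
    designs = list(d), aggregate = "sum"), class = "protein_quant")
  q
}

test_that("replicate tests handle degenerate peptide ratio sets", {
  zeros <- setNames(lapply(itraq8_channels, function(ch) c(0, 0, 0)),
                    itraq8_channels)
  tests <- replicate_pvalues(mock_quant(zeros))
  expect_true(all(tests$pvalue == 1))
  expect_true(all(tests$flag == "degenerate"))
  # symmetric +/- pair: mean 0, t = 0, p = 1
  sym <- setNames(lapply(itraq8_channels, function(ch) c(0.3, -0.3)),
                  itraq8_channels)
  t2 <- replicate_pvalues(mock_quant(sym))
  expect_true(all(abs(t2$mean_log2) < 1e-12))
  expect_true(all(abs(t2$pvalue - 1) < 1e-12))
  # single ratio: untestable, descriptive mean retained
  one <- setNames(lapply(itraq8_channels, function(ch) 0.4),
                  itraq8_channels)
  t3 <- replicate_pvalues(mock_quant(one))
  expect_true(all(is.na(t3$pvalue)))
  expect_true(all(t3$flag == "untestable"))
  expect_true(all(t3$mean_log2 == 0.4))
})

test_that("replicate p-values equal an independently coded t-test", {
  set.seed(12)
  x <- rnorm(6, 0.5, 0.3)
  ratios <- setNames(lapply(itraq8_channels, function(ch) x),
                     itraq8_channels)
  tests <- replicate_pvalues(mock_quant(ratios))
  n <- length(x)
  tstat <- mean(x) / (sd(x) / sqrt(n))
  p_manual <- 2 * pt(-abs(tstat), df = n - 1)
  expect_equal(tests$pvalue[1], p_manual, tolerance = 1e-12)
  # rank-based alternative agrees with the signed-rank oracle
  t2 <- replicate_pvalues(mock_quant(ratios), test = "wilcoxon")
  expect_equal(t2$pvalue[1],
               wilcox.test(x, mu = 0, exact = TRUE)$p.value)
})

test_that("printed fold change / p pairs classify as the study reports", {
  # cases taken from the packaged 61-protein table
  expect_identical(call_status(11.32, 0.0041), "up")
  expect_identical(call_status(1.29, 0.0016), "ns")  # p significant, FC inside (0.5, 1.5)
  expect_identical(call_status(0.18, 0.0322), "down")
  # strictness at the gates themselves
  expect_identical(call_status(1.5, 0.01), "ns")
  expect_identical(call_status(0.5, 0.01), "ns")
  expect_identical(call_status(2.0, 0.05), "ns")
})

test_that("support gates precede significance in classification", {
  tests <- data.frame(
    protein_id = "pA", treatment = "Kbrevis",
    replicate = as.character(1:4), run_id = rep(c("run1", "run2"), 2),
    channel = c("116", "121", "116", "121"),
    n_peptides = c(5L, 4L, 3L, 3L),
    mean_log2 = c(1.1, 0.9, 1.0, 1.05),
    pvalue = c(0.01, 0.02, 0.03, 0.01), flag = "ok",
    stringsAsFactors = FALSE)
  calls <- classify_calls(tests)
  expect_identical(calls$status, "up")
  expect_equal(calls$fold_change, 2^mean(c(1.1, 0.9, 1.0, 1.05)))
  expect_equal(calls$combined_p,
               fisher_combined(c(0.01, 0.02, 0.03, 0.01))$p)
  # too few peptides in one replicate -> not evaluable
  tests2 <- tests; tests2$n_peptides[3] <- 2L
  calls2 <- classify_calls(tests2)
  expect_identical(calls2$status, "ns")
  expect_identical(calls2$reason, "insufficient_support")
  # a missing replicate fails the tetraplicate requirement
  tests3 <- tests[1:3, ]
  expect_identical(classify_calls(tests3)$status, "ns")
})

test_that("set partitions obey the inclusion-exclusion identity", {
  mk <- function(ids, status) data.frame(protein_id = ids, status = status,
                                         stringsAsFactors = FALSE)
  # disjoint significant sets share nothing
  part <- partition_calls(mk(c("a", "b"), c("up", "down")),
                          mk(c("c", "d"), c("up", "up")))
  expect_identical(part$counts[["shared"]], 0L)
  expect_identical(part$counts[["union"]], 4L)
  # identical sets: union equals either set
  part2 <- partition_calls(mk(c("a", "b"), c("up", "down")),
                           mk(c("a", "b"), c("up", "down")))
  expect_identical(part2$counts[["union"]], 2L)
  expect_identical(part2$counts[["shared"]], 2L)
  expect_error(
    partition_calls(mk(c("a", "a"), c("up", "up")), mk("b", "up")),
    "duplicate")
  # randomised cases against direct set algebra
  set.seed(9)
  for (i in 1:20) {
    ids <- paste0("p", 1:30)
    a <- mk(ids, sample(c("up", "down", "ns"), 30, replace = TRUE))
    b <- mk(ids, sample(c("up", "down", "ns"), 30, replace = TRUE))
    part <- partition_calls(a, b)
    A <- ids[a$status != "ns"]; B <- ids[b$status != "ns"]
    expect_identical(part$counts[["union"]],
                     length(A) + length(B) - length(intersect(A, B)))
    expect_identical(sort(part$shared), sort(intersect(A, B)))
    expect_identical(sort(part$unique_up_a),
                     sort(setdiff(ids[a$status == "up"], B)))
    expect_length(intersect(part$shared, part$unique_down_b), 0)
  }
})

test_that("the packaged table yields the study's partition counts", {
  res <- table1_reanalysis()
  expect_identical(res$counts$pbtx_significant, 15L)
  expect_identical(res$counts$kb_significant, 52L)
  expect_identical(res$counts$shared, 6L)
  expect_identical(res$counts$union_total, 61L)
  # the six shared proteins are the ones the study names
  expect_setequal(res$partition$shared,
                  c("Cluster30", "Cluster78396", "Cluster153015",
                    "Cluster97665", "Cluster78285", "Cluster45626"))
})
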