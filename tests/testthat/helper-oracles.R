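# Independent brute-force oracles, deliberately written without reusing
# any package internals: a plain codon-table translator, predicate-by-
# predicate PSM filtering, and small-sample permutation enumerations for
# the KS and U statistics.

oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  # build explicitly, codon by codon
  tab <- character(0)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    tab[paste0(b1, b2, b3)] <- aas[k]
  }
  tab
})

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]),
        collapse = "")
}

oracle_translate_frame <- function(seq, offset) {
  n_codon <- (nchar(seq) - offset + 1) %/% 3
  aa <- character(0)
  for (i in seq_len(n_codon)) {
    codon <- substr(seq, offset + 3 * (i - 1), offset + 3 * i - 1)
    aa[i] <- if (grepl("N", codon)) "X" else oracle_codon_table[[codon]]
  }
  paste(aa, collapse = "")
}

# all six frames -> data frame of stop-free segments with frame labels
# and within-frame segment ordinals, keeping only length >= min_len
oracle_six_frame <- function(seq, min_len) {
  seq <- toupper(seq)
  out <- data.frame(frame = integer(0), segment_index = integer(0),
                    sequence = character(0), stringsAsFactors = FALSE)
  for (fr in c(1, 2, 3, -1, -2, -3)) {
    s <- if (fr > 0) seq else oracle_revcomp(seq)
    aa <- oracle_translate_frame(s, abs(fr))
    segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
    for (i in seq_along(segs)) {
      if (nchar(segs[i]) >= min_len) {
        out <- rbind(out, data.frame(frame = fr, segment_index = i,
                                     sequence = segs[i],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

oracle_filter_psms <- function(psms, sn_cols, min_score, sn_thr, min_len) {
  keep <- logical(nrow(psms))
  for (i in seq_len(nrow(psms))) {
    p <- psms[i, ]
    keep[i] <- p$score >= min_score &&
      !grepl(";", p$proteins, fixed = TRUE) &&
      nchar(p$peptide) >= min_len &&
      sum(unlist(p[sn_cols])) > sn_thr
  }
  keep
}

oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t),
                 numeric(1))))
}

# exact permutation p-value of the two-sample KS D (conditional on the
# pooled data): enumerate every assignment of the pooled values to the
# two groups
oracle_ks_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  d_obs <- oracle_ks_D(x, y)
  idx <- utils::combn(length(pooled), n)
  ds <- apply(idx, 2, function(ii) {
    oracle_ks_D(pooled[ii], pooled[-ii])
  })
  mean(ds >= d_obs - 1e-12)
}

# exact two-sided p-value of the Mann-Whitney U by the same enumeration
oracle_u_perm <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n <- length(x)
  u_obs <- u_stat(x, y)
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  p <- 2 * min(mean(us <= u_obs + 1e-12), mean(us >= u_obs - 1e-12))
  list(U = u_obs, p = min(1, p))
}

# minimal synthetic factorial data set builder
make_factorial <- function(means, n = 5, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (a in rownames(means)) for (b in colnames(means)) {
    rows[[length(rows) + 1]] <- data.frame(
      treatment = a, time = b,
      response = means[a, b] + rnorm(n, 0, sd),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
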