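# Behavioral and physiological statistics: choice-flume preference
# proportions, PSII maximum quantum yield, balanced factorial tests
# (parametric and rank-based) and their post hocs.

#' Maximum quantum yield of photosystem II
#'
#' Fv/Fm = (Fm - Fo)/Fm from dark-adapted minimal (Fo) and maximal (Fm)
#' fluorescence. Dimensionless, in \[0, 1\].
#'
#' @param F0 Minimal fluorescence, non-negative.
#' @param Fm Maximal fluorescence, strictly positive; `F0 <= Fm`.
#' @return (Fm - F0)/Fm, vectorized.
#' @examples
#' fvfm(300, 1000) # 0.7
#' @export
fvfm <- function(F0, Fm) {
  if (any(Fm <= 0)) stop("Fm must be strictly positive")
  if (any(F0 < 0)) stop("F0 must be non-negative")
  if (any(F0 > Fm)) stop("F0 must not exceed Fm")
  (Fm - F0) / Fm
}

#' Arcsine square-root transform of a proportion
#'
#' The classical variance-stabilising transform for percentage data:
#' asin(sqrt(p)), strictly monotone from \[0, 1\] onto \[0, pi/2\].
#' Percentages are converted to proportions first when `percent = TRUE`.
#'
#' @param p Proportions in \[0, 1\] (or percentages in \[0, 100\]).
#' @param percent Interpret `p` as percentages.
#' @return Transformed values in \[0, pi/2\].
#' @export
arcsine_sqrt <- function(p, percent = FALSE) {
  if (percent) p <- p / 100
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  asin(sqrt(p))
}

#' Time-in-cue proportion for one choice-flume trial
#'
#' A trial consists of two 2-minute observation periods with the cue
#' delivered on opposite sides (the side swap controls for side bias); the
#' larva's side is recorded at 5-s intervals, 24 observations per period.
#' The preference statistic is the percentage of the 48 pooled
#' observations in which the larva sat on that period's cue side.
#'
#' @param trial Data frame for a single larva with columns `period` (1 or
#'   2), `cue_side` (`"left"`/`"right"`, constant within period, opposite
#'   between periods) and `position` (`"left"`/`"right"`, 24 rows per
#'   period).
#' @return Percentage in \[0, 100\].
#' @export
cue_time_proportion <- function(trial) {
  stopifnot(is.data.frame(trial),
            all(c("period", "cue_side", "position") %in% names(trial)))
  periods <- sort(unique(trial$period))
  if (!identical(as.integer(periods), c(1L, 2L))) {
    stop("a trial must contain exactly periods 1 and 2")
  }
  cue <- character(2)
  for (p in 1:2) {
    sub <- trial[trial$period == p, , drop = FALSE]
    if (nrow(sub) != 24L) {
      stop("period ", p, " has ", nrow(sub), " observations; expected 24")
    }
    u <- unique(sub$cue_side)
    if (length(u) != 1L) stop("cue side varies within period ", p)
    cue[p] <- u
  }
  if (cue[1] == cue[2]) stop("cue side must swap between periods")
  if (!all(trial$position %in% c("left", "right"))) {
    stop("positions must be 'left' or 'right'")
  }
  100 * mean(trial$position == trial$cue_side)
}

#' Per-larva time-in-cue proportions for a trial table
#'
#' @param trials Data frame of flume observations with a `larva_id`
#'   column plus the columns of [cue_time_proportion()].
#' @return Data frame `larva_id`, `percent_in_cue`.
#' @export
flume_proportions <- function(trials) {
  ids <- unique(trials$larva_id)
  data.frame(
    larva_id = ids,
    percent_in_cue = vapply(ids, function(id) {
      cue_time_proportion(trials[trials$larva_id == id, , drop = FALSE])
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical distribution
#' functions. The p-value is exact (full enumeration of the D
#' distribution, conditional on ties) when `min(n, m) <= exact_max`, and
#' the standard asymptotic approximation otherwise; for small samples
#' both are reported.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact_max Largest smaller-sample size for which the exact
#'   p-value is used (default 5).
#' @return List: `D`, `p` (the one used), `method`, and `p_exact` /
#'   `p_asymptotic` (both populated when the exact path is taken).
#' @export
ks_two_sample <- function(x, y, exact_max = 5L) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  exact <- min(length(x), length(y)) <= exact_max
  ks_e <- suppressWarnings(ks.test(x, y, exact = TRUE))
  ks_a <- suppressWarnings(ks.test(x, y, exact = FALSE))
  D <- unname(ks_e$statistic)
  list(D = D,
       p = if (exact) ks_e$p.value else ks_a$p.value,
       method = if (exact) "exact" else "asymptotic",
       p_exact = if (exact) ks_e$p.value else NA_real_,
       p_asymptotic = ks_a$p.value)
}

check_factorial <- function(data, factor_a, factor_b, response,
                            need_reps = TRUE) {
  stopifnot(is.data.frame(data),
            all(c(factor_a, factor_b, response) %in% names(data)))
  A <- factor(data[[factor_a]]); B <- factor(data[[factor_b]])
  if (nlevels(A) < 2L || nlevels(B) < 2L) {
    stop("each factor needs at least 2 levels")
  }
  tab <- table(A, B)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)
    stop("empty design cells: ",
         paste(sprintf("%s x %s", rownames(tab)[empty[, 1]],
                       colnames(tab)[empty[, 2]]), collapse = ", "))
  }
  if (need_reps && any(tab < 2L)) {
    stop("the interaction term needs at least 2 replicates per cell")
  }
  list(A = A, B = B, y = data[[response]])
}

#' Balanced two-way fixed-effects ANOVA
#'
#' Type-I sums of squares on a (balanced) two-factor design with
#' interaction, F ratios against the residual mean square. A constant
#' response yields F = 0 and p = 1 for every term rather than 0/0.
#'
#' @param data Data frame of observations.
#' @param factor_a,factor_b Column names of the two fixed factors
#'   (defaults `"treatment"` and `"time"`).
#' @param response Response column name (default `"response"`).
#' @param transform Optional function applied to the response before
#'   fitting (e.g. [arcsine_sqrt()] for percentages).
#' @return Object of class `factorial_anova`: `table` (term, df, sumsq,
#'   statistic, p) and the underlying `aov` fit (NULL for the degenerate
#'   constant-response case).
#' @export
two_way_anova <- function(data, factor_a = "treatment", factor_b = "time",
                          response = "response", transform = NULL) {
  parts <- check_factorial(data, factor_a, factor_b, response)
  y <- if (is.null(transform)) parts$y else transform(parts$y)
  terms_lab <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  dfs <- c(nlevels(parts$A) - 1L, nlevels(parts$B) - 1L,
           (nlevels(parts$A) - 1L) * (nlevels(parts$B) - 1L))
  if (var(y) == 0) {
    tab <- data.frame(term = c(terms_lab, "Residuals"),
                      df = c(dfs, length(y) - 1L - sum(dfs)),
                      sumsq = 0, statistic = c(0, 0, 0, NA),
                      p = c(1, 1, 1, NA), stringsAsFactors = FALSE)
    return(structure(list(table = tab, fit = NULL), class = "factorial_anova"))
  }
  d <- data.frame(.y = y, .A = parts$A, .B = parts$B)
  fit <- aov(.y ~ .A * .B, data = d)
  a <- anova(fit)
  tab <- data.frame(term = c(terms_lab, "Residuals"),
                    df = a$Df, sumsq = a$`Sum Sq`,
                    statistic = a$`F value`, p = a$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, fit = fit), class = "factorial_anova")
}

#' @export
print.factorial_anova <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD post hoc comparisons
#'
#' Studentized-range pairwise comparisons for one factor of a fitted
#' [two_way_anova()].
#'
#' @param fit A `factorial_anova` object.
#' @param factor Which factor: `"A"`, `"B"` or `"AB"` (cell means).
#' @return Data frame: `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(fit, factor = "A") {
  stopifnot(inherits(fit, "factorial_anova"))
  if (is.null(fit$fit)) stop("degenerate (constant-response) fit has no post hoc")
  which_term <- switch(factor, A = ".A", B = ".B", AB = ".A:.B",
                       stop("factor must be 'A', 'B' or 'AB'"))
  tk <- TukeyHSD(fit$fit, which = which_term)[[which_term]]
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             stringsAsFactors = FALSE, row.names = NULL)
}

srh_ss <- function(r, f) {
  means <- tapply(r, f, mean)
  counts <- tapply(r, f, length)
  sum(counts * (means - mean(r))^2)
}

#' Scheirer-Ray-Hare nonparametric two-way ANOVA
#'
#' The rank-based extension of the Kruskal-Wallis test to a two-factor
#' design: responses are replaced by mid-ranks (ties averaged), two-way
#' sums of squares are computed on the ranks, and each effect's statistic
#' H = SS_effect / MS_total is referred to a chi-square distribution with
#' the effect's degrees of freedom, where MS_total = SS_total / (N - 1)
#' on the mid-ranks. Because the mid-rank total mean square equals
#' N(N+1)/12 times the standard tie-correction factor
#' 1 - sum(t^3 - t)/(N^3 - N), this denominator carries the tie
#' correction exactly as Kruskal-Wallis does. Cell sums of
#' squares use the balanced (equal cell size) decomposition; when one
#' factor has a single level the test for the other factor reduces
#' exactly to Kruskal-Wallis.
#'
#' @inheritParams two_way_anova
#' @return Data frame: `term`, `df`, `H`, `p`.
#' @export
scheirer_ray_hare <- function(data, factor_a = "treatment",
                              factor_b = "time", response = "response") {
  stopifnot(all(c(factor_a, factor_b, response) %in% names(data)))
  A <- factor(data[[factor_a]]); B <- factor(data[[factor_b]])
  y <- data[[response]]
  if (nlevels(A) < 1L || nlevels(B) < 1L) stop("factors must be non-empty")
  two_level <- nlevels(A) >= 2L && nlevels(B) >= 2L
  if (two_level) check_factorial(data, factor_a, factor_b, response)
  r <- rank(y)
  N <- length(r)
  # the total mean square of the mid-ranks equals N(N+1)/12 times the
  # standard tie-correction factor 1 - sum(t^3 - t)/(N^3 - N), so using
  # it as the denominator applies the correction
  ms_total <- sum((r - mean(r))^2) / (N - 1)
  if (ms_total == 0) {
    # all responses identical: no evidence against any effect
    terms <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
    return(data.frame(term = terms, df = NA_integer_, H = 0, p = 1,
                      stringsAsFactors = FALSE))
  }
  ss_a <- srh_ss(r, A)
  ss_b <- srh_ss(r, B)
  cells <- interaction(A, B, drop = TRUE)
  ss_cells <- srh_ss(r, cells)
  ss_ab <- max(0, ss_cells - ss_a - ss_b)
  dfs <- c(nlevels(A) - 1L, nlevels(B) - 1L,
           (nlevels(A) - 1L) * (nlevels(B) - 1L))
  H <- c(ss_a, ss_b, ss_ab) / ms_total
  terms <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  keep <- dfs > 0L
  data.frame(term = terms[keep], df = dfs[keep], H = H[keep],
             p = pchisq(H[keep], df = dfs[keep], lower.tail = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mann-Whitney U tests with Bonferroni correction
#'
#' Two-sided rank-sum tests for a set of pairwise group comparisons;
#' p-values are exact for small samples without ties and use the normal
#' approximation with continuity correction otherwise. The Bonferroni
#' adjustment multiplies each raw p by the number of comparisons made,
#' capped at 1.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (same length).
#' @param comparisons Optional list of 2-element character vectors naming
#'   the group pairs to test; all pairs by default.
#' @param exact_max Largest group size for which the exact U distribution
#'   is used when there are no ties (default 8).
#' @return Data frame: `group1`, `group2`, `U`, `p`, `p_adj`.
#' @export
mann_whitney_bonferroni <- function(values, groups, comparisons = NULL,
                                    exact_max = 8L) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  levs <- unique(groups)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(levs, 2L, simplify = FALSE)
  }
  rows <- lapply(comparisons, function(pair) {
    x <- values[groups == pair[1L]]
    y <- values[groups == pair[2L]]
    if (length(x) == 0L || length(y) == 0L) {
      stop("empty group in comparison ", pair[1L], " vs ", pair[2L])
    }
    ties <- anyDuplicated(c(x, y)) > 0L
    use_exact <- !ties && max(length(x), length(y)) <= exact_max
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                  correct = TRUE))
    data.frame(group1 = pair[1L], group2 = pair[2L],
               U = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * length(comparisons))
  rownames(out) <- NULL
  out
}
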