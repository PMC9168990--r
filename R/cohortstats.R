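# Two-group and subgroup statistics: pooled-variance Student's t,
# Pearson chi-square on 2x2 tables, and ANOVA-F feature ranking.

#' Two-tailed pooled-variance Student's t-test
#'
#' The classical equal-variance form (not Welch), with two-sided p from
#' the t distribution on `n_a + n_b - 2` degrees of freedom.  Degenerate
#' zero-variance inputs return `t = 0, p = 1` for equal means and
#' `t = +-Inf, p = 0` for unequal means.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `statistic` (t), `p`, `df`, and per-group
#'   `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`.
#' @export
#' @examples
#' ttest_two_tailed(c(1, 2, 3), c(4, 5, 6))
ttest_two_tailed <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    glyco_stop("each group needs at least 2 values", "glycomig_parameter_error")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 <= 0) {
    t <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
  } else {
    t <- delta / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * pt(-abs(t), df)
  }
  list(statistic = t, p = p, df = df,
       mean_a = mean(a), sd_a = sd(a), n_a = na,
       mean_b = mean(b), sd_b = sd(b), n_b = nb)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction:
#' `chisq = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, p from the
#' chi-square distribution with 1 df.
#'
#' @param a,b First row of the table (e.g. exposed cases / unexposed
#'   cases); `c`, `d` the second row.
#' @param c,d Second row counts.
#' @return List with `statistic`, `p`, `df = 1`, and the table.
#' @export
#' @examples
#' chi_square_2x2(9, 11, 3, 17)  # 4.286
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    glyco_stop("counts must be nonnegative integers", "glycomig_parameter_error")
  n <- sum(counts)
  if (n <= 0)
    glyco_stop("empty table", "glycomig_parameter_error")
  margins <- c("row1" = a + b, "row2" = c + d, "col1" = a + c, "col2" = b + d)
  if (any(margins == 0))
    glyco_stop(sprintf("chi-square undefined: margin '%s' is zero",
                       names(margins)[margins == 0][1]),
               "glycomig_parameter_error")
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, table = matrix(c(a, b, c, d), 2, byrow = TRUE))
}

#' Rank features by one-way ANOVA F
#'
#' Computes the two-group one-way ANOVA F statistic per feature (for two
#' groups, F equals the squared pooled t) and returns the top `k`
#' features by F, ties broken by feature name ascending.  The ranking is
#' invariant to positive rescaling of any feature.
#'
#' @param X Sample-by-feature data frame or matrix.
#' @param labels Binary group labels (two levels, each with >= 2 samples).
#' @param k Number of features to return.
#' @return Data frame `feature`, `F`, ordered by decreasing F, `k` rows.
#' @export
f_rank_features <- function(X, labels, k) {
  X <- as.matrix(X)
  if (k > ncol(X))
    glyco_stop(sprintf("k = %d exceeds the %d available features", k, ncol(X)),
               "glycomig_parameter_error")
  g <- as.factor(labels)
  if (nlevels(g) != 2L || any(table(g) < 2L))
    glyco_stop("labels must have two levels with >= 2 samples each",
               "glycomig_parameter_error")
  i1 <- g == levels(g)[1]
  f <- vapply(seq_len(ncol(X)), function(j) {
    tt <- ttest_two_tailed(X[i1, j], X[!i1, j])
    tt$statistic^2
  }, numeric(1))
  nm <- colnames(X) %||% as.character(seq_len(ncol(X)))
  ord <- order(-f, nm)
  data.frame(feature = nm[ord][seq_len(k)], F = f[ord][seq_len(k)],
             stringsAsFactors = FALSE)
}

#' Compare all features between two groups
#'
#' One pooled t-test per column of the feature table (glycopeptide
#' abundances and/or derived traits).  Raw p-values by default; an
#' optional Benjamini-Hochberg adjusted column can be added.
#'
#' @param features Sample-by-feature data frame (rows aligned with
#'   `manifest`).
#' @param manifest Data frame with the grouping columns (`group` coded
#'   `"case"`/`"control"`; logical `aura`, `family_history`; `phase`
#'   coded `"ictal"`/`"interictal"`).
#' @param grouping One of `"group"` (case vs control over all samples),
#'   or `"aura"`, `"phase"`, `"family_history"` (within cases).
#' @param adjust If TRUE append Benjamini-Hochberg `q` values.
#' @return Data frame with one row per feature: group means and SDs,
#'   `statistic`, `p` (and optionally `q`).
#' @export
compare_all <- function(features, manifest,
                        grouping = c("group", "aura", "phase", "family_history"),
                        adjust = FALSE) {
  grouping <- match.arg(grouping)
  if (grouping == "group") {
    idx <- rep(TRUE, nrow(manifest))
    lab <- manifest$group == "case"
  } else {
    idx <- manifest$group == "case"
    lab <- switch(grouping,
                  aura = manifest$aura[idx],
                  phase = manifest$phase[idx] == "ictal",
                  family_history = manifest$family_history[idx])
  }
  X <- features[idx, , drop = FALSE]
  if (length(unique(lab)) < 2L || any(table(lab) < 2L))
    glyco_stop(sprintf("grouping '%s' does not yield two levels with >= 2 samples",
                       grouping), "glycomig_parameter_error")
  rows <- lapply(colnames(X), function(f) {
    tt <- ttest_two_tailed(X[lab, f], X[!lab, f])
    data.frame(feature = f,
               mean_a = tt$mean_a, sd_a = tt$sd_a, n_a = tt$n_a,
               mean_b = tt$mean_b, sd_b = tt$sd_b, n_b = tt$n_b,
               statistic = tt$statistic, p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  attr(out, "grouping") <- grouping
  out
}
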