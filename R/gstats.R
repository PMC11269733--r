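# Shared group statistics behind the analyses: Benjamini-Hochberg FDR,
# one-sample t-tests, exact binomial tail tests, and one-way ANOVA with
# Tukey HSD. Thin, validated wrappers over the standard stats machinery so
# that every module reports corrections the same way.

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up procedure at level `q`; returns the rejection flags with the
#' BH-adjusted p-values attached as attribute `p_adjusted`.
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical rejection vector.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) stop("empty p-value vector")
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  padj <- stats::p.adjust(pvals, method = "BH")
  structure(padj <= q, p_adjusted = padj)
}

#' One-sample t-test against a reference mean
#'
#' Standard one-sample t; the degenerate zero-variance case is resolved
#' explicitly (all values at `mu0` gives t = 0, p = 1; all values equal but
#' away from `mu0` gives an infinite statistic with p reported as 0 and the
#' `degenerate` flag set).
#'
#' @param values Per-subject values (n >= 2, finite).
#' @param mu0 Null mean (default 0).
#' @param sides `"two"` or `"one"` (one-sided toward values > mu0).
#' @return List `statistic`, `df`, `p`, `degenerate`.
#' @export
group_ttest <- function(values, mu0 = 0, sides = c("two", "one")) {
  sides <- match.arg(sides)
  if (length(values) < 2L || any(!is.finite(values)))
    stop("need at least 2 finite values")
  n <- length(values)
  s <- stats::sd(values)
  if (s == 0) {
    if (mean(values) == mu0)
      return(list(statistic = 0, df = n - 1L, p = 1, degenerate = TRUE))
    stat <- sign(mean(values) - mu0) * Inf
    p <- if (sides == "two" || stat > 0) 0 else 1
    return(list(statistic = stat, df = n - 1L, p = p, degenerate = TRUE))
  }
  stat <- (mean(values) - mu0) / (s / sqrt(n))
  p <- if (sides == "two") 2 * stats::pt(-abs(stat), n - 1L)
  else stats::pt(stat, n - 1L, lower.tail = FALSE)
  list(statistic = stat, df = n - 1L, p = p, degenerate = FALSE)
}

#' Exact binomial tail test on a subject fraction
#'
#' Exact tail probability of observing `k` or more (side `"greater"`) /
#' `k` or fewer (side `"less"`) successes out of `n` under success
#' probability `p0`.
#'
#' @param k Observed successes (0..n).
#' @param n Number of trials (subjects).
#' @param p0 Null success probability in (0, 1).
#' @param side `"greater"` or `"less"`.
#' @return List `statistic` (k), `p`.
#' @export
binomial_fraction_test <- function(k, n, p0, side = c("greater", "less")) {
  side <- match.arg(side)
  if (k < 0 || k > n || p0 <= 0 || p0 >= 1)
    stop("parameters out of range: need 0 <= k <= n and p0 in (0, 1)")
  p <- if (side == "greater") stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  else stats::pbinom(k, n, p0)
  list(statistic = k, p = p)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Balanced one-way ANOVA across the columns of a subject-by-group matrix,
#' followed by Tukey's Honestly Significant Difference test at FWER
#' `alpha`. Identical groups (zero between- and within-group variance)
#' return F = 0, p = 1 with no pairs flagged.
#'
#' @param groups Subject-by-group numeric matrix (column names label the
#'   groups).
#' @param alpha Tukey FWER (default 0.05).
#' @return List `F`, `p`, `pairwise` (data frame `pair`, `diff`, `p_adj`,
#'   `significant`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  groups <- as.matrix(groups)
  if (ncol(groups) < 2L) stop("need at least 2 groups")
  if (nrow(groups) < 2L) stop("need at least 2 subjects per group")
  gnames <- colnames(groups)
  if (is.null(gnames)) gnames <- paste0("g", seq_len(ncol(groups)))
  long <- data.frame(value = as.vector(groups),
                     group = factor(rep(gnames, each = nrow(groups)),
                                    levels = gnames))
  if (stats::sd(long$value) == 0) {
    pairs <- t(utils::combn(gnames, 2L))
    pw <- data.frame(pair = paste(pairs[, 2], pairs[, 1], sep = "-"),
                     diff = 0, p_adj = 1, significant = FALSE)
    return(list(F = 0, p = 1, pairwise = pw))
  }
  fit <- stats::aov(value ~ group, data = long)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pw <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                   p_adj = tk[, "p adj"],
                   significant = tk[, "p adj"] < alpha)
  rownames(pw) <- NULL
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1], pairwise = pw)
}
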