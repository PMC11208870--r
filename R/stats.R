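#' Group comparison with a normality-gated test family
#'
#' Assesses per-group normality with the Shapiro-Wilk test at `alpha`;
#' if every group is compatible with normality the parametric family is
#' used (one-way ANOVA omnibus, Student's t pairwise), otherwise the
#' non-parametric family (Kruskal-Wallis omnibus, Wilcoxon rank-sum
#' pairwise). Pairwise p-values are Bonferroni-adjusted over all
#' pairwise comparisons of the metric (`p_adj = min(1, p * m)`).
#' Constant within-group data make normality undefined; the
#' non-parametric family is then used and recorded.
#'
#' @param metric_by_group Named list of numeric vectors, one per group
#'   (>= 2 groups of >= 3 samples).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `stats_table`: list with `family`
#'   (`"parametric"` or `"non-parametric"`), `normality` (per-group
#'   Shapiro-Wilk p), `omnibus` (test name, statistic, p), `pairwise`
#'   (data frame: groups, test, raw and adjusted p, direction of the
#'   first group's mean relative to the second), `descriptives` and
#'   `alpha`.
#' @export
compare_groups <- function(metric_by_group, alpha = 0.05) {
  stopifnot(is.list(metric_by_group), length(metric_by_group) >= 2)
  g <- names(metric_by_group)
  if (is.null(g) || any(!nzchar(g))) stop("groups must be named")
  if (any(vapply(metric_by_group, length, 0L) < 3))
    stop("each group needs at least 3 samples")

  sw <- vapply(metric_by_group, function(x) {
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }, 0)
  degenerate <- any(is.na(sw))
  parametric <- !degenerate && all(sw >= alpha)

  values <- unlist(metric_by_group, use.names = FALSE)
  labels <- factor(rep(g, vapply(metric_by_group, length, 0L)), levels = g)
  omnibus <- if (parametric) {
    a <- stats::oneway.test(values ~ labels, var.equal = TRUE)
    list(test = "one-way ANOVA", statistic = unname(a$statistic),
         p = a$p.value)
  } else {
    k <- stats::kruskal.test(values, labels)
    list(test = "Kruskal-Wallis", statistic = unname(k$statistic),
         p = k$p.value)
  }

  pairs <- utils::combn(g, 2)
  m <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   test = NA_character_, p_raw = NA_real_,
                   p_adj = NA_real_, direction = NA_character_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    x <- metric_by_group[[pw$group1[i]]]
    y <- metric_by_group[[pw$group2[i]]]
    res <- tryCatch({
      if (parametric) list(t = "Student t",
                           p = stats::t.test(x, y, var.equal = TRUE)$p.value)
      else list(t = "Wilcoxon rank-sum",
                p = suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value))
    }, error = function(e) list(t = "undefined", p = NA_real_))
    pw$test[i] <- res$t
    pw$p_raw[i] <- res$p
    pw$direction[i] <- if (mean(x) > mean(y)) ">"
                       else if (mean(x) < mean(y)) "<" else "="
  }
  pw$p_adj <- pmin(1, pw$p_raw * m)

  desc <- data.frame(
    group = g,
    n = vapply(metric_by_group, length, 0L),
    mean = vapply(metric_by_group, mean, 0),
    sd = vapply(metric_by_group, stats::sd, 0),
    median = vapply(metric_by_group, stats::median, 0),
    row.names = NULL)

  structure(list(family = if (parametric) "parametric" else "non-parametric",
                 normality_degenerate = degenerate,
                 normality = sw, omnibus = omnibus, pairwise = pw,
                 descriptives = desc, alpha = alpha),
            class = "stats_table")
}

#' @export
print.stats_table <- function(x, ...) {
  cat(sprintf("Group comparison (%s family; omnibus %s p = %.3g)\n",
              x$family, x$omnibus$test, x$omnibus$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Rank correlation between two sample vectors
#'
#' Spearman correlation with a two-sided p-value.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return List with `coefficient` (in `[-1, 1]`, `NA` when undefined),
#'   `p_value`, `n`, `method` and `defined`.
#' @export
correlate_metrics <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(coefficient = NA_real_, p_value = NA_real_,
                n = length(x), method = "spearman", defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), method = "spearman", defined = TRUE)
}
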