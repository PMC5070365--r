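# Group comparison: Kruskal-Wallis across physician groups with a
# rank-based all-pairs post hoc.

#' Compare travel-time distributions across physician groups
#'
#' Kruskal-Wallis rank test (tie-corrected H with the chi-square
#' approximation) across two or more groups, followed by all-pairs
#' post-hoc comparisons: by default the rank-based Nemenyi procedure using
#' the Studentized range (a Tukey-type correction on pooled mean ranks),
#' alternatively Dunn's z tests with Bonferroni adjustment.
#'
#' When every pooled value is identical the test is degenerate and H = 0,
#' p = 1 is returned with no significant pairs.
#'
#' @param values Numeric outcome (e.g. per-district travel times), pooled.
#' @param groups Group labels, same length as `values`; >= 2 groups, each
#'   with >= 1 value.
#' @param method `"nemenyi"` (Tukey-type) or `"dunn"`
#'   (Dunn-Bonferroni).
#' @param alpha Significance level for the pairwise flags.
#' @return Object of class `group_comparison`: `H`, `df`, `p_value`,
#'   `pairwise` (one row per pair with statistic, adjusted p, significance)
#'   and a symmetric logical `signif_matrix`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 5, 3, 4, 7, 6, 8, 9),
#'                rep(c("a", "b", "c"), each = 3))
compare_groups <- function(values, groups, method = c("nemenyi", "dunn"),
                           alpha = 0.05) {
  method <- match.arg(method)
  keep <- !is.na(values)
  values <- values[keep]
  groups <- factor(groups[keep])
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 1L)) stop("every group needs values", call. = FALSE)

  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)

  if (length(unique(values)) == 1L) {
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     diff_mean_rank = 0, statistic = 0, p_adj = 1,
                     significant = FALSE, stringsAsFactors = FALSE)
    return(.group_comparison(0, k - 1L, 1, pw, lev, alpha, method))
  }

  kt <- stats::kruskal.test(values, groups)
  H <- unname(kt$statistic)
  p <- kt$p.value

  r <- rank(values)
  N <- length(values)
  nn <- tapply(r, groups, length)
  mr <- tapply(r, groups, mean)

  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   stringsAsFactors = FALSE)
  d <- as.numeric(abs(mr[pw$group1] - mr[pw$group2]))
  pw$diff_mean_rank <- d
  if (method == "nemenyi") {
    se <- as.numeric(sqrt((N * (N + 1) / 12) *
                            (1 / nn[pw$group1] + 1 / nn[pw$group2])))
    pw$statistic <- d / se
    pw$p_adj <- pmin(1, 1 - stats::ptukey(pw$statistic * sqrt(2), k, Inf))
  } else {
    ties <- table(values)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    se <- as.numeric(sqrt((N * (N + 1) / 12 - tie_term) *
                            (1 / nn[pw$group1] + 1 / nn[pw$group2])))
    pw$statistic <- d / se
    pw$p_adj <- pmin(1, 2 * stats::pnorm(-pw$statistic) * ncol(pairs))
  }
  pw$significant <- pw$p_adj < alpha
  .group_comparison(H, k - 1L, p, pw, lev, alpha, method)
}

.group_comparison <- function(H, df, p, pw, lev, alpha, method) {
  m <- matrix(FALSE, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_len(nrow(pw))) {
    m[pw$group1[i], pw$group2[i]] <- pw$significant[i]
    m[pw$group2[i], pw$group1[i]] <- pw$significant[i]
  }
  out <- list(H = H, df = df, p_value = p, pairwise = pw,
              signif_matrix = m, alpha = alpha, method = method)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
              x$H, x$df, x$p_value))
  cat("Post hoc (", x$method, ", alpha = ", x$alpha, "):\n", sep = "")
  print(x$pairwise, digits = 4, row.names = FALSE)
  invisible(x)
}
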