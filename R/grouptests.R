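## Rank-based group comparisons: Kruskal-Wallis across dietary or body-size
## groups, and Dunn's z test for pairwise post hoc comparisons on the pooled
## ranks, with the usual tie corrections.

.check_rank_input <- function(values, groups) {
  values <- as.numeric(values)
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("values and groups must have the same length", call. = FALSE)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  if (length(unique(groups)) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (length(unique(values)) < 2L)
    stop("all values tied; rank statistic undefined", call. = FALSE)
  list(values = values, groups = groups)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution on
#' g - 1 degrees of freedom (computed via [stats::kruskal.test()]), plus the
#' pooled-rank group means used by the pairwise follow-up.
#'
#' @param values Numeric vector of observations (e.g. individual d13C ranges).
#' @param groups Grouping vector of the same length.
#' @return An object of class `kw_test`: list with `statistic` (H), `df`,
#'   `p.value`, `rank_means` (named), `n` (named group sizes), `N`.
#' @seealso [dunn_test()]
#' @export
kruskal_wallis <- function(values, groups) {
  inp <- .check_rank_input(values, groups)
  kt <- stats::kruskal.test(inp$values, factor(inp$groups))
  r <- rank(inp$values)
  out <- list(statistic = unname(kt$statistic),
              df = unname(kt$parameter),
              p.value = kt$p.value,
              rank_means = c(tapply(r, inp$groups, mean)),
              n = table(inp$groups),
              N = length(inp$values))
  class(out) <- "kw_test"
  out
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis rank test: H = %.6g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  cat("group rank means:\n")
  print(round(x$rank_means, 3))
  invisible(x)
}

#' Dunn's pairwise post hoc comparisons
#'
#' For every unordered pair of groups computes Dunn's tie-corrected z
#' statistic on the pooled ranks,
#' `z = (Ra - Rb) / sqrt((N(N+1)/12 - T/(12(N-1))) * (1/na + 1/nb))`
#' with `T = sum(t^3 - t)` over tie groups, and a two-sided normal p-value.
#' Unadjusted and Holm-adjusted p-values are reported side by side (a
#' Bonferroni column replaces Holm on request).
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector of the same length.
#' @param adjust Multiplicity adjustment for the `p_adjusted` column:
#'   `"holm"` (default), `"bonferroni"` or `"none"`.
#' @return A `data.frame` of class `dunn_test` with one row per pair:
#'   `group_a`, `group_b`, `z`, `p_value` (unadjusted two-sided),
#'   `p_adjusted`. Attribute `adjust` records the procedure.
#' @export
dunn_test <- function(values, groups, adjust = c("holm", "bonferroni",
                                                 "none")) {
  adjust <- match.arg(adjust)
  inp <- .check_rank_input(values, groups)
  v <- inp$values; g <- inp$groups
  N <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  n_g <- table(g)
  tie <- table(v)
  T_corr <- sum(tie^3 - tie)
  s2 <- N * (N + 1) / 12 - T_corr / (12 * (N - 1))
  lev <- sort(names(n_g))
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[[p[1]]] - rbar[[p[2]]]) /
      sqrt(s2 * (1 / n_g[[p[1]]] + 1 / n_g[[p[2]]]))
  })
  p_un <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_un, method = adjust)
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    z = z, p_value = p_un, p_adjusted = p_adj,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "adjust") <- adjust
  class(out) <- c("dunn_test", "data.frame")
  out
}

#' @export
print.dunn_test <- function(x, digits = 4, ...) {
  cat("Dunn pairwise comparisons (", attr(x, "adjust"),
      "-adjusted column)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
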