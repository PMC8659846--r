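# Descriptive and inferential statistics over maximum osteotomy
# deviations: five-number summaries, Kruskal-Wallis omnibus tests and
# Dunn's post-hoc pairwise comparisons.

#' Five-number summary of deviations
#'
#' Min, 25th percentile, median, 75th percentile and max of a deviation
#' sample, using linear interpolation between order statistics (R
#' quantile type 7, the common statistical-software default).
#'
#' @param values numeric vector of deviations (mm), n >= 1.
#' @param labels optional named list of grouping labels (phantom,
#'   method, region, ...) carried into the result.
#' @return An object of class `summary_row` with `n`, `min`, `q25`,
#'   `median`, `q75`, `max` and the labels.
#' @export
mod_describe <- function(values, labels = list()) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 1) stop("need at least one finite value")
  q <- unname(quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  structure(c(labels,
              list(n = length(values), min = q[1], q25 = q[2], median = q[3],
                   q75 = q[4], max = q[5])),
            class = "summary_row")
}

#' @export
print.summary_row <- function(x, ...) {
  lab <- x[!(names(x) %in% c("n", "min", "q25", "median", "q75", "max"))]
  if (length(lab))
    cat(paste(names(lab), unlist(lab), sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  n = %d: min %.2f | Q25 %.2f | Mdn %.2f | Q75 %.2f | max %.2f mm\n",
              x$n, x$min, x$q25, x$median, x$q75, x$max))
  invisible(x)
}

.as_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  if (any(vapply(groups, length, 0L) < 1))
    stop("every group needs at least one value")
  if (sum(vapply(groups, length, 0L)) < 3)
    stop("need at least 3 observations in total")
  pooled <- unlist(groups)
  if (diff(range(pooled)) == 0)
    stop("all observations are identical: rank statistic undefined")
  groups
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom (delegating the computation to
#' [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors, one per group.
#' @return An object of class `kw_result` with `H`, `df`, `p` and
#'   `tie_corrected`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- .as_groups(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  kt <- kruskal.test(unlist(groups), g)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, tie_corrected = TRUE),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.2f, p = %s\n", x$df, x$H,
              format_pvalue(x$p)))
  invisible(x)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics on mean ranks with the tie-corrected pooled
#' variance
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' where \eqn{T = \sum (t^3 - t) / (12 (N - 1))} over tied groups;
#' two-sided normal p-values with optional multiplicity adjustment.
#'
#' @param groups list (optionally named) of numeric vectors.
#' @param adjustment `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return A data frame of class `dunn_result` with columns `group1`,
#'   `group2`, `z`, `p` and attribute `adjustment`.
#' @export
dunn_posthoc <- function(groups, adjustment = c("none", "bonferroni", "holm")) {
  adjustment <- match.arg(adjustment)
  groups <- .as_groups(groups)
  k <- length(groups)
  nm <- names(groups) %||% paste0("group", seq_len(k))
  n <- vapply(groups, length, 0L)
  N <- sum(n)
  r <- rank(unlist(groups))
  idx <- rep(seq_len(k), n)
  rbar <- tapply(r, idx, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2)
  z <- p <- numeric(ncol(pairs))
  for (c2 in seq_len(ncol(pairs))) {
    i <- pairs[1, c2]; j <- pairs[2, c2]
    se <- sqrt(s2 * (1 / n[i] + 1 / n[j]))
    z[c2] <- (rbar[i] - rbar[j]) / se
    p[c2] <- 2 * pnorm(-abs(z[c2]))
  }
  p_adj <- switch(adjustment,
                  none = p,
                  bonferroni = pmin(1, length(p) * p),
                  holm = p.adjust(p, "holm"))
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    z = z, p = p_adj, stringsAsFactors = FALSE)
  attr(out, "adjustment") <- adjustment
  class(out) <- c("dunn_result", "data.frame")
  out
}

#' @export
print.dunn_result <- function(x, ...) {
  cat(sprintf("Dunn's post-hoc test (adjustment: %s)\n",
              attr(x, "adjustment")))
  df <- as.data.frame(x)
  df$p <- vapply(df$p, format_pvalue, "")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Render a p-value the way result sections print them
#' @param p numeric p-value.
#' @return `"p < 0.001"` style string for tiny values, otherwise the
#'   rounded value.
#' @export
format_pvalue <- function(p) {
  if (p < 0.001) "< 0.001" else sprintf("%.3g", p)
}
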