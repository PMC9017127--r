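# Group comparison layer: pooled-variance Student's t for two groups, one-way
# ANOVA followed by Tukey's multiple comparisons (alpha = 0.05) for more,
# Tukey box-plot summaries and fold change of group means.

.checkGroups <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs n >= 2")
  if (all(vapply(groups, stats::var, numeric(1)) == 0))
    stop("zero within-group variance everywhere")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  groups
}

#' Two-sided pooled-variance Student's t test
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @return \code{list(t, df, p)}.
#' @examples
#' studentT(c(1, 2, 3), c(4, 5, 6))
#' @export
studentT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 in each group")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero pooled variance")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition via \code{stats::aov}; p from the F
#' distribution.
#'
#' @param groups named list of numeric vectors (k >= 2, each n >= 2).
#' @return \code{list(F, dfBetween, dfWithin, p, msWithin, grandMeans)}.
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
oneWayAnova <- function(groups) {
  groups <- .checkGroups(groups)
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   label = factor(rep(names(groups),
                                      vapply(groups, length, integer(1)))))
  fit <- stats::aov(value ~ label, data = df)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], dfBetween = s[["Df"]][1],
       dfWithin = s[["Df"]][2], p = s[["Pr(>F)"]][1],
       msWithin = s[["Mean Sq"]][2],
       groupMeans = vapply(groups, mean, numeric(1)))
}

#' Tukey's multiple comparisons after one-way ANOVA
#'
#' Tukey-Kramer form for unequal group sizes: for each pair,
#' \eqn{q = |m_i - m_j| / \sqrt{(MSW/2)(1/n_i + 1/n_j)}}; adjusted p from the
#' studentized range distribution with k groups and the within-group degrees
#' of freedom.
#'
#' @param groups named list of numeric vectors.
#' @param alpha family-wise significance level (default 0.05); pairs with
#'   adjusted p below it are flagged, others labelled "ns".
#' @return list with the ANOVA fields of \code{\link{oneWayAnova}} plus
#'   \code{pairwise}: a data.frame \code{(label_a, label_b, mean_diff, q,
#'   p_adjusted, significant)} with \code{k(k-1)/2} rows, and \code{alpha}.
#' @examples
#' tukeyHsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))$pairwise
#' @export
tukeyHsd <- function(groups, alpha = 0.05) {
  groups <- .checkGroups(groups)
  av <- oneWayAnova(groups)
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  m <- vapply(groups, mean, numeric(1))
  cmb <- utils::combn(k, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(ci) {
    i <- cmb[1, ci]; j <- cmb[2, ci]
    se <- sqrt(av$msWithin / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(m[i] - m[j]) / se
    data.frame(label_a = names(groups)[i], label_b = names(groups)[j],
               mean_diff = m[j] - m[i], q = q,
               p_adjusted = stats::ptukey(q, nmeans = k, df = av$dfWithin,
                                          lower.tail = FALSE))
  }))
  rownames(pw) <- NULL
  pw$significant <- pw$p_adjusted < alpha
  c(av, list(pairwise = pw, alpha = alpha))
}

#' Tukey box-plot summary
#'
#' Quartiles by linear interpolation (type-7 convention); whiskers at the most
#' extreme data values within 1.5 x IQR of the box; data beyond are outliers.
#'
#' @param values numeric vector (n >= 1).
#' @return \code{list(q1, median, q3, whiskerLow, whiskerHigh, outliers, n)}.
#' @examples
#' tukeyBox(c(1, 2, 3, 4, 100))
#' @export
tukeyBox <- function(values) {
  if (!length(values)) stop("need n >= 1")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lowFence <- q[1] - 1.5 * iqr
  highFence <- q[3] + 1.5 * iqr
  inside <- values[values >= lowFence & values <= highFence]
  list(q1 = q[1], median = q[2], q3 = q[3],
       whiskerLow = min(inside), whiskerHigh = max(inside),
       outliers = sort(values[values < lowFence | values > highFence]),
       n = length(values))
}

#' Fold change of group means
#'
#' The ratio of the largest to the smallest mean; all means must be positive.
#'
#' @param means numeric vector of (positive) group means.
#' @return max(means) / min(means).
#' @examples
#' foldChange(c(12.68, 26.83))  # 2.1 at one decimal
#' @export
foldChange <- function(means) {
  if (any(means <= 0)) stop("all means must be > 0")
  max(means) / min(means)
}
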