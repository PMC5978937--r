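#' 2x2 contingency table
#'
#' Cell `a` counts units that are both in the query set and in the category
#' of interest; `b`, `c`, `d` complete the table row-wise.
#'
#' @param a,b,c,d nonnegative integer counts, total > 0.
#' @return a classed list with the four cells.
#' @export
table2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("table cells must be nonnegative integers")
  }
  if (sum(cells) == 0) stop("empty 2x2 table")
  structure(as.list(cells), class = "table2x2")
}

as_matrix_2x2 <- function(t) {
  matrix(c(t$a, t$c, t$b, t$d), nrow = 2,
         dimnames = list(in_set = c("yes", "no"), in_category = c("yes", "no")))
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = ad/bc with a log-scale Wald (Woolf) interval. When any cell is zero
#' and `haldane` is TRUE, 0.5 is added to every cell (Haldane–Anscombe)
#' before both the estimate and the interval.
#'
#' @param t a [table2x2()].
#' @param level confidence level, default 0.95.
#' @param haldane apply the 0.5 correction on zero cells (default TRUE).
#' @return list with `odds_ratio`, `ci_low`, `ci_high`, `p_value` (two-sided
#'   Wald on log OR), `method = "WOOLF"` and the input table.
#' @export
odds_ratio_ci <- function(t, level = 0.95, haldane = TRUE) {
  stopifnot(inherits(t, "table2x2"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    if (!haldane) stop("undefined OR: zero cell without Haldane correction")
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- 2 * stats::pnorm(-abs(log(or)) / se)
  list(odds_ratio = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       p_value = p, method = "WOOLF", tables = list(t))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional (hypergeometric) test; the two-sided p sums the
#' probabilities of tables no more likely than the observed one.
#'
#' @param t a [table2x2()].
#' @param side `"two_sided"`, `"greater"` or `"less"` (on cell `a`).
#' @return the p-value.
#' @export
fisher_exact <- function(t, side = c("two_sided", "greater", "less")) {
  side <- match.arg(side)
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[side]
  stats::fisher.test(as_matrix_2x2(t), alternative = alt)$p.value
}

#' Cochran–Mantel–Haenszel test over stratified 2x2 tables
#'
#' Mantel–Haenszel common odds ratio
#' `sum(a_k d_k / n_k) / sum(b_k c_k / n_k)` with a Robins–Breslow–Greenland
#' log-scale interval, and the CMH chi-square statistic without continuity
#' correction, referred to chi-square with 1 df.
#'
#' @param tables list of [table2x2()] strata.
#' @param level confidence level for the common-OR interval.
#' @return list with `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `statistic`, `method = "CMH"` and the strata.
#' @export
cmh_test <- function(tables, level = 0.95) {
  if (!length(tables)) stop("no strata")
  a <- vapply(tables, `[[`, 0, "a"); b <- vapply(tables, `[[`, 0, "b")
  c_ <- vapply(tables, `[[`, 0, "c"); d <- vapply(tables, `[[`, 0, "d")
  n <- a + b + c_ + d
  if (any(n == 0)) stop("stratum with zero total")
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  informative <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  if (!any(informative)) stop("all strata degenerate")
  num <- sum(a * d / n); den <- sum(b * c_ / n)
  or <- if (num > 0 && den > 0) {
    num / den
  } else {  # degenerate margins: fall back to 0.5-corrected cells
    sum((a + 0.5) * (d + 0.5) / (n + 2)) / sum((b + 0.5) * (c_ + 0.5) / (n + 2))
  }
  # RBG variance of log common OR
  P <- (a + d) / n; Q <- (b + c_) / n
  R <- a * d / n; S <- b * c_ / n
  sumR <- sum(R); sumS <- sum(S)
  if (sumR > 0 && sumS > 0) {
    var_log <- sum(P * R) / (2 * sumR^2) +
      sum(P * S + Q * R) / (2 * sumR * sumS) +
      sum(Q * S) / (2 * sumS^2)
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- exp(log(or) + c(-1, 1) * z * sqrt(var_log))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  # CMH statistic, no continuity correction
  e_a <- r1 * c1 / n
  v_a <- r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  v_a[n <= 1] <- 0
  stat <- (sum(a - e_a))^2 / sum(v_a)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(odds_ratio = or, ci_low = ci[1], ci_high = ci[2], p_value = p,
       statistic = stat, method = "CMH", tables = tables)
}

#' Upper-tail hypergeometric overlap probability
#'
#' `P(X >= k)` where `X` is the overlap between a random size-`n` draw and a
#' fixed size-`K` category in a population of `N`; computed exactly in log
#' space. This is the standard significance measure for the overlap of two
#' gene sets within a genome of `N` protein-coding genes.
#'
#' @param N population size (e.g. 20345 protein-coding genes in GRCh37).
#' @param K category size; `n` draw size; `k` observed overlap.
#' @param n,k see above.
#' @return the tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric arguments")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-proportion z-test (pooled)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p` the pooled
#' proportion; two-sided normal p-value.
#'
#' @param x1,n1 successes and trials in group 1; `x2,n2` for group 2.
#' @param x2,n2 see above.
#' @return list with `z` and `p_value`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) {
    stop("invalid proportion arguments")
  }
  p_pool <- (x1 + x2) / (n1 + n2)
  if (p_pool %in% c(0, 1)) stop("pooled proportion is 0 or 1; z undefined")
  z <- (x1 / n1 - x2 / n2) / sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini–Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Pearson chi-square test on an r x k count table
#'
#' @param table numeric matrix of counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_2xk <- function(table) {
  table <- as.matrix(table)
  exp_counts <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(exp_counts == 0)) stop("zero expected count")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
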