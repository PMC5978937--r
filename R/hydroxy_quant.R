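#' Estimate 5hmC beta-values from paired BS and OxBS channels
#'
#' The BS channel measures 5mC + 5hmC, the OxBS channel 5mC alone, so the
#' per-cell difference estimates 5hmC. Strictly negative differences are a
#' technical artifact (5mC cannot exceed total methylation) and are clamped
#' to a small positive floor; exact zeros are kept at 0.
#'
#' @param bs BS-channel [beta_matrix()].
#' @param oxbs OxBS-channel [beta_matrix()] with identical probes/samples in
#'   identical order.
#' @param clamp_value floor for negative differences (default `1e-7`).
#' @return a `"5hmC"` [beta_matrix()].
#' @export
compute_5hmc <- function(bs, oxbs, clamp_value = 1e-7) {
  if (bm_channel(bs) != "BS") stop("first argument must be the BS channel")
  if (bm_channel(oxbs) != "OxBS") stop("second argument must be the OxBS channel")
  if (!identical(rownames(bs), rownames(oxbs)) ||
      !identical(colnames(bs), colnames(oxbs))) {
    stop("BS and OxBS matrices must share probes and samples in the same order")
  }
  d <- unclass(bs) - unclass(oxbs)
  d[d < 0] <- clamp_value
  beta_matrix(d, "5hmC", clamp_value = clamp_value)
}

#' Relabel an OxBS matrix as 5mC
#'
#' The OxBS channel directly measures true 5mC; this re-tags the values.
#'
#' @param oxbs OxBS-channel [beta_matrix()].
#' @return a `"5mC"` [beta_matrix()] with identical values.
#' @export
compute_5mc <- function(oxbs) {
  if (bm_channel(oxbs) != "OxBS") stop("input must be the OxBS channel")
  beta_matrix(unclass(oxbs), "5mC")
}

#' Select the top fraction of probes by cohort-mean beta
#'
#' Probes are ranked by their mean beta over the masked samples, descending;
#' the top `ceiling(fraction * n_probes)` are returned. Ties at the selection
#' boundary are broken by lexical probe-id order (recorded in the result).
#'
#' @param beta a [beta_matrix()].
#' @param mask logical vector over samples (columns) defining the cohort, or
#'   NULL for all samples.
#' @param fraction fraction in (0, 1\], default 0.01 (the "top 1%" rule).
#' @param cohort label stored in the result (`"MT"`, `"WT"` or `"ALL"`).
#' @return list with `cohort`, `fraction`, `probe_ids` (ordered, best first),
#'   `threshold_value` (smallest selected mean) and `boundary_tie` flag.
#' @export
top_fraction_probes <- function(beta, mask = NULL, fraction = 0.01,
                                cohort = "ALL") {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (is.null(mask)) mask <- rep(TRUE, ncol(beta))
  if (!any(mask)) stop("mask selects no samples")
  means <- rowMeans(unclass(beta)[, mask, drop = FALSE])
  n_sel <- as.integer(ceiling(fraction * nrow(beta)))
  ord <- order(-means, rownames(beta))
  sel <- ord[seq_len(n_sel)]
  threshold <- means[sel[n_sel]]
  boundary_tie <- sum(means == threshold) > sum(means[sel] == threshold)
  list(cohort = cohort, fraction = fraction,
       probe_ids = rownames(beta)[sel],
       threshold_value = unname(threshold),
       boundary_tie = boundary_tie)
}

# method-of-moments fit of the scaled inverse chi-square prior (d0, s0^2)
# on log sample variances; the classical empirical-Bayes moment match on
# e_g = log s_g^2 - digamma(d/2) + log(d/2).
fit_variance_prior <- function(s2, df) {
  s2 <- s2[s2 > 0]
  if (length(s2) < 2) return(list(d0 = 0, s02 = stats::median(s2)))
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton solve of trigamma(y) = x for y > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Per-probe moderated-t volcano statistics between cohorts
#'
#' For each probe: `delta_beta = mean(MT) - mean(WT)`, pooled residual
#' variance with `n - 2` df, empirical-Bayes variance moderation
#' `s2_tilde = (d0 s0^2 + d s^2) / (d0 + d)` with the prior `(d0, s0^2)`
#' fitted by method of moments on the log sample variances (or fixed), and a
#' two-sided p from the t distribution with `d0 + d` df. P-values are
#' BH-adjusted across probes. With `prior_df = 0` this is the ordinary
#' pooled two-sample t-test.
#'
#' @param beta a [beta_matrix()] (typically the 5hmC channel).
#' @param sheet sample sheet covering all columns of `beta`; needs >= 2
#'   samples per cohort.
#' @param prior_df `"moment"` to fit the prior df, or a fixed nonnegative
#'   number (0 disables moderation).
#' @return data.frame with columns `probe_id`, `delta_beta`, `t_stat`,
#'   `p_value`, `adj_p` and `flagged` (zero-variance probes with no prior;
#'   excluded from BH). Attributes `d0` and `s02` record the fitted prior.
#' @export
volcano_stats <- function(beta, sheet, prior_df = "moment") {
  m_mask <- cohort_mask(beta, sheet, "MT")
  w_mask <- cohort_mask(beta, sheet, "WT")
  n1 <- sum(m_mask); n2 <- sum(w_mask)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per cohort")
  v <- unclass(beta)
  x1 <- v[, m_mask, drop = FALSE]; x2 <- v[, w_mask, drop = FALSE]
  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  delta <- mu1 - mu2
  ss1 <- rowSums((x1 - mu1)^2); ss2 <- rowSums((x2 - mu2)^2)
  df_resid <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df_resid
  if (identical(prior_df, "moment")) {
    prior <- fit_variance_prior(s2, df_resid)
  } else {
    d0 <- as.numeric(prior_df)
    if (is.na(d0) || d0 < 0) stop("prior_df must be 'moment' or a nonnegative number")
    prior <- list(d0 = d0,
                  s02 = if (d0 > 0) stats::median(s2[s2 > 0]) else NA_real_)
  }
  d0 <- prior$d0
  s2_tilde <- if (is.infinite(d0)) rep(prior$s02, length(s2)) else if (d0 > 0) {
    (d0 * prior$s02 + df_resid * s2) / (d0 + df_resid)
  } else s2
  flagged <- s2_tilde == 0
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_stat <- ifelse(flagged, NA_real_, delta / se)
  df_total <- d0 + df_resid
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  adj <- rep(NA_real_, length(p))
  adj[!flagged] <- bh_adjust(p[!flagged])
  out <- data.frame(probe_id = rownames(beta), delta_beta = delta,
                    t_stat = t_stat, p_value = p, adj_p = adj,
                    flagged = flagged, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- prior$s02
  out
}

#' Stratify a probe set by annotation category
#'
#' Counts and proportions of probes per CpG-island feature or gene-region
#' category (proportions sum to 1 over observed probes).
#'
#' @param probes character vector of probe ids, or the result of
#'   [top_fraction_probes()].
#' @param ann annotation table covering all probes.
#' @param by `"cpg_feature"` or `"gene_region"`.
#' @return data.frame with `category`, `count`, `proportion`.
#' @export
stratify_counts <- function(probes, ann, by = c("cpg_feature", "gene_region")) {
  by <- match.arg(by)
  if (is.list(probes) && !is.null(probes$probe_ids)) probes <- probes$probe_ids
  idx <- match(probes, ann$probe_id)
  if (anyNA(idx)) stop("unannotated probes in stratify_counts")
  tab <- table(ann[[by]][idx])
  data.frame(category = names(tab), count = as.integer(tab),
             proportion = as.numeric(tab) / length(probes),
             stringsAsFactors = FALSE)
}
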