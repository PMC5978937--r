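#' Quantile-normalise a log2 expression matrix
#'
#' Each column's sorted values are replaced by the cross-column mean of
#' sorted values (ties receive the mean of their would-be quantiles), so
#' all column distributions are identical afterwards. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param expr gene x sample numeric matrix.
#' @return normalised matrix with the same dimnames.
#' @export
quantile_normalize <- function(expr) {
  if (ncol(expr) < 2) stop("need >= 2 samples")
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Two-group differential expression with fold-change and FDR selection
#'
#' Per gene, a pooled two-sample comparison of log2 values between cohorts
#' (one-way ANOVA with two groups, identical to the pooled t-test), BH
#' adjustment across genes, and selection at `adj_p < alpha` together with
#' linear fold change above `fc_threshold`.
#'
#' @param expr gene x sample log2 matrix.
#' @param sheet sample sheet covering the expression samples.
#' @param fc_threshold linear fold-change cut (default 2).
#' @param alpha adjusted-p cut (default 0.05).
#' @return data.frame with `gene`, `log2fc` (MT minus WT), `fold_change`
#'   (linear, >= 1), `direction` (`UP_MT`/`DOWN_MT`), `p`, `adj_p`,
#'   `selected`, `flagged` (zero-variance genes, excluded).
#' @export
differential_expression <- function(expr, sheet, fc_threshold = 2,
                                    alpha = 0.05) {
  idx <- match(colnames(expr), sheet$sample_id)
  if (anyNA(idx)) stop("expression samples missing from sheet")
  mt <- sheet$cohort[idx] == "MT"
  n1 <- sum(mt); n2 <- sum(!mt)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per cohort")
  x1 <- expr[, mt, drop = FALSE]; x2 <- expr[, !mt, drop = FALSE]
  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  l2fc <- mu1 - mu2
  s2 <- (rowSums((x1 - mu1)^2) + rowSums((x2 - mu2)^2)) / (n1 + n2 - 2)
  flagged <- s2 == 0
  t_stat <- l2fc / sqrt(s2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t_stat), df = n1 + n2 - 2)
  p[flagged] <- NA_real_
  adj <- rep(NA_real_, length(p))
  adj[!flagged] <- bh_adjust(p[!flagged])
  fc <- 2^abs(l2fc)
  out <- data.frame(
    gene = rownames(expr), log2fc = l2fc, fold_change = fc,
    direction = ifelse(l2fc >= 0, "UP_MT", "DOWN_MT"),
    p = p, adj_p = adj,
    selected = !flagged & !is.na(adj) & adj < alpha & fc > fc_threshold,
    flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Top fraction of genes by mean expression
#'
#' Genes ranked by mean log2 expression over all samples; the top
#' `ceiling(fraction * n)` are returned, boundary ties broken by symbol
#' order.
#'
#' @param expr gene x sample log2 matrix.
#' @param fraction fraction in (0, 1\], default 0.2 (the "top 20%" rule).
#' @return character vector of gene symbols.
#' @export
top_expressed_genes <- function(expr, fraction = 0.2) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  means <- rowMeans(expr)
  ord <- order(-means, rownames(expr))
  rownames(expr)[ord[seq_len(ceiling(fraction * nrow(expr)))]]
}

#' Association between a probe set and highly expressed gene targets
#'
#' Builds a 2x2 table over annotated probe-gene pairs — query-set
#' membership against target-gene membership in `top_genes` — optionally
#' restricted to probes in given gene regions, and returns the Woolf odds
#' ratio with CI and p via [odds_ratio_ci()].
#'
#' @param probes query probe ids (e.g. a cohort's top-fraction 5hmC set).
#' @param ann probe annotation.
#' @param top_genes gene symbols of the highly expressed set.
#' @param all_genes gene universe (symbols with expression data).
#' @param region_filter optional character vector of `gene_region` values,
#'   e.g. `c("TSS200", "FIRST_EXON")` or `c("BODY", "INTRON")`.
#' @return an enrichment result list (see [odds_ratio_ci()]) with the table.
#' @export
expression_association <- function(probes, ann, top_genes, all_genes,
                                   region_filter = NULL) {
  ann2 <- ann[!is.na(ann$gene_symbol) & ann$gene_symbol %in% all_genes, ]
  if (!is.null(region_filter)) {
    ann2 <- ann2[ann2$gene_region %in% region_filter, ]
  }
  in_query <- ann2$probe_id %in% probes
  if (!any(in_query)) stop("empty query: no annotated probes remain")
  in_top <- ann2$gene_symbol %in% top_genes
  t <- table2x2(sum(in_query & in_top), sum(in_query & !in_top),
                sum(!in_query & in_top), sum(!in_query & !in_top))
  odds_ratio_ci(t)
}

#' Probes with extreme cohort-mean 5mC
#'
#' @param mc a `"5mC"` [beta_matrix()].
#' @param mask logical sample mask (NULL = all samples).
#' @param mode `"ge"` selects cohort means `>= threshold`, `"le"` means
#'   `<= threshold` (both inclusive).
#' @param threshold beta cut, default 0.7 for `"ge"` and 0.3 for `"le"`.
#' @return character vector of probe ids.
#' @export
methylation_extreme_probes <- function(mc, mask = NULL, mode = c("ge", "le"),
                                       threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "ge") 0.7 else 0.3
  if (is.null(mask)) mask <- rep(TRUE, ncol(mc))
  if (!any(mask)) stop("mask selects no samples")
  means <- rowMeans(unclass(mc)[, mask, drop = FALSE])
  keep <- if (mode == "ge") means >= threshold else means <= threshold
  rownames(mc)[keep]
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks on ties, Pearson correlation of the ranks, and a two-sided
#' p from `t = r * sqrt((n-2)/(1-r^2))` with `n - 2` df.
#'
#' @param x,y numeric vectors of equal length >= 4 with >= 2 distinct
#'   values each.
#' @return list with `r` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) stop("need >= 4 paired values")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("constant vector in correlation")
  }
  r <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(r) >= 1) return(list(r = r, p_value = 0))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(t_stat), df = n - 2))
}

#' Classify probe-gene pairs into correlation groups 1-4
#'
#' For each query probe whose annotated gene is differentially expressed,
#' the Spearman correlation of its 5hmC (and 5mC) betas with the gene's
#' expression is computed across the samples present on both platforms.
#' Probes with `|r_5hmc| >= rs_threshold` are assigned: Group 1 = positive
#' r and gene up in MT, Group 2 = negative r and up, Group 3 = positive r
#' and down, Group 4 = negative r and down. A 2x2 count table
#' (correlation sign x expression direction) is tested by Fisher's exact
#' test when any expected count is < 5, else chi-square.
#'
#' @param hmc,mc `"5hmC"` and `"5mC"` [beta_matrix()] objects.
#' @param expr gene x sample log2 expression matrix.
#' @param de result of [differential_expression()].
#' @param probes query probe ids.
#' @param ann probe annotation.
#' @param rs_threshold minimum absolute 5hmC correlation (default 0.5).
#' @return list with `records` (one row per retained probe: correlations,
#'   direction, group, gene region), `skipped` (unannotated/unmatched probe
#'   count), `group_counts` (named G1-G4), `count_table` (2x2),
#'   `p_value` and `test` used.
#' @export
classify_groups <- function(hmc, mc, expr, de, probes, ann,
                            rs_threshold = 0.5) {
  shared <- intersect(colnames(hmc), colnames(expr))
  if (length(shared) < 4) stop("need >= 4 samples present on both platforms")
  de_sel <- de[de$selected, ]
  idx <- match(probes, ann$probe_id)
  gene <- ann$gene_symbol[idx]
  usable <- !is.na(idx) & !is.na(gene) & gene %in% de_sel$gene &
    gene %in% rownames(expr)
  skipped <- sum(!usable)
  probes <- probes[usable]; gene <- gene[usable]
  recs <- vector("list", length(probes))
  h <- unclass(hmc)[, shared, drop = FALSE]
  m <- unclass(mc)[, shared, drop = FALSE]
  e <- expr[, shared, drop = FALSE]
  for (i in seq_along(probes)) {
    hv <- h[probes[i], ]; mv <- m[probes[i], ]; ev <- e[gene[i], ]
    if (length(unique(hv)) < 2 || length(unique(ev)) < 2) next
    sh <- spearman_cor(hv, ev)
    sm <- if (length(unique(mv)) < 2) list(r = NA_real_, p_value = NA_real_) else {
      spearman_cor(mv, ev)
    }
    dirn <- de_sel$direction[match(gene[i], de_sel$gene)]
    group <- if (abs(sh$r) < rs_threshold) "NONE" else {
      if (sh$r > 0 && dirn == "UP_MT") "G1"
      else if (sh$r < 0 && dirn == "UP_MT") "G2"
      else if (sh$r > 0 && dirn == "DOWN_MT") "G3"
      else "G4"
    }
    recs[[i]] <- data.frame(
      probe_id = probes[i], gene = gene[i], r_5hmc = sh$r, p_5hmc = sh$p_value,
      r_5mc = sm$r, p_5mc = sm$p_value, gene_direction = dirn, group = group,
      gene_region = ann$gene_region[match(probes[i], ann$probe_id)],
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(records)) records <- data.frame()
  retained <- records[records$group != "NONE", , drop = FALSE]
  counts <- stats::setNames(integer(4), c("G1", "G2", "G3", "G4"))
  if (nrow(retained)) {
    tab <- table(factor(retained$group, levels = names(counts)))
    counts[] <- as.integer(tab)
  }
  ct <- matrix(c(counts["G1"], counts["G3"], counts["G2"], counts["G4"]),
               2, 2, byrow = TRUE,
               dimnames = list(sign = c("positive", "negative"),
                               direction = c("UP_MT", "DOWN_MT")))
  p_value <- NA_real_; test <- NA_character_
  if (sum(ct) > 0 && all(rowSums(ct) > 0) && all(colSums(ct) > 0)) {
    expd <- outer(rowSums(ct), colSums(ct)) / sum(ct)
    if (any(expd < 5)) {
      p_value <- fisher_exact(table2x2(ct[1, 1], ct[1, 2], ct[2, 1], ct[2, 2]))
      test <- "fisher"
    } else {
      res <- chi_square_2xk(ct)
      p_value <- res$p_value
      test <- "chi_square"
    }
  }
  list(records = records, skipped = skipped, group_counts = counts,
       count_table = ct, p_value = p_value, test = test)
}

#' Share of total methylation carried by 5hmC over a gene set
#'
#' Per gene: the mean over its annotated probes of 5hmC and 5mC (per sample
#' or per cohort), and `pct_5hmc = 100 * 5hmC / (5hmC + 5mC)`. Genes whose
#' total methylation is below `min_total` are flagged and excluded from the
#' percentage summaries; the per-sample summary reports min/median/max pct
#' over retained genes.
#'
#' @param hmc,mc channel [beta_matrix()] objects.
#' @param genes gene set (list with `symbols`, or character vector).
#' @param ann probe annotation.
#' @param sheet sample sheet (needed for `level = "per_cohort"`).
#' @param min_total minimum total methylation beta (default 0.3).
#' @param level `"per_sample"` or `"per_cohort"`.
#' @return list with `contributions` (long data.frame: gene, unit,
#'   mean_5hmc, mean_5mc, pct_5hmc, excluded), `summary` (per-unit
#'   min/median/max of retained pct), `missing_genes` (no annotated probe).
#' @export
gcimp_contribution <- function(hmc, mc, genes, ann, sheet = NULL,
                               min_total = 0.3,
                               level = c("per_sample", "per_cohort")) {
  level <- match.arg(level)
  symbols <- if (is.list(genes)) genes$symbols else genes
  probe_sets <- lapply(symbols, function(g) {
    ann$probe_id[!is.na(ann$gene_symbol) & ann$gene_symbol == g &
                   ann$probe_id %in% rownames(hmc)]
  })
  names(probe_sets) <- symbols
  missing_genes <- symbols[lengths(probe_sets) == 0]
  symbols <- setdiff(symbols, missing_genes)
  h <- unclass(hmc); m <- unclass(mc)
  units <- if (level == "per_sample") colnames(hmc) else c("MT", "WT")
  unit_cols <- if (level == "per_sample") {
    stats::setNames(as.list(colnames(hmc)), units)
  } else {
    if (is.null(sheet)) stop("per_cohort level needs a sample sheet")
    list(MT = colnames(hmc)[cohort_mask(hmc, sheet, "MT")],
         WT = colnames(hmc)[cohort_mask(hmc, sheet, "WT")])
  }
  rows <- list()
  for (g in symbols) {
    p <- probe_sets[[g]]
    for (u in units) {
      cols <- unit_cols[[u]]
      mh <- mean(h[p, cols]); mm <- mean(m[p, cols])
      total <- mh + mm
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, unit = u, mean_5hmc = mh, mean_5mc = mm,
        pct_5hmc = if (total >= min_total) 100 * mh / total else NA_real_,
        excluded = total < min_total, stringsAsFactors = FALSE)
    }
  }
  contributions <- do.call(rbind, rows)
  kept <- contributions[!contributions$excluded, , drop = FALSE]
  summary <- do.call(rbind, lapply(units, function(u) {
    v <- kept$pct_5hmc[kept$unit == u]
    data.frame(unit = u, n_genes = length(v),
               min_pct = if (length(v)) min(v) else NA_real_,
               median_pct = if (length(v)) stats::median(v) else NA_real_,
               max_pct = if (length(v)) max(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(contributions = contributions, summary = summary,
       missing_genes = missing_genes)
}

#' Proportion of probes with negative 5hmC-5mC correlation
#'
#' Per probe, the Spearman correlation between its 5hmC and 5mC betas
#' across samples; returns the fraction strictly below zero (zero counts as
#' non-negative) and the number of usable probes. Two probe sets are
#' compared with [two_proportion_z()].
#'
#' @param hmc,mc channel [beta_matrix()] objects.
#' @param probes probe ids to evaluate.
#' @return list with `proportion`, `n`, `n_excluded` (zero-variance).
#' @export
negative_correlation_proportion <- function(hmc, mc, probes) {
  h <- unclass(hmc)[probes, , drop = FALSE]
  m <- unclass(mc)[probes, , drop = FALSE]
  if (ncol(h) < 4) stop("need >= 4 paired samples")
  rh <- apply(h, 1, function(v) length(unique(v)) > 1)
  rm_ <- apply(m, 1, function(v) length(unique(v)) > 1)
  usable <- rh & rm_
  n_excl <- sum(!usable)
  h <- h[usable, , drop = FALSE]; m <- m[usable, , drop = FALSE]
  if (!nrow(h)) stop("no usable probes (all constant)")
  hr <- t(apply(h, 1, rank)); mr <- t(apply(m, 1, rank))
  hr <- hr - rowMeans(hr); mr <- mr - rowMeans(mr)
  r <- rowSums(hr * mr) / sqrt(rowSums(hr^2) * rowSums(mr^2))
  list(proportion = mean(r < 0), n = length(r), n_excluded = n_excl)
}
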