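pipeline_default_config <- function() {
  list(
    inputs = list(sheet = NULL, bs = NULL, oxbs = NULL, annotation = NULL,
                  expression = NULL, geneset = NULL, hmedip_beds = NULL),
    out_dir = NULL,
    clamp_value = 1e-7,
    drop_snp = TRUE, drop_sex = TRUE,
    top_fraction = 0.01,
    max_gap = 1000,
    min_probes = 7, cutoff_quantile = 0.99, cutoff = NULL,
    smooth_window = 3, n_perm = 250, alpha = 0.05,
    enrichment_strata = "cpg_feature",
    k_range = c(2, 6), n_resample = 1000, subsample_fraction = 0.8,
    fc_threshold = 2, de_alpha = 0.05,
    expr_top_fraction = 0.2, rs_threshold = 0.5,
    gcimp_min_total = 0.3, gcimp_level = "per_cohort",
    hmedip_ws = 100, hmedip_extend = 300, hmedip_min_mean = 3,
    hmedip_logfc = 1, universe_size = 20345,
    seed = 1)
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- pipeline_default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  for (k in c("sheet", "bs", "oxbs", "annotation")) {
    if (is.null(cfg$inputs[[k]])) stop("config must set inputs$", k)
  }
  cfg
}

#' Run the full paired BS/OxBS analysis pipeline
#'
#' Executes 5hmC/5mC quantification, top-fraction selection, volcano
#' statistics, DHMR and DMR detection, enhancer enrichment (per annotation
#' source, Cochran-Mantel-Haenszel over the configured strata), consensus
#' clustering of the differential probes unique to one cohort's top set,
#' expression integration (differential expression, correlation groups,
#' methylator-signature 5hmC contribution), and, when read BEDs are given,
#' hMeDIP window arithmetic. Every stage's outputs land under `out_dir`
#' together with `summary.json` (headline numbers) and `manifest.json`
#' (the config echoed verbatim, its hash, the seed and per-stage timing).
#'
#' @param config named list, or path to a YAML/JSON file, with keys from
#'   the documented default set (unknown keys are rejected): input paths
#'   (`inputs$sheet`, `inputs$bs`, `inputs$oxbs`, `inputs$annotation`,
#'   optional `inputs$expression`, `inputs$geneset`, `inputs$hmedip_beds`),
#'   `out_dir`, tuning parameters of each stage, and `seed`.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timing <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  summary <- list(seed = cfg$seed)

  sheet <- read_sample_sheet(cfg$inputs$sheet)
  ann <- read_probe_annotation(cfg$inputs$annotation)
  bs <- read_beta_matrix(cfg$inputs$bs, "BS", sheet)
  oxbs <- read_beta_matrix(cfg$inputs$oxbs, "OxBS", sheet)
  bs <- filter_probes(bs, ann, cfg$drop_snp, cfg$drop_sex)
  oxbs <- filter_probes(oxbs, ann, cfg$drop_snp, cfg$drop_sex)
  tick("load")

  hmc <- compute_5hmc(bs, oxbs, cfg$clamp_value)
  mc <- compute_5mc(oxbs)
  mt_mask <- cohort_mask(hmc, sheet, "MT")
  top_mt <- top_fraction_probes(hmc, mt_mask, cfg$top_fraction, "MT")
  top_wt <- top_fraction_probes(hmc, !mt_mask, cfg$top_fraction, "WT")
  volcano <- volcano_stats(hmc, sheet)
  utils::write.table(volcano, file.path(cfg$out_dir, "volcano.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$mean_5hmc_mt <- mean(unclass(hmc)[, mt_mask])
  summary$mean_5hmc_wt <- mean(unclass(hmc)[, !mt_mask])
  summary$n_top_mt <- length(top_mt$probe_ids)
  summary$n_top_wt <- length(top_wt$probe_ids)
  tick("hydroxy")

  clusters <- cluster_probes(ann[match(rownames(hmc), ann$probe_id), ],
                             cfg$max_gap)
  dhmrs <- bumphunt(hmc, sheet, clusters, min_probes = cfg$min_probes,
                    cutoff_quantile = cfg$cutoff_quantile,
                    cutoff = cfg$cutoff, smooth_window = cfg$smooth_window,
                    n_perm = cfg$n_perm, alpha = cfg$alpha, seed = cfg$seed)
  dmrs <- bumphunt(mc, sheet, clusters, min_probes = cfg$min_probes,
                   cutoff_quantile = cfg$cutoff_quantile,
                   cutoff = cfg$cutoff, smooth_window = cfg$smooth_window,
                   n_perm = cfg$n_perm, alpha = cfg$alpha,
                   seed = cfg$seed + 1L)
  write_regions_bed(file.path(cfg$out_dir, "dhmrs.bed"), dhmrs)
  write_regions_bed(file.path(cfg$out_dir, "dmrs.bed"), dmrs)
  dhmr_genes <- regions_to_genes(dhmrs, ann)
  summary$n_dhmrs <- nrow(dhmrs)
  summary$n_dmrs <- nrow(dmrs)
  summary$n_dhmr_probes <- length(unlist(dhmrs$probe_ids))
  summary$n_dhmr_genes <- nrow(dhmr_genes)
  tick("regions")

  dhmr_probes <- unlist(dhmrs$probe_ids)
  enr <- list()
  for (src in enhancer_sources(ann)) {
    flag_col <- paste0("enh_", src)
    strata <- split(seq_len(nrow(ann)), ann[[cfg$enrichment_strata]])
    for (set_name in c("top_mt", "top_wt", "dhmr")) {
      probes <- switch(set_name, top_mt = top_mt$probe_ids,
                       top_wt = top_wt$probe_ids, dhmr = dhmr_probes)
      if (!length(probes)) next
      tables <- lapply(strata, function(idx) {
        in_set <- ann$probe_id[idx] %in% probes
        in_cat <- ann[[flag_col]][idx]
        table2x2(sum(in_set & in_cat), sum(in_set & !in_cat),
                 sum(!in_set & in_cat), sum(!in_set & !in_cat))
      })
      ok <- vapply(tables, function(t) {
        (t$a + t$b) > 0 && (t$c + t$d) > 0 && (t$a + t$c) > 0 && (t$b + t$d) > 0
      }, TRUE)
      res <- cmh_test(tables[ok])
      enr[[paste(src, set_name, sep = ".")]] <- data.frame(
        source = src, probe_set = set_name, odds_ratio = res$odds_ratio,
        ci_low = res$ci_low, ci_high = res$ci_high, p_value = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  enr_df <- do.call(rbind, enr)
  if (!is.null(enr_df)) {
    utils::write.table(enr_df, file.path(cfg$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tick("enrich")

  cons_probes <- select_consensus_probes(dhmr_probes, top_mt$probe_ids,
                                         top_wt$probe_ids)
  summary$n_consensus_probes <- length(cons_probes)
  if (length(cons_probes) >= 5) {
    cc <- consensus_cluster(unclass(bm_subset(hmc, probes = cons_probes)),
                            k_range = seq(cfg$k_range[1], cfg$k_range[2]),
                            n_resample = cfg$n_resample,
                            subsample_fraction = cfg$subsample_fraction,
                            seed = cfg$seed)
    summary$chosen_k <- cc$chosen_k
    assign_df <- data.frame(sample_id = colnames(hmc),
                            do.call(cbind, cc$assignments))
    names(assign_df)[-1] <- paste0("k", cc$k_values)
    utils::write.table(assign_df, file.path(cfg$out_dir, "cluster_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tick("cluster")

  if (!is.null(cfg$inputs$expression)) {
    expr <- read_expression_matrix(cfg$inputs$expression, sheet)
    expr <- quantile_normalize(expr)
    de <- differential_expression(expr, sheet, cfg$fc_threshold, cfg$de_alpha)
    utils::write.table(de, file.path(cfg$out_dir, "differential_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_de_genes <- sum(de$selected)
    top_genes <- top_expressed_genes(expr, cfg$expr_top_fraction)
    assoc <- expression_association(
      union(top_mt$probe_ids, top_wt$probe_ids), ann, top_genes,
      rownames(expr))
    summary$top_expression_or <- assoc$odds_ratio
    groups <- classify_groups(hmc, mc, expr, de,
                              union(union(top_mt$probe_ids, top_wt$probe_ids),
                                    dhmr_probes),
                              ann, cfg$rs_threshold)
    summary$group_counts <- as.list(groups$group_counts)
    summary$group_test_p <- groups$p_value
    if (nrow(groups$records)) {
      utils::write.table(groups$records,
                         file.path(cfg$out_dir, "correlation_records.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(cfg$inputs$geneset)) {
      gs <- read_gene_set(cfg$inputs$geneset)
      contrib <- gcimp_contribution(hmc, mc, gs, ann, sheet,
                                    cfg$gcimp_min_total, cfg$gcimp_level)
      utils::write.table(contrib$contributions,
                         file.path(cfg$out_dir, "gcimp_contribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$gcimp_pct_range <- list(
        min = min(contrib$summary$min_pct, na.rm = TRUE),
        max = max(contrib$summary$max_pct, na.rm = TRUE))
      gs_probes <- ann$probe_id[!is.na(ann$gene_symbol) &
                                  ann$gene_symbol %in% gs$symbols &
                                  ann$probe_id %in% rownames(hmc)]
      ncp_gs <- negative_correlation_proportion(hmc, mc, gs_probes)
      ncp_all <- negative_correlation_proportion(hmc, mc, rownames(hmc))
      zt <- two_proportion_z(round(ncp_gs$proportion * ncp_gs$n), ncp_gs$n,
                             round(ncp_all$proportion * ncp_all$n), ncp_all$n)
      summary$neg_corr_geneset <- ncp_gs$proportion
      summary$neg_corr_all <- ncp_all$proportion
      summary$neg_corr_z <- zt$z
    }
  } else {
    message("expression input missing: integration stage skipped")
  }
  tick("integrate")

  if (!is.null(cfg$inputs$hmedip_beds) && !is.null(cfg$inputs$annotation)) {
    beds <- cfg$inputs$hmedip_beds
    reads <- lapply(beds, read_bed)
    names(reads) <- sub("\\.bed$", "", basename(unlist(beds)))
    chrom_lengths <- tapply(ann$pos, ann$chrom, max) + 5000L
    wc <- count_windows(reads, chrom_lengths, cfg$hmedip_ws, cfg$hmedip_extend)
    dw <- differential_windows(wc, sheet, cfg$hmedip_min_mean, cfg$hmedip_logfc)
    summary$n_diff_windows <- nrow(dw)
    utils::write.table(dw, file.path(cfg$out_dir, "hmedip_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tick("hmedip")
  }

  summary_path <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config = cfg,
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    timing_s = timing,
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}

# order-independent hash of the config (djb2 over the serialised key=value text)
config_hash <- function(cfg) {
  flat <- unlist(cfg)
  txt <- paste(names(flat)[order(names(flat))],
               flat[order(names(flat))], sep = "=", collapse = ";")
  h <- 5381
  for (ch in utf8ToInt(txt)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
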