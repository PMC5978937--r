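# shared fixtures, all generated in code

tiny_sheet <- function(n_mt = 3, n_wt = 3) {
  data.frame(sample_id = sprintf("S%02d", seq_len(n_mt + n_wt)),
             cohort = factor(rep(c("MT", "WT"), c(n_mt, n_wt)),
                             levels = c("MT", "WT")),
             stringsAsFactors = FALSE)
}

tiny_beta <- function(values, channel = "BS", probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- if (is.null(probes)) sprintf("cg%03d", seq_len(nrow(m))) else probes
  colnames(m) <- if (is.null(samples)) sprintf("S%02d", seq_len(ncol(m))) else samples
  beta_matrix(m, channel)
}

random_beta <- function(n_probes, n_samples, channel = "BS", seed = 1) {
  set.seed(seed)
  tiny_beta(matrix(runif(n_probes * n_samples), n_probes), channel)
}

tiny_annotation <- function(probe_ids, chrom = "chr1",
                            pos = seq(100, by = 200, length.out = length(probe_ids)),
                            gene_symbol = NA_character_,
                            gene_region = "INTERGENIC",
                            cpg_feature = "OPEN_SEA",
                            snp = FALSE, sex = FALSE, enh = FALSE) {
  data.frame(probe_id = probe_ids, chrom = chrom, pos = pos,
             cpg_feature = cpg_feature, gene_region = gene_region,
             gene_symbol = gene_symbol, enh_src1 = enh,
             snp_flag = snp, sex_chrom_flag = sex,
             stringsAsFactors = FALSE)
}

small_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_probes = 2000, n_genes = 120, n_planted_dhmrs = 5,
         n_coupled_genes = 8, n_coupled_neg_genes = 2,
         gcimp_gene_count = 15, n_de_extra = 10, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# independent log-space enumeration oracle for the hypergeometric upper tail
hyper_tail_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  ks <- k:min(K, n)
  logp <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  m <- max(logp)
  exp(m) * sum(exp(logp - m))
}
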