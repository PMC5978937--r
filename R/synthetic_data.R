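#' Simulation configuration for synthetic paired BS/OxBS studies
#'
#' Defaults describe the emulated study: a 12-vs-9 two-cohort design on a
#' 20,000-probe array annotated to 1,000 genes, low genome-wide 5hmC
#' (baseline mean 0.04) over a feature-dependent 5mC background, 20 planted
#' differentially hydroxymethylated regions of 10 probes gaining 0.15 5hmC
#' beta in the MT cohort, a 50-gene methylator-phenotype (G-CIMP-style)
#' promoter hypermethylation signature (+0.3 5mC in MT), 25 genes whose
#' body-probe 5hmC is coupled to expression at correlation 0.9, and planted
#' differential expression at fold change 4.
#'
#' @param n_probes,n_genes array and transcriptome size.
#' @param n_mt,n_wt cohort sizes.
#' @param baseline_5mc_mean named mean 5mC beta per CpG feature class.
#' @param baseline_5hmc_level genome-wide mean 5hmC beta in \[0, 0.1\].
#' @param technical_noise_sd additive Gaussian noise sd applied
#'   independently to the BS and OxBS channels (makes BS < OxBS artifacts).
#' @param bio_noise_sd per-sample biological variation sd on true 5mC.
#' @param n_planted_dhmrs,dhmr_effect,dhmr_effect_range,dhmr_probes_per_region,dhmr_min_probes
#'   planted-region count, MT-cohort 5hmC gain, the relative per-region
#'   effect-size range (each region's gain is `dhmr_effect` times a uniform
#'   draw from this range; heterogeneous magnitudes are what make cohort
#'   profiles separable under correlation distance — set `c(1, 1)` for a
#'   homogeneous effect), probes per region, and the detection floor the
#'   layout must respect.
#' @param gcimp_gene_count,gcimp_5mc_effect methylator-phenotype signature
#'   size and MT promoter 5mC gain.
#' @param n_coupled_genes,n_coupled_neg_genes,coupled_probes_per_gene,coupling_r,coupled_bio_sd
#'   expression-coupled genes: counts of positively coupled genes up in MT
#'   (Group-1-style) and negatively coupled genes down in MT
#'   (Group-4-style), body probes per gene, target correlation magnitude,
#'   and the per-gene biological 5hmC sd that carries the coupling.
#' @param n_de_extra additional planted DE genes (half up, half down in MT).
#' @param expression_fc planted fold change for DE genes (linear scale).
#' @param expr_noise_sd residual log2-expression noise sd.
#' @param enhancer_sources,enhancer_fraction enhancer annotation sources and
#'   the per-source flag probability.
#' @param snp_fraction,sex_fraction fractions of SNP-flagged probes and of
#'   probes placed on a sex chromosome.
#' @param max_gap gap-cluster limit the layout respects (planted regions are
#'   internally within `max_gap` and isolated by more than it).
#' @param cluster_structure `"cohort"` (clusters = cohorts) or
#'   `"three_group"` (an intermediate cluster of `mixed_mt` MT + `mixed_wt`
#'   WT samples carrying half the planted effect).
#' @param mixed_mt,mixed_wt intermediate-cluster composition.
#' @param hmedip_depth,hmedip_read_len,spike_sd hMeDIP read simulation:
#'   Poisson rate multiplier (reads per unit 5hmC beta per probe), read
#'   length, and log-sd of the per-sample spike-in recovery factor.
#' @param seed integer seed; generators derive stage seeds from it.
#' @return classed list of validated settings.
#' @export
sim_config <- function(n_probes = 20000, n_genes = 1000, n_mt = 12, n_wt = 9,
                       baseline_5mc_mean = c(ISLAND = 0.25, SHORE = 0.5,
                                             SHELF = 0.65, OPEN_SEA = 0.75),
                       baseline_5hmc_level = 0.04,
                       technical_noise_sd = 0.02, bio_noise_sd = 0.02,
                       n_planted_dhmrs = 20, dhmr_effect = 0.15,
                       dhmr_effect_range = c(0.5, 1.5),
                       dhmr_probes_per_region = 10, dhmr_min_probes = 7,
                       gcimp_gene_count = 50, gcimp_5mc_effect = 0.3,
                       n_coupled_genes = 25, n_coupled_neg_genes = 5,
                       coupled_probes_per_gene = 4,
                       coupling_r = 0.9, coupled_bio_sd = 0.05,
                       n_de_extra = 50, expression_fc = 4,
                       expr_noise_sd = 0.5,
                       enhancer_sources = c("illumina", "mgg6", "astro"),
                       enhancer_fraction = 0.1,
                       snp_fraction = 0.02, sex_fraction = 0.02,
                       max_gap = 1000,
                       cluster_structure = c("cohort", "three_group"),
                       mixed_mt = 2, mixed_wt = 3,
                       hmedip_depth = 60, hmedip_read_len = 100,
                       spike_sd = 0.2, seed = 1) {
  cfg <- as.list(environment())
  cfg$cluster_structure <- match.arg(cluster_structure)
  if (cfg$baseline_5hmc_level < 0 || cfg$baseline_5hmc_level > 0.1) {
    stop("baseline_5hmc_level must lie in [0, 0.1]")
  }
  if (cfg$dhmr_probes_per_region < cfg$dhmr_min_probes) {
    stop("planted regions must have at least dhmr_min_probes probes")
  }
  if (cfg$n_probes < cfg$n_planted_dhmrs * cfg$dhmr_min_probes) {
    stop("n_probes too small for the requested planted regions")
  }
  special <- cfg$n_planted_dhmrs + cfg$n_coupled_genes +
    cfg$n_coupled_neg_genes + cfg$gcimp_gene_count + cfg$n_de_extra
  if (cfg$n_genes < special) stop("n_genes too small for the planted roles")
  if (cfg$cluster_structure == "three_group" &&
      (cfg$mixed_mt >= cfg$n_mt || cfg$mixed_wt >= cfg$n_wt)) {
    stop("intermediate cluster would absorb a whole cohort")
  }
  structure(cfg, class = "sim_config")
}

#' Deterministic synthetic sample sheet
#' @param cfg a [sim_config()].
#' @return sample-sheet data.frame (`n_mt` MT samples then `n_wt` WT).
#' @export
make_sample_sheet <- function(cfg) {
  n <- cfg$n_mt + cfg$n_wt
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    cohort = factor(rep(c("MT", "WT"), c(cfg$n_mt, cfg$n_wt)),
                    levels = c("MT", "WT")),
    age_years = round(c(seq(26, 54, length.out = cfg$n_mt),
                        seq(37, 77, length.out = cfg$n_wt)), 1),
    who_grade = rep(c("III", "IV"), c(cfg$n_mt, cfg$n_wt)),
    stringsAsFactors = FALSE)
}

# gene roles in layout order: planted-region hosts, expression-coupled,
# methylator-signature, extra DE (up then down), background
gene_roles <- function(cfg) {
  roles <- rep("background", cfg$n_genes)
  i <- 1
  take <- function(k) { out <- seq(i, length.out = k); i <<- i + k; out }
  roles[take(cfg$n_planted_dhmrs)] <- "dhmr"
  roles[take(cfg$n_coupled_genes)] <- "coupled"
  roles[take(cfg$n_coupled_neg_genes)] <- "coupled_neg"
  roles[take(cfg$gcimp_gene_count)] <- "gcimp"
  roles[take(ceiling(cfg$n_de_extra / 2))] <- "de_up"
  roles[take(floor(cfg$n_de_extra / 2))] <- "de_down"
  roles
}

#' Generate a synthetic probe annotation manifest
#'
#' Lays probes on four autosomes plus `chrX`, giving every gene one
#' promoter probe and at least three body probes. Planted-region host genes
#' carry a body-probe block that forms its own gap-cluster: internal
#' spacing well under `max_gap`, isolated from all other probes by more
#' than `max_gap`. Enhancer flags, SNP flags and CpG features are drawn at
#' configurable rates. Attributes `genes` (gene intervals and roles),
#' `planted_regions` (probe ids per region) and `chrom_lengths` support the
#' downstream generators.
#'
#' @param cfg a [sim_config()].
#' @return annotation data.frame as read by [read_probe_annotation()].
#' @export
generate_manifest <- function(cfg) {
  set.seed(cfg$seed)
  roles <- gene_roles(cfg)
  body_n <- ifelse(roles == "dhmr", cfg$dhmr_probes_per_region,
                   ifelse(roles %in% c("coupled", "coupled_neg"),
                          cfg$coupled_probes_per_gene, 3L))
  gene_probe_total <- sum(body_n) + cfg$n_genes
  n_sex <- round(cfg$sex_fraction * cfg$n_probes)
  n_intergenic <- cfg$n_probes - gene_probe_total - n_sex
  if (n_intergenic < 0) {
    stop("layout impossible: gene probes exceed n_probes under constraints")
  }
  autosomes <- paste0("chr", 1:4)
  gene_chrom <- rep(autosomes, length.out = cfg$n_genes)

  rows <- vector("list", cfg$n_genes + 1L)
  inter_rows <- vector("list", cfg$n_genes)
  cursor <- stats::setNames(rep(1L, 5), c(autosomes, "chrX"))
  inter_per_gene <- floor(n_intergenic / cfg$n_genes)
  inter_left <- n_intergenic
  genes <- data.frame(gene_symbol = sprintf("GENE%04d", seq_len(cfg$n_genes)),
                      chrom = gene_chrom, start = NA_integer_,
                      end = NA_integer_, role = roles,
                      stringsAsFactors = FALSE)
  planted <- list()
  cpg_props <- c(ISLAND = 0.15, SHORE = 0.25, SHELF = 0.2, OPEN_SEA = 0.4)
  feat_draw <- function(k) {
    sample(names(cpg_props), k, replace = TRUE, prob = cpg_props)
  }
  big_gap <- function() cfg$max_gap + sample(500:2000, 1)

  for (g in seq_len(cfg$n_genes)) {
    ch <- gene_chrom[g]
    pos <- cursor[ch] + big_gap()
    prom_pos <- pos
    # planted hosts: isolate the body block from the promoter as well
    body_gap0 <- if (roles[g] == "dhmr") big_gap() else sample(200:400, 1)
    body_pos <- prom_pos + body_gap0 +
      cumsum(c(0, sample(50:300, body_n[g] - 1, replace = TRUE)))
    p_ids <- sprintf("cg%07d", g * 1000L + seq_len(body_n[g] + 1L))
    prom_feat <- if (roles[g] == "gcimp") "ISLAND" else {
      sample(c("ISLAND", "SHORE"), 1, prob = c(0.6, 0.4))
    }
    gene_rows <- data.frame(
      probe_id = p_ids,
      chrom = ch,
      pos = c(prom_pos, body_pos),
      cpg_feature = c(prom_feat, feat_draw(body_n[g])),
      gene_region = c("TSS200",
                      sample(c("BODY", "INTRON"), body_n[g], replace = TRUE)),
      gene_symbol = genes$gene_symbol[g],
      stringsAsFactors = FALSE)
    rows[[g]] <- gene_rows
    genes$start[g] <- prom_pos - 200L
    genes$end[g] <- max(body_pos) + 200L
    if (roles[g] == "dhmr") planted[[length(planted) + 1L]] <- p_ids[-1]
    cursor[ch] <- max(body_pos)
    # trailing intergenic block for this chromosome
    k <- min(inter_per_gene, inter_left)
    if (g == cfg$n_genes) k <- inter_left
    if (k > 0) {
      ipos <- cursor[ch] + big_gap() +
        cumsum(c(0, sample(100:900, k - 1, replace = TRUE)))
      inter_rows[[g]] <- data.frame(
        probe_id = sprintf("ig%07d", n_intergenic - inter_left + seq_len(k)),
        chrom = ch, pos = ipos, cpg_feature = feat_draw(k),
        gene_region = "INTERGENIC", gene_symbol = NA_character_,
        stringsAsFactors = FALSE)
      inter_left <- inter_left - k
      cursor[ch] <- max(ipos)
    }
  }
  rows <- c(rows, inter_rows)
  if (n_sex > 0) {
    xpos <- cumsum(sample(100:900, n_sex, replace = TRUE)) + 10000L
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = sprintf("cx%07d", seq_len(n_sex)), chrom = "chrX",
      pos = xpos, cpg_feature = feat_draw(n_sex),
      gene_region = "INTERGENIC", gene_symbol = NA_character_,
      stringsAsFactors = FALSE)
    cursor["chrX"] <- max(xpos)
  }
  ann <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  ann <- ann[order(ann$chrom, ann$pos), , drop = FALSE]
  rownames(ann) <- NULL
  ann$snp_flag <- runif(nrow(ann)) < cfg$snp_fraction
  ann$sex_chrom_flag <- ann$chrom == "chrX"
  # keep planted regions and their host genes clean of removable probes
  protected <- ann$gene_symbol %in% genes$gene_symbol[roles != "background"]
  ann$snp_flag[which(protected)] <- FALSE
  for (src in cfg$enhancer_sources) {
    ann[[paste0("enh_", src)]] <- runif(nrow(ann)) < cfg$enhancer_fraction
  }
  ann <- ann[, c("probe_id", "chrom", "pos", "cpg_feature", "gene_region",
                 "gene_symbol", paste0("enh_", cfg$enhancer_sources),
                 "snp_flag", "sex_chrom_flag")]
  names(planted) <- sprintf("planted_%03d", seq_along(planted))
  attr(ann, "genes") <- genes
  attr(ann, "planted_regions") <- planted
  attr(ann, "chrom_lengths") <- cursor + 5000L
  ann
}

#' Generate paired BS/OxBS beta matrices with planted ground truth
#'
#' True per-sample 5mC and 5hmC surfaces are drawn per probe, then the two
#' channels are formed as `OxBS = clip(5mC + noise)` and
#' `BS = clip(5mC + 5hmC + noise)` with channel-independent technical noise,
#' so a nonzero fraction of probes shows the negative-difference artifact of
#' real OxBS data. MT samples gain `dhmr_effect` 5hmC inside planted
#' regions (half of it in the intermediate cluster under the
#' `"three_group"` structure), methylator-signature promoters gain
#' `gcimp_5mc_effect` 5mC, and coupled body probes receive per-sample
#' biological 5hmC variation that later drives expression coupling.
#'
#' @param manifest result of [generate_manifest()].
#' @param sheet sample sheet (see [make_sample_sheet()]).
#' @param cfg the [sim_config()] used for the manifest.
#' @return list with `bs` and `oxbs` [beta_matrix()] objects and `truth`
#'   (planted regions, signature genes, coupled probes, DE genes, cluster
#'   labels, and the true per-sample 5hmC of coupled probes).
#' @export
generate_paired_betas <- function(manifest, sheet, cfg) {
  set.seed(cfg$seed + 1L)
  genes <- attr(manifest, "genes")
  planted <- attr(manifest, "planted_regions")
  n_p <- nrow(manifest); n_s <- nrow(sheet)
  mt <- sheet$cohort == "MT"

  cluster_labels <- ifelse(mt, 1L, 3L)
  if (cfg$cluster_structure == "three_group") {
    mixed <- c(utils::tail(which(mt), cfg$mixed_mt),
               utils::tail(which(!mt), cfg$mixed_wt))
    cluster_labels[mixed] <- 2L
  } else {
    cluster_labels <- ifelse(mt, 1L, 2L)
    mixed <- integer()
  }

  mu_m <- cfg$baseline_5mc_mean[manifest$cpg_feature]
  conc <- 10
  m_probe <- rbeta(n_p, mu_m * conc, (1 - mu_m) * conc)
  # probes carrying planted 5hmC signal sit at moderate 5mC so the planted
  # hydroxymethylation has headroom below total methylation 1
  plant_lowm <- manifest$probe_id %in% unlist(planted)
  m_probe[plant_lowm] <- rbeta(sum(plant_lowm), 0.5 * conc, 0.5 * conc)
  hmu <- cfg$baseline_5hmc_level
  h_probe <- if (hmu > 0) rbeta(n_p, 0.5, 0.5 * (1 - hmu) / hmu) else rep(0, n_p)

  gcimp_genes <- genes$gene_symbol[genes$role == "gcimp"]
  # methylator-signature genes carry appreciable 5hmC (the emulated study
  # reports 5hmC shares of 7-18% of their total methylation), so their
  # probes sit well clear of the negative-difference clamp
  gc_all <- manifest$gene_symbol %in% gcimp_genes
  h_probe[gc_all] <- rbeta(sum(gc_all), 0.08 * 30, 0.92 * 30)
  gcimp_prom <- manifest$gene_symbol %in% gcimp_genes &
    manifest$gene_region == "TSS200"
  coupled_genes <- genes$gene_symbol[genes$role == "coupled"]
  coupled_neg_genes <- genes$gene_symbol[genes$role == "coupled_neg"]
  coupled_mask <- manifest$gene_symbol %in% c(coupled_genes, coupled_neg_genes) &
    manifest$gene_region %in% c("BODY", "INTRON")
  planted_mask <- manifest$probe_id %in% unlist(planted)

  # per-sample true surfaces
  m_true <- matrix(m_probe, n_p, n_s) +
    matrix(rnorm(n_p * n_s, 0, cfg$bio_noise_sd), n_p, n_s)
  m_true[gcimp_prom, mt] <- m_true[gcimp_prom, mt] + cfg$gcimp_5mc_effect

  effect_frac <- ifelse(cluster_labels == 1L, 1,
                        ifelse(cluster_labels == 2L &
                                 cfg$cluster_structure == "three_group", 0.5, 0))
  h_true <- matrix(h_probe, n_p, n_s)
  region_mult <- runif(length(planted), cfg$dhmr_effect_range[1],
                       cfg$dhmr_effect_range[2])
  region_effect <- cfg$dhmr_effect * region_mult
  for (i in seq_along(planted)) {
    rows_i <- match(planted[[i]], manifest$probe_id)
    h_true[rows_i, ] <- h_true[rows_i, ] +
      region_effect[i] * rep(effect_frac, each = length(rows_i))
  }
  # coupled probes: elevated base, cohort effect, and per-gene biological
  # variation shared by a gene's probes (small per-probe jitter on top), so
  # every probe of a coupled gene tracks the same latent 5hmC signal
  c_idx <- which(coupled_mask)
  m_probe[c_idx] <- rbeta(length(c_idx), 0.3 * conc, 0.7 * conc)
  m_true[c_idx, ] <- matrix(m_probe[c_idx], length(c_idx), n_s) +
    matrix(rnorm(length(c_idx) * n_s, 0, cfg$bio_noise_sd), length(c_idx), n_s)
  c_gene <- manifest$gene_symbol[c_idx]
  for (g in unique(c_gene)) {
    rows_g <- c_idx[c_gene == g]
    latent <- rnorm(n_s, 0, cfg$coupled_bio_sd)
    h_true[rows_g, ] <- 0.15 +
      cfg$dhmr_effect * rep(as.numeric(mt), each = length(rows_g)) +
      rep(latent, each = length(rows_g)) +
      matrix(rnorm(length(rows_g) * n_s, 0, 0.01), length(rows_g), n_s)
  }
  m_true <- pmin(pmax(m_true, 0), 1)
  h_true <- pmin(pmax(h_true, 0), 1 - m_true)  # total methylation cannot exceed 1

  noise1 <- matrix(rnorm(n_p * n_s, 0, cfg$technical_noise_sd), n_p, n_s)
  noise2 <- matrix(rnorm(n_p * n_s, 0, cfg$technical_noise_sd), n_p, n_s)
  bs <- pmin(pmax(m_true + h_true + noise1, 0), 1)
  oxbs <- pmin(pmax(m_true + noise2, 0), 1)
  dimnames(bs) <- dimnames(oxbs) <- list(manifest$probe_id, sheet$sample_id)

  if (length(planted)) {
    planted_df <- data.frame(
      region_id = names(planted),
      chrom = vapply(planted, function(p) {
        manifest$chrom[match(p[1], manifest$probe_id)]
      }, ""),
      start = vapply(planted, function(p) {
        min(manifest$pos[match(p, manifest$probe_id)])
      }, 0),
      end = vapply(planted, function(p) {
        max(manifest$pos[match(p, manifest$probe_id)])
      }, 0),
      sign = 1, effect = region_effect, stringsAsFactors = FALSE)
    planted_df$probe_ids <- unname(planted)
  } else {
    planted_df <- data.frame(region_id = character(), chrom = character(),
                             start = numeric(), end = numeric(),
                             sign = numeric(), effect = numeric(),
                             stringsAsFactors = FALSE)
    planted_df$probe_ids <- list()
  }

  coupled_df <- data.frame(
    probe_id = manifest$probe_id[coupled_mask],
    gene = manifest$gene_symbol[coupled_mask],
    group = ifelse(manifest$gene_symbol[coupled_mask] %in% coupled_genes,
                   1L, 4L),
    stringsAsFactors = FALSE)
  de_block <- function(g, dir) {
    data.frame(gene = g, direction = rep(dir, length(g)),
               fold_change = rep(cfg$expression_fc, length(g)),
               stringsAsFactors = FALSE)
  }
  de_df <- rbind(
    de_block(coupled_genes, "UP_MT"),
    de_block(coupled_neg_genes, "DOWN_MT"),
    de_block(genes$gene_symbol[genes$role == "de_up"], "UP_MT"),
    de_block(genes$gene_symbol[genes$role == "de_down"], "DOWN_MT"))

  coupled_h <- h_true[coupled_mask, , drop = FALSE]
  rownames(coupled_h) <- manifest$probe_id[coupled_mask]
  colnames(coupled_h) <- sheet$sample_id

  truth <- list(
    planted_dhmrs = planted_df,
    planted_gcimp_genes = gcimp_genes,
    planted_coupled_probes = coupled_df,
    planted_de_genes = de_df,
    cluster_labels = stats::setNames(cluster_labels, sheet$sample_id),
    coupled_h = coupled_h,
    gcimp_true_contribution = NULL)
  # record the planted per-gene 5hmC share of total methylation (MT cohort)
  gc_probes <- manifest$gene_symbol %in% gcimp_genes
  gmeans <- function(x) {
    tapply(rowMeans(x[gc_probes, mt, drop = FALSE]),
           manifest$gene_symbol[gc_probes], mean)
  }
  gh <- gmeans(h_true); gm <- gmeans(m_true)
  truth$gcimp_true_contribution <- data.frame(
    gene = names(gh), mean_5hmc = as.numeric(gh), mean_5mc = as.numeric(gm),
    pct_5hmc = 100 * as.numeric(gh) / (as.numeric(gh) + as.numeric(gm)),
    stringsAsFactors = FALSE)

  list(bs = beta_matrix(bs, "BS"), oxbs = beta_matrix(oxbs, "OxBS"),
       truth = truth)
}

#' Generate a log2 expression matrix with planted DE and 5hmC coupling
#'
#' Planted DE genes receive a cohort shift of `log2(expression_fc)`;
#' coupled genes are generated from the recorded true body-probe 5hmC so
#' that the expression-5hmC correlation targets `coupling_r` while the
#' cohort fold change targets `expression_fc`.
#'
#' @param manifest result of [generate_manifest()].
#' @param truth truth list from [generate_paired_betas()].
#' @param sheet sample sheet.
#' @param cfg the [sim_config()].
#' @return gene x sample numeric matrix of log2 expression.
#' @export
generate_expression <- function(manifest, truth, sheet, cfg) {
  if (cfg$coupling_r <= 0 || cfg$coupling_r >= 1) {
    stop("coupling_r must lie in (0, 1)")
  }
  set.seed(cfg$seed + 2L)
  genes <- attr(manifest, "genes")
  n_g <- nrow(genes); n_s <- nrow(sheet)
  mt <- sheet$cohort == "MT"
  base <- rnorm(n_g, 7, 1.5)
  expr <- matrix(base, n_g, n_s) +
    matrix(rnorm(n_g * n_s, 0, cfg$expr_noise_sd), n_g, n_s)
  dimnames(expr) <- list(genes$gene_symbol, sheet$sample_id)
  half <- log2(cfg$expression_fc) / 2
  up <- genes$role == "de_up"; down <- genes$role == "de_down"
  expr[up, mt] <- expr[up, mt] + half
  expr[up, !mt] <- expr[up, !mt] - half
  expr[down, mt] <- expr[down, mt] - half
  expr[down, !mt] <- expr[down, !mt] + half

  r <- cfg$coupling_r
  for (g in which(genes$role %in% c("coupled", "coupled_neg"))) {
    gsym <- genes$gene_symbol[g]
    sign_g <- if (genes$role[g] == "coupled") 1 else -1
    probes <- truth$planted_coupled_probes$probe_id[
      truth$planted_coupled_probes$gene == gsym]
    h <- colMeans(truth$coupled_h[probes, , drop = FALSE])
    z_h <- as.numeric(scale(h))
    d <- mean(z_h[mt]) - mean(z_h[!mt])
    scale_c <- if (d > 0) 2 * half / (r * d) else 1
    expr[g, ] <- base[g] +
      sign_g * scale_c * (r * z_h + sqrt(1 - r^2) * rnorm(n_s))
  }
  expr
}

#' Simulate hMeDIP read intervals with spike-in recovery factors
#'
#' Per sample, reads are drawn around probe positions with Poisson rates
#' proportional to the cohort-level true 5hmC (baseline plus planted
#' effect), scaled by a per-sample log-normal spike-in recovery factor.
#'
#' @param manifest result of [generate_manifest()].
#' @param truth truth list from [generate_paired_betas()].
#' @param sheet sample sheet.
#' @param cfg the [sim_config()].
#' @return list with `reads` (named list of per-sample BED-style
#'   data.frames: chrom, start 0-based, end half-open) and `spike_factors`.
#' @export
generate_hmedip_reads <- function(manifest, truth, sheet, cfg) {
  set.seed(cfg$seed + 3L)
  n_p <- nrow(manifest)
  mt <- sheet$cohort == "MT"
  hmu <- cfg$baseline_5hmc_level
  h_base <- if (hmu > 0) rep(hmu, n_p) else rep(0, n_p)
  planted_mask <- manifest$probe_id %in% unlist(attr(manifest, "planted_regions"))
  chrom_len <- attr(manifest, "chrom_lengths")
  spike <- rlnorm(nrow(sheet), 0, cfg$spike_sd)
  names(spike) <- sheet$sample_id
  reads <- vector("list", nrow(sheet))
  names(reads) <- sheet$sample_id
  for (s in seq_len(nrow(sheet))) {
    h <- h_base
    if (mt[s]) h[planted_mask] <- h[planted_mask] + cfg$dhmr_effect
    lambda <- cfg$hmedip_depth * h * spike[s]
    counts <- rpois(n_p, lambda)
    if (sum(counts) == 0) {
      reads[[s]] <- data.frame(chrom = character(), start = integer(),
                               end = integer(), stringsAsFactors = FALSE)
      next
    }
    idx <- rep.int(seq_len(n_p), counts)
    jitter <- sample(-50:50, length(idx), replace = TRUE)
    start <- pmax(manifest$pos[idx] - 1L + jitter, 0L)
    maxlen <- chrom_len[manifest$chrom[idx]]
    end <- pmin(start + cfg$hmedip_read_len, maxlen)
    ord <- order(manifest$chrom[idx], start)
    reads[[s]] <- data.frame(chrom = manifest$chrom[idx][ord],
                             start = start[ord], end = end[ord],
                             stringsAsFactors = FALSE)
  }
  list(reads = reads, spike_factors = spike)
}

#' Generate and write a complete synthetic study to disk
#'
#' Emits the exact file formats the readers consume: sample sheet CSV,
#' BS/OxBS beta TSVs, probe annotation TSV, expression TSV, the
#' methylator-signature gene set, per-sample hMeDIP BEDs (optional) and a
#' `truth.json` recording everything planted.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @param include_hmedip also simulate and write hMeDIP reads (default
#'   FALSE; they are bulky).
#' @return invisible list of file `paths` plus in-memory `manifest`,
#'   `sheet`, `bs`, `oxbs`, `expr`, `truth`.
#' @export
simulate_study <- function(cfg, dir, include_hmedip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- make_sample_sheet(cfg)
  manifest <- generate_manifest(cfg)
  pb <- generate_paired_betas(manifest, sheet, cfg)
  expr <- generate_expression(manifest, pb$truth, sheet, cfg)
  paths <- list(
    sheet = file.path(dir, "samples.csv"),
    bs = file.path(dir, "beta_bs.tsv"),
    oxbs = file.path(dir, "beta_oxbs.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    expression = file.path(dir, "expression.tsv"),
    gcimp = file.path(dir, "gcimp_genes.txt"),
    truth = file.path(dir, "truth.json"))
  utils::write.csv(sheet, paths$sheet, row.names = FALSE, quote = FALSE)
  write_beta_matrix(pb$bs, paths$bs)
  write_beta_matrix(pb$oxbs, paths$oxbs)
  ann_out <- manifest
  attributes(ann_out)[c("genes", "planted_regions", "chrom_lengths")] <- NULL
  utils::write.table(ann_out, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expr_df <- data.frame(gene_symbol = rownames(expr), expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr_df, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(pb$truth$planted_gcimp_genes, paths$gcimp)
  truth_json <- pb$truth
  truth_json$coupled_h <- NULL
  truth_json$planted_dhmrs$probe_ids <- NULL
  truth_json$planted_probe_ids <- attr(manifest, "planted_regions")
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  hmedip <- NULL
  if (include_hmedip) {
    hmedip <- generate_hmedip_reads(manifest, pb$truth, sheet, cfg)
    bed_dir <- file.path(dir, "hmedip")
    dir.create(bed_dir, showWarnings = FALSE)
    paths$hmedip <- vapply(names(hmedip$reads), function(s) {
      p <- file.path(bed_dir, paste0(s, ".bed"))
      r <- hmedip$reads[[s]]
      writeLines(sprintf("%s\t%d\t%d", r$chrom, r$start, r$end), p)
      p
    }, "")
  }
  invisible(list(paths = paths, manifest = manifest, sheet = sheet,
                 bs = pb$bs, oxbs = pb$oxbs, expr = expr, truth = pb$truth,
                 hmedip = hmedip))
}
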