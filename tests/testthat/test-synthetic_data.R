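test_that("generators are deterministic under a fixed seed", {
  cfg <- small_sim(seed = 5)
  sheet <- make_sample_sheet(cfg)
  m1 <- generate_manifest(cfg)
  m2 <- generate_manifest(cfg)
  expect_identical(m1, m2)
  p1 <- generate_paired_betas(m1, sheet, cfg)
  p2 <- generate_paired_betas(m1, sheet, cfg)
  expect_identical(unclass(p1$bs), unclass(p2$bs))
  expect_identical(unclass(p1$oxbs), unclass(p2$oxbs))
  e1 <- generate_expression(m1, p1$truth, sheet, cfg)
  e2 <- generate_expression(m1, p2$truth, sheet, cfg)
  expect_identical(e1, e2)
  r1 <- generate_hmedip_reads(m1, p1$truth, sheet, cfg)
  r2 <- generate_hmedip_reads(m1, p1$truth, sheet, cfg)
  expect_identical(r1, r2)
})

test_that("manifest layout isolates planted regions and covers gene structure", {
  cfg <- small_sim(seed = 2)
  man <- generate_manifest(cfg)
  expect_equal(nrow(man), cfg$n_probes)
  expect_false(anyDuplicated(man$probe_id) > 0)

  cl <- cluster_probes(man, cfg$max_gap)
  planted <- attr(man, "planted_regions")
  expect_length(planted, cfg$n_planted_dhmrs)
  for (p in planted) {
    cids <- unique(cl$cluster_id[match(p, cl$probe_id)])
    expect_length(cids, 1)                       # internally one gap-cluster
    members <- cl$probe_id[cl$cluster_id == cids]
    expect_setequal(members, p)                  # isolated from other probes
  }

  genes <- attr(man, "genes")
  per_gene <- split(man$gene_region, man$gene_symbol)
  expect_true(all(vapply(per_gene, function(r) sum(r == "TSS200") >= 1, TRUE)))
  expect_true(all(vapply(per_gene,
                         function(r) sum(r %in% c("BODY", "INTRON")) >= 3, TRUE)))

  # enhancer flag rate within the binomial 99% interval
  for (src in cfg$enhancer_sources) {
    frac <- mean(man[[paste0("enh_", src)]])
    bound <- 2.576 * sqrt(0.1 * 0.9 / nrow(man))
    expect_lt(abs(frac - cfg$enhancer_fraction), bound + 1e-9)
  }
})

test_that("noise-free channels reproduce true 5hmC exactly and noise is symmetric", {
  cfg0 <- small_sim(seed = 3, technical_noise_sd = 0, bio_noise_sd = 0,
                    n_planted_dhmrs = 0, dhmr_effect = 0,
                    gcimp_gene_count = 0, gcimp_5mc_effect = 0,
                    n_coupled_genes = 2, n_coupled_neg_genes = 1,
                    baseline_5hmc_level = 0.05)
  sheet <- make_sample_sheet(cfg0)
  man <- generate_manifest(cfg0)
  pb <- generate_paired_betas(man, sheet, cfg0)
  d <- unclass(pb$bs) - unclass(pb$oxbs)
  expect_true(all(d >= 0))         # no artifact without technical noise

  # with noise and zero 5hmC, about half the cells go negative
  cfg1 <- small_sim(seed = 3, technical_noise_sd = 0.02, baseline_5hmc_level = 0,
                    n_planted_dhmrs = 0, dhmr_effect = 0, gcimp_gene_count = 0,
                    gcimp_5mc_effect = 0, n_coupled_genes = 2,
                    n_coupled_neg_genes = 1)
  pb1 <- generate_paired_betas(man, sheet, cfg1)
  keep <- !rownames(pb1$bs) %in% pb1$truth$planted_coupled_probes$probe_id
  d1 <- (unclass(pb1$bs) - unclass(pb1$oxbs))[keep, ]
  frac_neg <- mean(d1 < 0)
  n_cells <- length(d1)
  expect_lt(abs(frac_neg - 0.5), 3 * sqrt(0.25 / n_cells) + 0.02)
})

test_that("planted expression coupling and fold changes are realised", {
  cfg <- small_sim(seed = 8, coupling_r = 0.95)
  sheet <- make_sample_sheet(cfg)
  man <- generate_manifest(cfg)
  pb <- generate_paired_betas(man, sheet, cfg)
  expr <- generate_expression(man, pb$truth, sheet, cfg)
  cp <- pb$truth$planted_coupled_probes
  r <- mapply(function(p, g) {
    cor(rank(pb$truth$coupled_h[p, ]), rank(expr[g, ]))
  }, cp$probe_id, cp$gene)
  signs <- ifelse(cp$group == 1L, 1, -1)
  expect_gte(mean(r * signs >= 0.5), 0.95)

  # planted pure-DE genes realise the requested mean log2 difference
  mt <- sheet$cohort == "MT"
  de_extra <- setdiff(pb$truth$planted_de_genes$gene, cp$gene)
  diffs <- rowMeans(expr[de_extra, mt]) - rowMeans(expr[de_extra, !mt])
  dirs <- pb$truth$planted_de_genes$direction[
    match(de_extra, pb$truth$planted_de_genes$gene)]
  expected <- ifelse(dirs == "UP_MT", 1, -1) * log2(cfg$expression_fc)
  expect_lt(max(abs(diffs - expected)),
            4 * cfg$expr_noise_sd / sqrt(min(sum(mt), sum(!mt))) + 0.2)
  expect_error(
    generate_expression(man, pb$truth, sheet,
                        utils::modifyList(cfg, list(coupling_r = 1.5))),
    "coupling_r")
})

test_that("hMeDIP reads respond to planted enrichment and zero rate gives no reads", {
  cfg <- small_sim(seed = 6, n_probes = 1000, n_genes = 60,
                   n_planted_dhmrs = 3, gcimp_gene_count = 5, n_de_extra = 5,
                   hmedip_depth = 100)
  sheet <- make_sample_sheet(cfg)
  man <- generate_manifest(cfg)
  pb <- generate_paired_betas(man, sheet, cfg)
  hm <- generate_hmedip_reads(man, pb$truth, sheet, cfg)
  expect_length(hm$reads, nrow(sheet))
  wc <- count_windows(hm$reads, attr(man, "chrom_lengths"))
  dw <- differential_windows(wc, sheet)
  planted_pos <- man$pos[man$probe_id %in% unlist(attr(man, "planted_regions"))]
  hits <- vapply(planted_pos, function(p) {
    any(dw$window_start < p & dw$window_end >= p & dw$log_fc > 1)
  }, TRUE)
  expect_gt(mean(hits), 0.5)

  cfg0 <- utils::modifyList(cfg, list(hmedip_depth = 0, baseline_5hmc_level = 0))
  hm0 <- generate_hmedip_reads(man, pb$truth, sheet, cfg0)
  expect_equal(sum(vapply(hm0$reads, nrow, 0L)), 0)
})

test_that("a written study round-trips through the readers consistently", {
  cfg <- small_sim(seed = 12, n_probes = 800, n_genes = 60,
                   n_planted_dhmrs = 2, gcimp_gene_count = 5, n_de_extra = 4)
  dir <- withr::local_tempdir()
  sim <- simulate_study(cfg, dir)
  sheet <- read_sample_sheet(sim$paths$sheet)
  expect_equal(as.integer(table(sheet$cohort)), c(cfg$n_mt, cfg$n_wt))
  bs <- read_beta_matrix(sim$paths$bs, "BS", sheet)
  expect_equal(unclass(bs), unclass(sim$bs), tolerance = 1e-12)
  ann <- read_probe_annotation(sim$paths$annotation)
  expect_setequal(ann$probe_id, rownames(bs))
  truth <- jsonlite::read_json(sim$paths$truth, simplifyVector = TRUE)
  expect_true(all(unlist(truth$planted_probe_ids) %in% ann$probe_id))
  gs <- read_gene_set(sim$paths$gcimp)
  expect_setequal(gs$symbols, sim$truth$planted_gcimp_genes)
})
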