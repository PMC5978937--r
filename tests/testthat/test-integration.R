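test_that("quantile normalisation forces identical column distributions", {
  m <- cbind(a = c(1, 3), b = c(2, 4))
  rownames(m) <- c("g1", "g2")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(1.5, 3.5), c(1.5, 3.5)))

  same <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
  rownames(same) <- paste0("g", 1:3)
  expect_equal(quantile_normalize(same), same)

  set.seed(3)
  r <- matrix(rnorm(200), 50, dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  qr <- quantile_normalize(r)
  sorted <- apply(qr, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
})

test_that("differential expression requires both fold change and adjusted p", {
  sheet <- tiny_sheet(5, 5)
  set.seed(21)
  base <- matrix(rnorm(30 * 10, 6, 0.2), 30,
                 dimnames = list(sprintf("g%02d", 1:30), sheet$sample_id))
  de0 <- differential_expression(base, sheet)
  expect_equal(sum(de0$selected), 0)  # near-identical cohorts

  planted <- base
  planted["g01", sheet$cohort == "MT"] <- planted["g01", sheet$cohort == "MT"] + 2
  de1 <- differential_expression(planted, sheet)
  expect_true(de1$selected[de1$gene == "g01"])
  expect_equal(de1$direction[de1$gene == "g01"], "UP_MT")

  # strong fold change but hopeless p: not selected
  noisy <- base
  noisy["g02", ] <- rnorm(10, 6, 4)
  noisy["g02", sheet$cohort == "MT"] <- noisy["g02", sheet$cohort == "MT"] + 1.6
  de2 <- differential_expression(noisy, sheet)
  row2 <- de2[de2$gene == "g02", ]
  if (row2$fold_change > 2 && row2$adj_p > 0.05) expect_false(row2$selected)

  swapped <- sheet
  swapped$cohort <- factor(ifelse(sheet$cohort == "MT", "WT", "MT"),
                           levels = c("MT", "WT"))
  de_sw <- differential_expression(planted, swapped)
  expect_equal(de_sw$fold_change, de1$fold_change)
  expect_equal(de_sw$direction[de_sw$gene == "g01"], "DOWN_MT")
})

test_that("top expressed genes equal brute-force sort-and-slice", {
  set.seed(10)
  m <- matrix(rnorm(100 * 6, 7, 2), 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:6)))
  top <- top_expressed_genes(m, 0.2)
  expect_length(top, 20)
  expect_setequal(top, names(sort(rowMeans(m), decreasing = TRUE))[1:20])
  expect_length(top_expressed_genes(m, 1), 100)
})

test_that("expression association builds the right table and flags empty queries", {
  ann <- tiny_annotation(sprintf("p%02d", 1:40),
                         gene_symbol = rep(sprintf("g%02d", 1:20), each = 2),
                         gene_region = rep(c("BODY", "TSS200"), 20))
  top <- sprintf("g%02d", 1:5)
  universe <- sprintf("g%02d", 1:20)
  # query probes all target top genes
  query <- ann$probe_id[ann$gene_symbol %in% top]
  res <- expression_association(query, ann, top, universe)
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p_value, 0.05)
  t <- res$tables[[1]]
  expect_equal(t$a, 10); expect_equal(t$b, 0)
  expect_equal(t$c, 0); expect_equal(t$d, 30)

  res_body <- expression_association(query, ann, top, universe,
                                     region_filter = "BODY")
  expect_equal(res_body$tables[[1]]$a, 5)
  expect_error(
    expression_association(query, ann, top, universe,
                           region_filter = "THREE_UTR"),
    "empty query")
})

test_that("extreme-methylation probe selection is inclusive and matches a filter oracle", {
  v <- matrix(c(0.7, 0.5, 0.3, 0.75, 0.5, 0.1), 3)
  mc <- tiny_beta(v, "5mC")
  means <- rowMeans(v)
  expect_setequal(methylation_extreme_probes(mc, mode = "ge"),
                  rownames(mc)[means >= 0.7])
  expect_true("cg001" %in% methylation_extreme_probes(mc, mode = "ge"))  # 0.725 >= 0.7
  expect_setequal(methylation_extreme_probes(mc, mode = "le"),
                  rownames(mc)[means <= 0.3])
  flat <- tiny_beta(matrix(0.5, 4, 2), "5mC")
  expect_length(methylation_extreme_probes(flat, mode = "ge"), 0)
  expect_length(methylation_extreme_probes(flat, mode = "le"), 0)
})

test_that("spearman correlation handles monotone data and ties like the rank formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, exp(x))$r, 1)
  expect_equal(spearman_cor(x, -x)$r, -1)

  xt <- c(1, 2, 2, 3); yt <- c(1, 3, 2, 4)
  mine <- spearman_cor(xt, yt)
  expect_equal(mine$r, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman", exact = FALSE))
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(spearman_cor(c(1, 1, 1, 1), 1:4), "constant")
})

test_that("group classification follows the sign-by-direction rules", {
  sheet <- tiny_sheet(5, 5)
  set.seed(6)
  n_s <- 10
  expr <- matrix(6, 4, n_s, dimnames = list(paste0("g", 1:4), sheet$sample_id))
  h <- matrix(runif(4 * n_s, 0.02, 0.05), 4,
              dimnames = list(paste0("p", 1:4), sheet$sample_id))
  # gene g1 UP_MT, probe p1 positively tracking expression -> G1
  # gene g2 DOWN_MT, probe p2 negatively tracking -> G4
  # gene g3 UP_MT, probe p3 weakly correlated -> NONE
  latent <- rnorm(n_s)
  expr["g1", ] <- 6 + 2 * (sheet$cohort == "MT") + 0.3 * latent + rnorm(n_s, 0, 0.05)
  h["p1", ] <- 0.2 + 0.05 * latent + 0.1 * (sheet$cohort == "MT")
  latent2 <- rnorm(n_s)
  expr["g2", ] <- 6 - 2 * (sheet$cohort == "MT") - 0.3 * latent2 + rnorm(n_s, 0, 0.05)
  h["p2", ] <- 0.2 + 0.05 * latent2 + 0.1 * (sheet$cohort == "MT")
  expr["g3", ] <- 6 + 2 * (sheet$cohort == "MT") + rnorm(n_s, 0, 0.1)
  expr["g4", ] <- 6 + rnorm(n_s, 0, 0.05)
  hmc <- tiny_beta(h, "5hmC", probes = rownames(h), samples = sheet$sample_id)
  mc <- tiny_beta(matrix(runif(4 * n_s, 0.4, 0.6), 4), "5mC",
                  probes = rownames(h), samples = sheet$sample_id)
  ann <- tiny_annotation(rownames(h), gene_symbol = paste0("g", 1:4),
                         gene_region = "BODY")
  de <- differential_expression(expr, sheet)
  res <- classify_groups(hmc, mc, expr, de, rownames(h), ann)
  rec <- res$records
  expect_equal(rec$group[rec$probe_id == "p1"], "G1")
  expect_equal(rec$group[rec$probe_id == "p2"], "G4")
  if ("p3" %in% rec$probe_id && abs(rec$r_5hmc[rec$probe_id == "p3"]) < 0.5) {
    expect_equal(rec$group[rec$probe_id == "p3"], "NONE")
  }
  expect_equal(sum(res$group_counts), sum(rec$group != "NONE"))
  expect_equal(sum(res$count_table), sum(res$group_counts))
})

test_that("methylation-share accounting follows the percentage rule and exclusions", {
  sheet <- tiny_sheet(2, 2)
  h <- tiny_beta(matrix(0.1, 2, 4), "5hmC", probes = c("p1", "p2"),
                 samples = sheet$sample_id)
  m <- tiny_beta(matrix(c(0.3, 0.3, 0.3, 0.3, 0.1, 0.1, 0.1, 0.1),
                        2, 4, byrow = TRUE), "5mC",
                 probes = c("p1", "p2"), samples = sheet$sample_id)
  ann <- tiny_annotation(c("p1", "p2"), gene_symbol = c("A", "B"),
                         gene_region = "TSS200")
  res <- gcimp_contribution(h, m, c("A", "B", "C"), ann, sheet,
                            level = "per_sample")
  contA <- res$contributions[res$contributions$gene == "A", ]
  expect_equal(contA$pct_5hmc, rep(25, 4))  # 0.1 / 0.4
  contB <- res$contributions[res$contributions$gene == "B", ]
  expect_true(all(contB$excluded))          # total 0.2 < 0.3
  expect_true(all(is.na(contB$pct_5hmc)))
  expect_equal(res$missing_genes, "C")
  expect_true(all(res$summary$min_pct >= 0 & res$summary$max_pct <= 100,
                  na.rm = TRUE))

  # scale invariance of the percentage under a common factor
  h2 <- tiny_beta(unclass(h) * 0.5, "5hmC", probes = rownames(h),
                  samples = colnames(h))
  m2 <- tiny_beta(unclass(m) * 0.5, "5mC", probes = rownames(m),
                  samples = colnames(m))
  res2 <- gcimp_contribution(h2, m2, "A", ann, sheet, min_total = 0.1,
                             level = "per_sample")
  expect_equal(res2$contributions$pct_5hmc, rep(25, 4))
})

test_that("negative-correlation proportion detects perfect anticorrelation", {
  sheet <- tiny_sheet(3, 3)
  set.seed(15)
  m_vals <- matrix(runif(10 * 6, 0.2, 0.8), 10)
  h_vals <- 1 - m_vals
  hmc <- tiny_beta(h_vals, "5hmC", samples = sheet$sample_id)
  mc <- tiny_beta(m_vals, "5mC", probes = rownames(hmc),
                  samples = sheet$sample_id)
  res <- negative_correlation_proportion(hmc, mc, rownames(hmc))
  expect_equal(res$proportion, 1)
  expect_equal(res$n, 10)

  # independent channels: proportion near one half
  h_ind <- tiny_beta(matrix(runif(200 * 8), 200), "5hmC",
                     samples = sprintf("S%02d", 1:8))
  m_ind <- tiny_beta(matrix(runif(200 * 8), 200), "5mC",
                     probes = rownames(h_ind), samples = colnames(h_ind))
  res_ind <- negative_correlation_proportion(h_ind, m_ind, rownames(h_ind))
  expect_lt(abs(res_ind$proportion - 0.5), 3 * sqrt(0.25 / 200) + 0.02)

  # exact zero correlation counts as non-negative
  hz <- tiny_beta(matrix(c(0.1, 0.2, 0.3, 0.4), 1), "5hmC",
                  samples = sprintf("S%02d", 1:4))
  mz <- tiny_beta(matrix(c(0.2, 0.1, 0.4, 0.3) * 0 + c(0.2, 0.3, 0.2, 0.3), 1),
                  "5mC", probes = rownames(hz), samples = colnames(hz))
  rz <- cor(rank(unclass(hz)[1, ]), rank(unclass(mz)[1, ]))
  if (rz == 0) {
    expect_equal(negative_correlation_proportion(hz, mz, rownames(hz))$proportion, 0)
  }
})
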