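test_that("window counting follows the overlap rule on worked examples", {
  lens <- c(chr1 = 1000L)
  # single read inside one window, no extension
  r <- list(s1 = data.frame(chrom = "chr1", start = 105L, end = 130L))
  wc <- count_windows(r, lens, ws = 100, extend = 0)
  expect_equal(nrow(wc), 1)
  expect_equal(wc$window_start, 100)
  expect_equal(wc$s1, 1L)

  # boundary-crossing read increments both windows
  r2 <- list(s1 = data.frame(chrom = "chr1", start = 95L, end = 105L))
  wc2 <- count_windows(r2, lens, ws = 100, extend = 0)
  expect_equal(wc2$window_start, c(0, 100))
  expect_equal(wc2$s1, c(1L, 1L))

  # extension to 300 bp from the 5' end spans three windows
  r3 <- list(s1 = data.frame(chrom = "chr1", start = 10L, end = 60L))
  wc3 <- count_windows(r3, lens, ws = 100, extend = 300)
  expect_equal(wc3$window_start, c(0, 100, 200, 300))

  # clipping beyond chromosome bounds warns
  r4 <- list(s1 = data.frame(chrom = "chr1", start = 950L, end = 980L))
  expect_warning(count_windows(r4, lens, ws = 100, extend = 300), "clipped")
})

test_that("window counts equal a brute-force per-window overlap tally", {
  set.seed(25)
  lens <- c(chr1 = 5000L, chr2 = 3000L)
  for (rep in 1:5) {
    reads <- lapply(1:3, function(s) {
      n <- sample(20:60, 1)
      chrom <- sample(names(lens), n, replace = TRUE)
      start <- vapply(chrom, function(c) sample(0:(lens[[c]] - 400), 1), 0)
      data.frame(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + sample(50:200, n, replace = TRUE)),
                 stringsAsFactors = FALSE)
    })
    names(reads) <- paste0("s", 1:3)
    ws <- 100; extend <- 300
    wc <- count_windows(reads, lens, ws = ws, extend = extend, uniq = FALSE)
    for (s in names(reads)) {
      r <- reads[[s]]
      end <- r$start + pmax(r$end - r$start, extend)
      for (i in sample(nrow(wc), 10)) {
        w <- wc[i, ]
        tally <- sum(r$chrom == w$chrom & r$start < w$window_end &
                       end > w$window_start)
        expect_equal(w[[s]], tally)
      }
    }
    # every read hits at least one window
    totals <- colSums(as.matrix(wc[, names(reads)]))
    expect_true(all(totals >= vapply(reads, nrow, 0L)))
  }
})

test_that("differential window filter equals brute force on random fixtures", {
  set.seed(30)
  sheet <- tiny_sheet(3, 3)
  for (rep in 1:10) {
    n_w <- 40
    counts <- data.frame(chrom = "chr1",
                         window_start = seq(0, by = 100, length.out = n_w),
                         window_end = seq(100, by = 100, length.out = n_w))
    for (s in sheet$sample_id) counts[[s]] <- rpois(n_w, sample(1:8, 1))
    counts <- counts[rowSums(counts[, sheet$sample_id]) > 0, ]
    dw <- differential_windows(counts, sheet)
    raw <- as.matrix(counts[, sheet$sample_id])
    cpm <- sweep(raw, 2, colSums(raw) / 1e6, "/")
    mt <- sheet$cohort == "MT"
    lfc <- log2((rowMeans(cpm[, mt]) + 0.5) / (rowMeans(cpm[, !mt]) + 0.5))
    pass <- rowMeans(raw) >= 3 & abs(lfc) > 1
    expect_equal(nrow(dw), sum(pass))
    if (nrow(dw)) {
      expect_equal(dw$window_start, counts$window_start[pass])
      expect_equal(dw$log_fc, unname(lfc[pass]), tolerance = 1e-12)
    }
  }
  # sub-threshold mean depth is filtered regardless of fold change: the
  # first window has mean 17/6 < 3 and a large cohort imbalance
  shallow <- data.frame(chrom = "chr1", window_start = c(0, 100),
                        window_end = c(100, 200))
  counts_by_sample <- rbind(c(5L, 5L, 5L, 1L, 1L, 0L),
                            c(200L, 200L, 200L, 200L, 200L, 200L))
  for (j in seq_along(sheet$sample_id)) {
    shallow[[sheet$sample_id[j]]] <- counts_by_sample[, j]
  }
  dw_shallow <- differential_windows(shallow, sheet)
  expect_false(0 %in% dw_shallow$window_start)
})

test_that("window-to-gene intersection matches interval-join semantics", {
  genes <- data.frame(gene_symbol = c("A", "B"), chrom = "chr1",
                      start = c(1001, 1451), end = c(1500, 2000),
                      stringsAsFactors = FALSE)
  win <- data.frame(chrom = "chr1", window_start = c(1100, 1400, 2500),
                    window_end = c(1200, 1500, 2600),
                    log_fc = c(2, -2, 2), stringsAsFactors = FALSE)
  res <- windows_to_genes(win, genes)
  expect_setequal(res$up, "A")            # window inside gene A only
  expect_setequal(res$down, c("A", "B"))  # spanning window hits both
  expect_setequal(res$all, c("A", "B"))
  empty <- windows_to_genes(win[0, ], genes)
  expect_length(empty$all, 0)
})

test_that("spike normalisation is a scale-invariant ratio", {
  expect_equal(spike_normalized_enrichment(0.08, 0.04)$normalized, 2)
  expect_equal(spike_normalized_enrichment(0.5, 0.5)$normalized, 1)
  for (c_ in c(0.1, 3, 100)) {
    expect_equal(spike_normalized_enrichment(0.08 * c_, 0.04 * c_)$normalized, 2)
  }
  expect_error(spike_normalized_enrichment(0.1, 0), "positive")
})

test_that("hMeDIP/array gene-set overlap reduces to the hypergeometric tail", {
  disjoint <- overlap_with_array_genes(paste0("a", 1:10), paste0("b", 1:10),
                                       universe_size = 100)
  expect_equal(disjoint$p_value, 1)
  same <- overlap_with_array_genes(paste0("g", 1:10), paste0("g", 1:10),
                                   universe_size = 100)
  expect_equal(same$n_common, 10)
  expect_equal(same$p_value, hyper_tail_enum(100, 10, 10, 10), tolerance = 1e-12)
  expect_error(overlap_with_array_genes(paste0("g", 1:10), paste0("g", 1:10),
                                        universe_size = 5),
               "universe")
})
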