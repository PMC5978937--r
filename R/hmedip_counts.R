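#' Read a 3+-column BED file of aligned read intervals
#' @param path BED path (0-based half-open; columns beyond chrom/start/end
#'   are ignored).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1),
             start = as.integer(vapply(parts, `[`, "", 2)),
             end = as.integer(vapply(parts, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Count extended reads in fixed genomic windows
#'
#' Each read interval is extended to at least `extend` bp from its 5' end
#' (as-given orientation for interval input), then increments every window
#' it overlaps by at least 1 bp. Windows tile each chromosome from 0 in
#' steps of `ws`. Reads beyond the chromosome bounds are clipped with a
#' warning. Optional exact-duplicate removal stands in for a
#' unique-read filter; a 1-bp shift parameter is a no-op for interval
#' input.
#'
#' @param reads named list of per-sample BED data.frames (see
#'   [read_bed()]).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param ws window size in bp (default 100).
#' @param extend minimum read length after extension (default 300).
#' @param uniq drop exact-duplicate intervals within a sample (default
#'   TRUE).
#' @return data.frame with `chrom`, `window_start` (0-based),
#'   `window_end` (half-open) and one count column per sample; only
#'   windows with at least one read in any sample are retained.
#' @export
count_windows <- function(reads, chrom_lengths, ws = 100, extend = 300,
                          uniq = TRUE) {
  if (ws <= 0) stop("ws must be positive")
  chroms <- names(chrom_lengths)
  n_win <- as.integer(ceiling(chrom_lengths / ws))
  offsets <- stats::setNames(c(0L, cumsum(n_win))[seq_along(chroms)], chroms)
  total_windows <- sum(n_win)
  counts <- matrix(0L, total_windows, length(reads),
                   dimnames = list(NULL, names(reads)))
  for (s in seq_along(reads)) {
    r <- reads[[s]]
    if (!nrow(r)) next
    unknown <- !r$chrom %in% chroms
    if (any(unknown)) stop("reads on unknown chromosome: ",
                           paste(unique(r$chrom[unknown]), collapse = ", "))
    if (uniq) r <- unique(r)
    len <- r$end - r$start
    end <- r$start + pmax(len, extend)
    lim <- chrom_lengths[r$chrom]
    clipped <- end > lim | r$start < 0
    if (any(clipped)) {
      warning(sum(clipped), " read(s) clipped to chromosome bounds")
      end <- pmin(end, lim)
      r$start <- pmax(r$start, 0L)
    }
    first_w <- r$start %/% ws
    last_w <- (end - 1L) %/% ws
    idx <- sequence(last_w - first_w + 1L,
                    from = offsets[r$chrom] + first_w + 1L)
    counts[, s] <- counts[, s] + tabulate(idx, nbins = total_windows)
  }
  keep <- rowSums(counts) > 0
  win_chrom <- rep(chroms, n_win)
  win_start <- unlist(lapply(n_win, function(k) (seq_len(k) - 1L))) * ws
  out <- data.frame(chrom = win_chrom[keep],
                    window_start = win_start[keep],
                    window_end = win_start[keep] + ws,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(counts[keep, , drop = FALSE]))
}

#' Filter windows by mean depth and cohort log fold change
#'
#' Per-sample counts are library-size normalised (counts per million)
#' before cohort means; `log_fc = log2((mean_MT + pc) / (mean_WT + pc))`.
#' A window passes when its mean raw count over all samples is at least
#' `min_mean` and `|log_fc| > logfc_cut`.
#'
#' @param counts window table from [count_windows()].
#' @param sheet sample sheet covering the count columns.
#' @param min_mean minimum mean raw read count (default 3).
#' @param logfc_cut absolute log2 fold-change cut (default 1, exclusive).
#' @param pseudocount added to normalised means (default 0.5).
#' @return the passing windows with `mean_reads` and `log_fc` columns.
#' @export
differential_windows <- function(counts, sheet, min_mean = 3, logfc_cut = 1,
                                 pseudocount = 0.5) {
  sample_cols <- intersect(sheet$sample_id, names(counts))
  if (!length(sample_cols)) stop("no sample columns match the sheet")
  mt <- sheet$cohort[match(sample_cols, sheet$sample_id)] == "MT"
  if (!any(mt) || all(mt)) stop("need >= 1 sample per cohort")
  raw <- as.matrix(counts[, sample_cols, drop = FALSE])
  lib <- colSums(raw)
  if (any(lib == 0)) stop("sample with zero total reads")
  cpm <- sweep(raw, 2, lib / 1e6, "/")
  mean_reads <- rowMeans(raw)
  mean_mt <- rowMeans(cpm[, mt, drop = FALSE])
  mean_wt <- rowMeans(cpm[, !mt, drop = FALSE])
  log_fc <- log2((mean_mt + pseudocount) / (mean_wt + pseudocount))
  passes <- mean_reads >= min_mean & abs(log_fc) > logfc_cut
  out <- counts[passes, , drop = FALSE]
  out$mean_reads <- mean_reads[passes]
  out$log_fc <- log_fc[passes]
  rownames(out) <- NULL
  out
}

#' Intersect passing windows with gene intervals
#'
#' Genes overlapping at least one passing window by >= 1 bp, split by the
#' window's fold-change sign.
#'
#' @param windows result of [differential_windows()].
#' @param gene_table data.frame with `gene_symbol`, `chrom`, `start`,
#'   `end` (1-based inclusive; the synthetic manifest's `genes` attribute).
#' @return list with `up` and `down` character vectors of gene symbols and
#'   `all` (their union).
#' @export
windows_to_genes <- function(windows, gene_table) {
  if (!nrow(windows)) return(list(up = character(), down = character(),
                                  all = character()))
  wgr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$window_start + 1L,
                     end = windows$window_end))
  ggr <- GenomicRanges::GRanges(
    gene_table$chrom,
    IRanges::IRanges(start = gene_table$start, end = gene_table$end))
  hits <- GenomicRanges::findOverlaps(wgr, ggr)
  up <- unique(gene_table$gene_symbol[
    S4Vectors::subjectHits(hits)[windows$log_fc[S4Vectors::queryHits(hits)] > 0]])
  down <- unique(gene_table$gene_symbol[
    S4Vectors::subjectHits(hits)[windows$log_fc[S4Vectors::queryHits(hits)] < 0]])
  list(up = up, down = down, all = union(up, down))
}

#' Spike-in-normalised hMeDIP enrichment
#'
#' `normalized = raw_target / raw_spike`: the target enrichment divided by
#' the enrichment of the exogenous spike-in control, cancelling per-sample
#' immunoprecipitation efficiency.
#'
#' @param raw_target,raw_spike positive enrichment values.
#' @param sample_id,target_name optional labels carried into the result.
#' @return list with the inputs and `normalized`.
#' @export
spike_normalized_enrichment <- function(raw_target, raw_spike,
                                        sample_id = NA_character_,
                                        target_name = NA_character_) {
  if (raw_spike <= 0) stop("spike-in enrichment must be positive")
  if (raw_target <= 0) stop("target enrichment must be positive")
  list(sample_id = sample_id, target_name = target_name,
       raw_target = raw_target, raw_spike = raw_spike,
       normalized = raw_target / raw_spike)
}

#' Overlap between hMeDIP genes and array-derived region genes
#'
#' Upper-tail hypergeometric probability of observing the intersection of
#' the two gene sets within a universe of `universe_size` genes.
#'
#' @param hmedip_genes,array_genes character vectors of gene symbols.
#' @param universe_size genome gene count (default 20345, the GRCh37
#'   protein-coding estimate).
#' @return list with `n_hmedip`, `n_array`, `n_common`, `p_value`.
#' @export
overlap_with_array_genes <- function(hmedip_genes, array_genes,
                                     universe_size = 20345) {
  k <- length(intersect(hmedip_genes, array_genes))
  K <- length(unique(array_genes))
  n <- length(unique(hmedip_genes))
  if (K > universe_size || n > universe_size) {
    stop("gene sets exceed the universe")
  }
  list(n_hmedip = n, n_array = K, n_common = k,
       p_value = hypergeom_tail(universe_size, K, n, k))
}
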