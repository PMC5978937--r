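#' Gap-cluster probes along the genome
#'
#' Consecutive probes on the same chromosome separated by at most `max_gap`
#' bp share a cluster; clusters never span chromosomes. Prerequisite for
#' bump-hunting.
#'
#' @param ann probe annotation table.
#' @param max_gap maximum intra-cluster gap in bp (default 1000).
#' @return data.frame sorted by chromosome and position with columns
#'   `probe_id`, `chrom`, `pos`, `cluster_id`.
#' @export
cluster_probes <- function(ann, max_gap = 1000) {
  ord <- order(ann$chrom, ann$pos)
  chrom <- ann$chrom[ord]; pos <- ann$pos[ord]
  n <- length(pos)
  if (n == 0) {
    return(data.frame(probe_id = character(), chrom = character(),
                      pos = integer(), cluster_id = integer()))
  }
  new_cluster <- c(TRUE, chrom[-1] != chrom[-n] | (pos[-1] - pos[-n]) > max_gap)
  data.frame(probe_id = ann$probe_id[ord], chrom = chrom, pos = pos,
             cluster_id = cumsum(new_cluster), stringsAsFactors = FALSE)
}

# truncated centered running mean within clusters; clusters shorter than
# `window` are left unsmoothed. x is ordered as `clusters` (sorted layout).
smooth_in_clusters <- function(x, cluster_id, window) {
  if (window <= 1) return(x)
  n <- length(x)
  run <- rle(cluster_id)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  cl_start <- rep(starts, run$lengths)
  cl_end <- rep(ends, run$lengths)
  cl_len <- cl_end - cl_start + 1L
  h <- (window - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(cl_start, i - h)
  hi <- pmin(cl_end, i + h)
  cs <- cumsum(x)
  sm <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
  ifelse(cl_len < window, x, sm)
}

# maximal same-sign runs of smoothed effects beyond the cutoff, within
# clusters; returns a data.frame of candidate runs with >= min_probes probes
candidate_runs <- function(sm, cluster_id, cutoff, min_probes) {
  sign_v <- (sm > cutoff) - (sm < -cutoff)
  grp <- cumsum(c(TRUE, diff(cluster_id) != 0 | diff(sign_v) != 0))
  run <- rle(grp)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  keep <- sign_v[starts] != 0 & run$lengths >= min_probes
  data.frame(start_idx = starts[keep], end_idx = ends[keep],
             n_probes = run$lengths[keep], sign = sign_v[starts[keep]])
}

run_areas <- function(runs, sm) {
  if (nrow(runs) == 0) return(numeric())
  vapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start_idx[i]:runs$end_idx[i]
    abs(mean(sm[idx])) * length(idx)
  }, 0)
}

# per-probe MT-minus-WT mean difference for arbitrary label assignments;
# labels is a logical matrix (samples x assignments), TRUE = "MT"
effect_for_labels <- function(v, labels) {
  n1 <- colSums(labels)
  n2 <- nrow(labels) - n1
  (v %*% labels) / rep(n1, each = nrow(v)) -
    (v %*% (!labels)) / rep(n2, each = nrow(v))
}

#' Permutation bump-hunting for differentially (hydroxy)methylated regions
#'
#' Detects regions where the smoothed per-probe cohort difference
#' (MT minus WT) exceeds a cutoff over at least `min_probes` consecutive
#' probes of a gap-cluster, and assigns permutation significance. The same
#' engine serves DMR detection (5mC input) and DHMR detection (5hmC input).
#'
#' Per-probe effects are smoothed by a truncated centered running mean of
#' width `smooth_window` within each cluster; the cutoff is either the
#' `cutoff_quantile` of the genome-wide absolute smoothed effects or an
#' absolute value given via `cutoff`. Candidate regions are maximal
#' same-sign runs beyond the cutoff with at least `min_probes` probes.
#' Cohort labels are then permuted `n_perm` times (or all distinct
#' assignments enumerated when fewer exist) and null areas recomputed under
#' the same cutoff from every beyond-cutoff run of the permuted effects
#' (no length filter, the Bumphunter convention); each observed region
#' receives
#' `p = (1 + #\{null areas >= observed\}) / (1 + total null areas)` plus a
#' family-wise adjusted
#' `adj_p = (1 + #\{permutations whose max null area >= observed\}) /
#' (1 + n_perm)`. Regions with `adj_p <= alpha` are returned sorted by area.
#'
#' @param beta a [beta_matrix()] (5hmC for DHMRs, 5mC for DMRs).
#' @param sheet sample sheet; >= 2 samples per cohort.
#' @param clusters result of [cluster_probes()] covering the probes of
#'   `beta` (extra probes are ignored).
#' @param min_probes minimum probes per region (default 7).
#' @param cutoff_quantile genome-wide quantile of |smoothed effect| defining
#'   the cutoff (default 0.99); ignored when `cutoff` is given.
#' @param cutoff optional absolute effect cutoff.
#' @param smooth_window running-mean width (default 3; 1 disables).
#' @param n_perm number of label permutations (default 250, minimum 100).
#' @param alpha family-wise significance threshold on `adj_p` (default 0.05).
#' @param seed integer seed for the permutation draw.
#' @return data.frame of regions: `region_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `probe_ids` (list column), `n_probes`, `value`
#'   (mean smoothed effect), `area`, `p_value`, `adj_p`; attribute `cutoff`
#'   records the threshold used.
#' @export
bumphunt <- function(beta, sheet, clusters, min_probes = 7,
                     cutoff_quantile = 0.99, cutoff = NULL,
                     smooth_window = 3, n_perm = 250, alpha = 0.05,
                     seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  keep <- clusters$probe_id %in% rownames(beta)
  cl <- clusters[keep, , drop = FALSE]
  if (nrow(cl) < nrow(beta)) {
    stop("clusters missing probes present in the beta matrix")
  }
  v <- unclass(beta)[cl$probe_id, , drop = FALSE]
  m_mask <- cohort_mask(beta, sheet, "MT")
  n1 <- sum(m_mask); n <- ncol(v)
  if (n1 < 2 || n - n1 < 2) stop("need >= 2 samples per cohort")

  obs_effect <- rowMeans(v[, m_mask, drop = FALSE]) -
    rowMeans(v[, !m_mask, drop = FALSE])
  sm <- smooth_in_clusters(obs_effect, cl$cluster_id, smooth_window)
  if (is.null(cutoff)) {
    cutoff <- stats::quantile(abs(sm), cutoff_quantile, names = FALSE)
  }
  obs_runs <- candidate_runs(sm, cl$cluster_id, cutoff, min_probes)
  obs_area <- run_areas(obs_runs, sm)

  n_distinct <- choose(n, n1)
  set.seed(seed)
  if (n_distinct <= n_perm) {
    warning(sprintf("only %d distinct label assignments; enumerating all",
                    n_distinct))
    combs <- utils::combn(n, n1)
    labels <- matrix(FALSE, n, ncol(combs))
    labels[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = n1))] <- TRUE
  } else {
    labels <- vapply(seq_len(n_perm),
                     function(i) seq_len(n) %in% sample.int(n, n1),
                     logical(n))
  }
  n_used <- ncol(labels)
  null_effects <- effect_for_labels(v, labels)
  null_areas <- vector("list", n_used)
  max_null <- numeric(n_used)
  for (j in seq_len(n_used)) {
    smj <- smooth_in_clusters(null_effects[, j], cl$cluster_id, smooth_window)
    # null areas come from every beyond-cutoff run, with no length filter:
    # the Bumphunter convention, strictly conservative for the observed
    # length-filtered regions
    runsj <- candidate_runs(smj, cl$cluster_id, cutoff, 1L)
    aj <- run_areas(runsj, smj)
    null_areas[[j]] <- aj
    max_null[j] <- if (length(aj)) max(aj) else 0
  }
  all_null <- unlist(null_areas)

  if (nrow(obs_runs) == 0) {
    out <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_probes = integer(), value = numeric(),
                      area = numeric(), p_value = numeric(),
                      adj_p = numeric(), stringsAsFactors = FALSE)
    out$probe_ids <- list()
    attr(out, "cutoff") <- cutoff
    return(out)
  }
  p_val <- vapply(obs_area, function(a) {
    (1 + sum(all_null >= a)) / (1 + length(all_null))
  }, 0)
  adj_p <- vapply(obs_area, function(a) {
    (1 + sum(max_null >= a)) / (1 + n_used)
  }, 0)
  probe_ids <- lapply(seq_len(nrow(obs_runs)), function(i) {
    cl$probe_id[obs_runs$start_idx[i]:obs_runs$end_idx[i]]
  })
  value <- vapply(seq_len(nrow(obs_runs)), function(i) {
    mean(sm[obs_runs$start_idx[i]:obs_runs$end_idx[i]])
  }, 0)
  out <- data.frame(
    region_id = sprintf("region_%04d", seq_len(nrow(obs_runs))),
    chrom = cl$chrom[obs_runs$start_idx],
    start = cl$pos[obs_runs$start_idx],
    end = cl$pos[obs_runs$end_idx],
    n_probes = obs_runs$n_probes,
    value = value, area = obs_area, p_value = p_val, adj_p = adj_p,
    stringsAsFactors = FALSE)
  out$probe_ids <- probe_ids
  out <- out[out$adj_p <= alpha, , drop = FALSE]
  out <- out[order(-out$area), , drop = FALSE]
  if (nrow(out)) out$region_id <- sprintf("region_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Map detected regions to their annotated genes
#'
#' Union of the gene symbols of member probes, dropping intergenic probes,
#' with per-gene probe counts.
#'
#' @param regions data.frame from [bumphunt()].
#' @param ann probe annotation table.
#' @return data.frame with `gene_symbol` and `n_probes`, sorted by count.
#' @export
regions_to_genes <- function(regions, ann) {
  probes <- unlist(regions$probe_ids)
  idx <- match(probes, ann$probe_id)
  if (anyNA(idx)) stop("region probes missing from annotation")
  genes <- ann$gene_symbol[idx]
  genes <- genes[!is.na(genes)]
  if (!length(genes)) {
    return(data.frame(gene_symbol = character(), n_probes = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- sort(table(genes), decreasing = TRUE)
  data.frame(gene_symbol = names(tab), n_probes = as.integer(tab),
             stringsAsFactors = FALSE)
}
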