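#' Probes for consensus clustering: region probes unique to one cohort's top set
#'
#' Returns the differential-region probes that are in exactly one cohort's
#' top-fraction set: `dhmr & ((top_mt | top_wt) & !(top_mt & top_wt))`.
#'
#' @param dhmr_probes character vector of region probe ids.
#' @param top1_mt,top1_wt top-fraction probe ids per cohort.
#' @return character vector of selected probe ids.
#' @export
select_consensus_probes <- function(dhmr_probes, top1_mt, top1_wt) {
  if (!length(dhmr_probes) || (!length(top1_mt) && !length(top1_wt))) {
    stop("empty input set")
  }
  xor_set <- setdiff(union(top1_mt, top1_wt), intersect(top1_mt, top1_wt))
  intersect(dhmr_probes, xor_set)
}

pearson_dissimilarity <- function(m) {
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant profile (zero variance) for sample ",
         colnames(m)[which(sds == 0)[1]])
  }
  stats::as.dist(1 - stats::cor(m))
}

mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- length(labels)
  if (length(unique(labels)) < 2) return(NA_real_)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(d[i, labels == k]), 0))
    if (sum(labels == labels[i]) == 1) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Consensus clustering over resampled probe subsets
#'
#' For each of `n_resample` draws, a fraction `subsample_fraction` of probes
#' is sampled without replacement, samples are clustered by Ward linkage on
#' Pearson dissimilarity (1 - r) over the drawn probes, and co-clustering at
#' each `k` is tallied into a sample x sample consensus matrix (with probe
#' resampling every sample pair is co-sampled, so the denominator is
#' `n_resample`). Final assignments cut a Ward tree on `1 - consensus`;
#' per-k CDF areas and mean silhouette widths are reported and `chosen_k`
#' maximises the silhouette (advisory, never hiding the diagnostics).
#'
#' @param m probe x sample numeric matrix (e.g. 5hmC betas over the probes
#'   from [select_consensus_probes()]).
#' @param k_range integer vector of cluster counts to evaluate.
#' @param n_resample resampling steps (default 1000).
#' @param subsample_fraction probe fraction per resample (default 0.8).
#' @param linkage agglomeration method, `"ward.D"` (Lance-Williams Ward
#'   update on the non-Euclidean dissimilarity) or `"ward.D2"`.
#' @param seed integer seed.
#' @return list with `k_values`, `consensus_matrices`, `assignments`,
#'   `cdf_summaries` (per-k CDF area), `silhouette`, `chosen_k`.
#' @export
consensus_cluster <- function(m, k_range = 2:6, n_resample = 1000,
                              subsample_fraction = 0.8,
                              linkage = "ward.D", seed = 1) {
  n_s <- ncol(m)
  if (n_s < 2) stop("need >= 2 samples")
  if (any(k_range > n_s)) stop("k exceeds the number of samples")
  set.seed(seed)
  n_draw <- ceiling(subsample_fraction * nrow(m))
  consensus <- lapply(k_range, function(k) matrix(0, n_s, n_s))
  names(consensus) <- as.character(k_range)
  for (b in seq_len(n_resample)) {
    sel <- sample.int(nrow(m), n_draw)
    d <- pearson_dissimilarity(m[sel, , drop = FALSE])
    hc <- stats::hclust(d, method = linkage)
    for (j in seq_along(k_range)) {
      lab <- stats::cutree(hc, k_range[j])
      consensus[[j]] <- consensus[[j]] + outer(lab, lab, `==`)
    }
  }
  consensus <- lapply(consensus, function(cm) {
    cm <- cm / n_resample
    dimnames(cm) <- list(colnames(m), colnames(m))
    diag(cm) <- 1
    cm
  })
  assignments <- list(); cdf_area <- numeric(length(k_range))
  sil <- numeric(length(k_range))
  for (j in seq_along(k_range)) {
    dcons <- stats::as.dist(1 - consensus[[j]])
    hc <- stats::hclust(dcons, method = linkage)
    lab <- stats::cutree(hc, k_range[j])
    assignments[[j]] <- lab
    vals <- consensus[[j]][upper.tri(consensus[[j]])]
    grid <- seq(0, 1, by = 0.01)
    cdf_area[j] <- mean(stats::ecdf(vals)(grid))
    sil[j] <- mean_silhouette(dcons, lab)
  }
  names(assignments) <- as.character(k_range)
  chosen <- k_range[which.max(sil)]
  list(k_values = k_range, consensus_matrices = consensus,
       assignments = assignments,
       cdf_summaries = data.frame(k = k_range, cdf_area = cdf_area),
       silhouette = stats::setNames(sil, k_range), chosen_k = chosen)
}

#' Hierarchical clustering of samples
#'
#' Deterministic agglomeration (ties merge the lowest-index pair first, the
#' `hclust` convention) on Pearson dissimilarity or Euclidean distance.
#'
#' @param m probe x sample matrix.
#' @param k cut height in clusters; NULL returns only the tree.
#' @param distance `"pearson_dissimilarity"` or `"euclidean"`.
#' @param linkage `"ward.D"` or `"ward.D2"`.
#' @return list with `tree` (hclust) and `assignments` (named integer
#'   vector, NULL if `k` is NULL).
#' @export
hierarchical_cluster <- function(m, k = NULL,
                                 distance = c("pearson_dissimilarity", "euclidean"),
                                 linkage = "ward.D") {
  distance <- match.arg(distance)
  if (ncol(m) < 2) stop("need >= 2 samples")
  d <- if (distance == "pearson_dissimilarity") {
    pearson_dissimilarity(m)
  } else {
    stats::dist(t(m))
  }
  hc <- stats::hclust(d, method = linkage)
  list(tree = hc,
       assignments = if (is.null(k)) NULL else stats::cutree(hc, k))
}
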