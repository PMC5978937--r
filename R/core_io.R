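#' Read a sample sheet
#'
#' The sample sheet is a CSV with header
#' `sample_id,cohort[,age_years,who_grade,histology]`. Cohort tokens are
#' normalised case-insensitively to `MT` / `WT`.
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `sample_id`, `cohort` (factor MT/WT) and
#'   any of the optional columns present.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no samples in sample sheet ", path)
  required <- c("sample_id", "cohort")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("sample sheet missing columns: ", paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  coh <- toupper(trimws(df$cohort))
  bad <- which(!coh %in% c("MT", "WT"))
  if (length(bad)) {
    stop("unknown cohort token in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(df$cohort[bad]), collapse = ", "))
  }
  df$cohort <- factor(coh, levels = c("MT", "WT"))
  if ("age_years" %in% names(df)) {
    df$age_years <- as.numeric(df$age_years)
    if (any(!is.na(df$age_years) & df$age_years < 0)) stop("negative age_years")
  }
  df
}

#' Read a beta-value matrix from TSV
#'
#' TSV with first column `probe_id` and one column per sample. Values are
#' validated to lie in \[0, 1\]. When a sample sheet is supplied, columns are
#' re-ordered to sheet order so downstream cohort masks are positional.
#'
#' @param path path to the TSV file.
#' @param channel channel tag for the matrix, see [beta_matrix()].
#' @param sheet optional sample sheet from [read_sample_sheet()].
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path, channel = c("BS", "OxBS", "5mC", "5hmC"),
                             sheet = NULL) {
  channel <- match.arg(channel)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "probe_id") stop("first column must be probe_id in ", path)
  probes <- as.character(df$probe_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    for (j in seq_len(ncol(m))) {
      v <- suppressWarnings(as.numeric(m[, j]))
      bad <- which(is.na(v) & !is.na(m[, j]) & m[, j] != "")
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at probe %s, sample %s",
                     m[bad[1], j], probes[bad[1]], colnames(m)[j]))
      }
    }
    m <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at probe %s, sample %s (missing betas are not supported)",
                 probes[idx[1]], colnames(m)[idx[2]]))
  }
  out <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(out)) {
    stop(sprintf("beta value %g outside [0,1] at probe %s, sample %s",
                 m[out[1, 1], out[1, 2]], probes[out[1, 1]], colnames(m)[out[1, 2]]))
  }
  rownames(m) <- probes
  if (!is.null(sheet)) {
    missing <- setdiff(sheet$sample_id, colnames(m))
    if (length(missing)) {
      stop("samples in sheet missing from matrix: ", paste(missing, collapse = ", "))
    }
    m <- m[, sheet$sample_id, drop = FALSE]
  }
  beta_matrix(m, channel)
}

#' Write a beta-value matrix as TSV
#'
#' Inverse of [read_beta_matrix()]; values round-trip to at least 12
#' significant digits.
#'
#' @param x a [beta_matrix()].
#' @param path output TSV path.
#' @export
write_beta_matrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Fixed-header TSV: `probe_id, chrom, pos, cpg_feature, gene_region,
#' gene_symbol, enh_<source>..., snp_flag, sex_chrom_flag`. Coordinates are
#' 1-based. Any number of `enh_`-prefixed logical columns define enhancer
#' annotation sources.
#'
#' @param path path to the TSV file.
#' @return data.frame, one row per probe, with logical flag columns.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("probe_id", "chrom", "pos", "cpg_feature", "gene_region",
                "gene_symbol", "snp_flag", "sex_chrom_flag")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("annotation missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
  if (any(df$pos < 1)) stop("annotation positions must be >= 1")
  feat_levels <- c("ISLAND", "SHORE", "SHELF", "OPEN_SEA")
  reg_levels <- c("TSS200", "TSS1500", "FIRST_EXON", "FIVE_UTR", "BODY",
                  "INTRON", "THREE_UTR", "INTERGENIC")
  if (any(!df$cpg_feature %in% feat_levels)) stop("unknown cpg_feature token")
  if (any(!df$gene_region %in% reg_levels)) stop("unknown gene_region token")
  df$gene_symbol[df$gene_symbol %in% c("", "NA")] <- NA_character_
  inter <- df$gene_region == "INTERGENIC"
  if (any(inter & !is.na(df$gene_symbol))) {
    stop("INTERGENIC probes must not carry a gene_symbol")
  }
  for (col in c("snp_flag", "sex_chrom_flag", grep("^enh_", names(df), value = TRUE))) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Enhancer annotation source names of an annotation table
#' @param ann annotation data.frame from [read_probe_annotation()].
#' @return character vector of source names (without the `enh_` prefix).
#' @export
enhancer_sources <- function(ann) {
  sub("^enh_", "", grep("^enh_", names(ann), value = TRUE))
}

#' Read a gene set (one symbol per line)
#' @param path path to the text file.
#' @param name set name; defaults to the file name.
#' @return list with `name` and unique `symbols`.
#' @export
read_gene_set <- function(path, name = NULL) {
  symbols <- unique(trimws(readLines(path)))
  symbols <- symbols[symbols != ""]
  if (!length(symbols)) stop("empty gene set: ", path)
  list(name = if (is.null(name)) basename(path) else name, symbols = symbols)
}

#' Read a gene x sample log2 expression matrix from TSV
#' @param path TSV with first column `gene_symbol`, one column per sample.
#' @param sheet optional sample sheet; columns restricted/reordered to the
#'   sheet samples that are present (samples without expression are allowed
#'   and simply absent from the matrix).
#' @return numeric matrix, genes in rows.
#' @export
read_expression_matrix <- function(path, sheet = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_symbol") stop("first column must be gene_symbol in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  if (anyNA(m) || any(!is.finite(m))) stop("expression values must be finite")
  rownames(m) <- as.character(df$gene_symbol)
  if (anyDuplicated(rownames(m))) stop("duplicate gene_symbol in ", path)
  if (!is.null(sheet)) {
    keep <- intersect(sheet$sample_id, colnames(m))
    if (!length(keep)) stop("no expression samples overlap the sample sheet")
    m <- m[, keep, drop = FALSE]
  }
  m
}

#' Drop SNP-overlapping and/or sex-chromosome probes
#'
#' @param beta a [beta_matrix()].
#' @param ann annotation table covering every probe in `beta`.
#' @param drop_snp,drop_sex which flag classes to remove.
#' @return the filtered [beta_matrix()], probe order preserved.
#' @export
filter_probes <- function(beta, ann, drop_snp = TRUE, drop_sex = TRUE) {
  idx <- match(rownames(beta), ann$probe_id)
  if (anyNA(idx)) {
    miss <- rownames(beta)[is.na(idx)]
    stop("probes missing from annotation: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10) else "")
  }
  keep <- rep(TRUE, nrow(beta))
  if (drop_snp) keep <- keep & !ann$snp_flag[idx]
  if (drop_sex) keep <- keep & !ann$sex_chrom_flag[idx]
  beta_matrix(unclass(beta)[keep, , drop = FALSE], bm_channel(beta))
}

#' Write detected regions as BED plus a statistics sidecar TSV
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open. The BED score is `-log10(adj_p)` capped at 1000.
#'
#' @param path output BED path; the sidecar TSV is written next to it with
#'   extension `.stats.tsv`.
#' @param regions data.frame of regions as returned by [bumphunt()].
#' @return invisibly, the BED path.
#' @export
write_regions_bed <- function(path, regions) {
  header <- "# region BED: chrom, start (0-based), end (half-open), region_id, -log10(adj_p) capped at 1000"
  if (is.null(regions) || nrow(regions) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  if (any(regions$start > regions$end)) stop("region with start > end")
  score <- -log10(pmax(regions$adj_p, 0))
  score[!is.finite(score) | score > 1000] <- 1000
  bed <- sprintf("%s\t%d\t%d\t%s\t%g", regions$chrom,
                 as.integer(regions$start) - 1L, as.integer(regions$end),
                 regions$region_id, score)
  writeLines(c(header, bed), path)
  stats_path <- sub("\\.bed$", "", path)
  stats_path <- paste0(stats_path, ".stats.tsv")
  out <- regions
  out$probe_ids <- vapply(regions$probe_ids, paste, "", collapse = ",")
  utils::write.table(out, stats_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
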