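#' Beta-value matrix with a channel tag
#'
#' A `beta_matrix` is a numeric probe x sample matrix of Infinium-style
#' beta-values in \[0, 1\] carrying a `channel` attribute identifying what the
#' values measure: `"BS"` (bisulfite: 5mC + 5hmC), `"OxBS"` (oxidative
#' bisulfite: 5mC only), `"5mC"` or `"5hmC"`.
#'
#' @param values numeric matrix, probes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param channel one of `"BS"`, `"OxBS"`, `"5mC"`, `"5hmC"`.
#' @param clamp_value retained for interface compatibility; recorded as the
#'   floor used when the matrix was produced by clamping. Values below it
#'   can still occur legitimately (a genuine BS-OxBS difference may be any
#'   nonnegative number), so validation only enforces nonnegativity.
#' @return `values` with class `beta_matrix` and attribute `channel`.
#' @export
beta_matrix <- function(values, channel = c("BS", "OxBS", "5mC", "5hmC"),
                        clamp_value = 1e-7) {
  channel <- match.arg(channel)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (nrow(values) > 0 && (is.null(rownames(values)) ||
                           anyDuplicated(rownames(values)))) {
    stop("probe ids (rownames) must be present and unique")
  }
  if (ncol(values) > 0 && (is.null(colnames(values)) ||
                           anyDuplicated(colnames(values)))) {
    stop("sample ids (colnames) must be present and unique")
  }
  if (anyNA(values)) stop("beta matrix contains missing values")
  if (length(values) && (min(values) < 0 || max(values) > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  structure(values, channel = channel, class = c("beta_matrix", "matrix", "array"))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix [%s]: %d probes x %d samples\n",
              bm_channel(x), nrow(x), ncol(x)))
  if (nrow(x) > 0 && ncol(x) > 0) {
    print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE], 4L))
  }
  invisible(x)
}

#' Channel tag of a beta matrix
#' @param x a [beta_matrix()].
#' @return the channel string.
#' @export
bm_channel <- function(x) {
  ch <- attr(x, "channel")
  if (is.null(ch)) stop("not a channel-tagged beta matrix")
  ch
}

#' Subset a beta matrix by probes and/or samples, keeping the channel tag
#' @param x a [beta_matrix()].
#' @param probes,samples character vectors of ids (NULL keeps all).
#' @return a [beta_matrix()].
#' @export
bm_subset <- function(x, probes = NULL, samples = NULL) {
  v <- unclass(x)
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(v))
    if (length(missing)) {
      stop("probes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
    }
    v <- v[probes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing)) {
      stop("samples absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
    }
    v <- v[, samples, drop = FALSE]
  }
  beta_matrix(v, bm_channel(x))
}

# positional mask of a cohort's samples in a beta matrix, taken from the sheet
cohort_mask <- function(x, sheet, cohort) {
  idx <- match(colnames(x), sheet$sample_id)
  if (anyNA(idx)) {
    stop("samples absent from sample sheet: ",
         paste(utils::head(colnames(x)[is.na(idx)], 5), collapse = ", "))
  }
  sheet$cohort[idx] == cohort
}
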