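#' Impute missing expression values by the gene-row mean
#'
#' Each missing cell is replaced by the mean of the observed values in its
#' gene row. Genes with no observed value at all are dropped with a warning.
#'
#' @param m Numeric genes x samples matrix, `NA` for missing.
#' @return The completed matrix, with attributes `was_imputed` (named logical
#'   per retained gene) and `dropped` (ids of all-missing genes).
#' @export
impute_row_mean <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("m must be a numeric matrix", call. = FALSE)
  obs <- !is.na(m)
  n_obs <- rowSums(obs)
  dropped <- rownames(m)[n_obs == 0L]
  if (length(dropped)) {
    warning("dropping ", length(dropped), " gene(s) with no observed values: ",
            paste(utils::head(dropped, 5L), collapse = ", "), call. = FALSE)
    m <- m[n_obs > 0L, , drop = FALSE]
    obs <- obs[n_obs > 0L, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no genes left after dropping all-missing rows", call. = FALSE)
  was_imputed <- !matrixStats_all(obs)
  if (any(!obs)) {
    mu <- rowSums(m * obs, na.rm = TRUE) / rowSums(obs)
    idx <- which(!obs, arr.ind = TRUE)
    m[idx] <- mu[idx[, 1L]]
  }
  attr(m, "was_imputed") <- stats::setNames(was_imputed, rownames(m))
  attr(m, "dropped") <- dropped
  m
}

# rowwise all() without matrixStats
matrixStats_all <- function(b) rowSums(b) == ncol(b)

#' Z-normalize each gene row
#'
#' Standardizes every gene to mean zero and unit variance across samples:
#' `z = (x - mean(x)) / sd(x)` with the sample (n-1) standard deviation.
#' Genes with zero variance are dropped with a warning. Supplying `center`
#' and `scale` (e.g. estimated from training samples only) standardizes with
#' those statistics instead, which keeps held-out samples from influencing
#' the transform.
#'
#' @param m Complete numeric genes x samples matrix (see [impute_row_mean()]).
#' @param center,scale Optional named per-gene center/scale vectors; defaults
#'   are the row means and row sample standard deviations of `m`.
#' @param tol Scales below `tol` count as zero variance.
#' @return The normalized matrix (possibly fewer rows).
#' @export
znormalize <- function(m, center = NULL, scale = NULL, tol = 1e-12) {
  if (ncol(m) < 2L) stop("z-normalization needs at least 2 samples", call. = FALSE)
  if (anyNA(m)) stop("missing values present; run impute_row_mean() first", call. = FALSE)
  center <- center %||% rowMeans(m)
  scale <- scale %||% row_sds(m)
  center <- center[rownames(m)]
  scale <- scale[rownames(m)]
  keep <- !is.na(scale) & scale > tol
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance gene(s): ",
            paste(utils::head(rownames(m)[!keep], 5L), collapse = ", "),
            call. = FALSE)
  }
  (m[keep, , drop = FALSE] - center[keep]) / scale[keep]
}
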