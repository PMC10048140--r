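#' Equal-variance two-sample t-test for one gene
#'
#' Classic pooled-variance t-statistic between normal (label 0) and tumor
#' (label 1) samples, `t = (mean0 - mean1) / (s_pooled * sqrt(1/N1 + 1/N2))`
#' with `N1 + N2 - 2` degrees of freedom and a two-tailed p-value. If both
#' class variances are zero with equal means the statistic is defined as 0
#' with p = 1; zero pooled variance with unequal means is an error unless a
#' positive `epsilon` stabilizer is supplied.
#'
#' @param x Numeric expression vector.
#' @param labels 0/1 vector aligned with `x`.
#' @param epsilon Optional additive stabilizer on the pooled standard
#'   deviation (0 = off).
#' @return List with elements `t` and `p_value`.
#' @export
ttest_equal_variance <- function(x, labels, epsilon = 0) {
  res <- row_ttest(matrix(x, nrow = 1L), labels, epsilon = epsilon)
  list(t = unname(res$t), p_value = unname(res$p_value))
}

# vectorized equal-variance t over matrix rows
row_ttest <- function(m, labels, epsilon = 0) {
  labels <- as.integer(labels)
  i0 <- labels == 0L
  i1 <- labels == 1L
  n1 <- sum(i0)
  n2 <- sum(i1)
  if (n1 < 2L || n2 < 2L) {
    stop("each class needs at least 2 samples (got ", n1, " normal, ", n2,
         " tumor)", call. = FALSE)
  }
  m0 <- m[, i0, drop = FALSE]
  m1 <- m[, i1, drop = FALSE]
  mu0 <- rowMeans(m0)
  mu1 <- rowMeans(m1)
  ss <- rowSums((m0 - mu0)^2) + rowSums((m1 - mu1)^2)
  df <- n1 + n2 - 2L
  s_pooled <- sqrt(ss / df) + epsilon
  se <- s_pooled * sqrt(1 / n1 + 1 / n2)
  delta <- mu0 - mu1
  t <- delta / se
  degen <- se == 0
  if (any(degen & abs(delta) > 0)) {
    bad <- rownames(m)[degen & abs(delta) > 0] %||% "input"
    stop("zero within-class variance with unequal means for ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; set epsilon > 0 to stabilize", call. = FALSE)
  }
  t[degen] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(t = t, p_value = p, row.names = rownames(m))
}

#' Point-biserial correlation between a gene and the phenotype
#'
#' `rho = (M1 - M0) * sqrt(p*q) / S` where `M1`, `M0` are the class means,
#' `p`, `q` the class proportions and `S` the population (1/n) standard
#' deviation of all samples pooled. With this reading the statistic is
#' numerically identical to the Pearson correlation between the expression
#' vector and the 0/1 label coding (tumor-positive sign convention; only the
#' absolute value enters the PCT score).
#'
#' @inheritParams ttest_equal_variance
#' @return The correlation in \[-1, 1\].
#' @export
point_biserial <- function(x, labels) {
  unname(row_point_biserial(matrix(x, nrow = 1L), labels))
}

row_point_biserial <- function(m, labels) {
  labels <- as.integer(labels)
  assert_binary_labels(labels)
  n <- length(labels)
  i1 <- labels == 1L
  p1 <- sum(i1) / n
  mu <- rowMeans(m)
  s_pop <- sqrt(rowMeans((m - mu)^2))
  if (any(s_pop == 0)) {
    stop("zero overall standard deviation; correlation undefined for ",
         paste(utils::head(rownames(m)[s_pop == 0] %||% "input", 5L),
               collapse = ", "), call. = FALSE)
  }
  delta <- rowMeans(m[, i1, drop = FALSE]) - rowMeans(m[, !i1, drop = FALSE])
  delta * sqrt(p1 * (1 - p1)) / s_pop
}

#' PCT gene score
#'
#' Combined differential-expression weight `t^2 + |rho_pb|`: the squared
#' equal-variance t-statistic plus the absolute point-biserial correlation.
#' Monotone in both the magnitude of differential expression and the
#' strength of phenotype correlation.
#'
#' @param t t-statistic ([ttest_equal_variance()]).
#' @param rho_pb Point-biserial correlation ([point_biserial()]).
#' @return Non-negative score.
#' @export
pct_score <- function(t, rho_pb) {
  stopifnot(is.finite(t), is.finite(rho_pb))
  t^2 + abs(rho_pb)
}

#' Min-max initial gene weights
#'
#' Maps PCT scores onto \[0, 1\] to seed the random walk. The default
#' `"inverse"` orientation applies the original e-DRW min-max form
#' `|pct - max| / (max - min)`, under which the gene with the largest PCT
#' score receives weight 0; `"direct"` uses `(pct - min) / (max - min)` so
#' the most differentially expressed gene starts the walk with the most
#' mass. Both orientations are kept because the inverse form inverts the
#' ranking that the surrounding method motivates; see the methods vignette.
#'
#' @param pct Vector of PCT scores over all scored genes.
#' @param orientation `"inverse"` (original form) or `"direct"`.
#' @param uniform_fallback If all scores are equal, return uniform weights
#'   instead of erroring.
#' @return Weights in \[0, 1\], same names as `pct`.
#' @export
initial_weight_minmax <- function(pct, orientation = c("inverse", "direct"),
                                  uniform_fallback = FALSE) {
  orientation <- match.arg(orientation)
  rng <- range(pct)
  if (diff(rng) == 0) {
    if (uniform_fallback) return(rep_len(1 / length(pct), length(pct)) |>
                                   stats::setNames(names(pct)))
    stop("all PCT scores are equal; pass uniform_fallback = TRUE for uniform ",
         "initial weights", call. = FALSE)
  }
  w <- if (orientation == "inverse") {
    abs(pct - rng[2L]) / diff(rng)
  } else {
    (pct - rng[1L]) / diff(rng)
  }
  stats::setNames(w, names(pct))
}

#' Score every gene against the phenotype
#'
#' Computes, per gene row: the equal-variance t-statistic and two-tailed
#' p-value, the point-biserial correlation, the PCT score `t^2 + |rho|`, and
#' the min-max initial walk weight. The t-statistic and correlation are
#' invariant to per-gene affine rescaling, so raw, cleaned or z-normalized
#' input give identical scores.
#'
#' @param m Complete numeric genes x samples matrix.
#' @param labels 0/1 vector aligned with the columns of `m`.
#' @param w0_orientation Passed to [initial_weight_minmax()].
#' @param epsilon Passed to the t-test (see [ttest_equal_variance()]).
#' @return Data frame with columns `gene_id`, `t`, `p_value`, `rho_pb`,
#'   `pct`, `w0`, one row per gene in input order.
#' @export
score_genes <- function(m, labels, w0_orientation = c("inverse", "direct"),
                        epsilon = 0) {
  w0_orientation <- match.arg(w0_orientation)
  labels <- align_labels(labels, colnames(m) %||% as.character(seq_len(ncol(m))))
  tt <- row_ttest(m, labels, epsilon = epsilon)
  rho <- row_point_biserial(m, labels)
  pct <- tt$t^2 + abs(rho)
  w0 <- initial_weight_minmax(stats::setNames(pct, rownames(m)),
                              orientation = w0_orientation)
  data.frame(gene_id = rownames(m), t = tt$t, p_value = tt$p_value,
             rho_pb = rho, pct = pct, w0 = unname(w0),
             row.names = NULL, stringsAsFactors = FALSE)
}
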