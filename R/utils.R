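# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# C-locale character sort so orderings are platform-independent
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

# derive a stream-specific seed from a base seed, staying inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(k)) %% 2147483647)
}

assert_binary_labels <- function(labels) {
  if (!all(labels %in% c(0L, 1L))) {
    stop("phenotype labels must be coded 0 (normal) / 1 (tumor)", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both phenotype classes must be present", call. = FALSE)
  }
  invisible(labels)
}

# align a label vector to the columns of an expression-like matrix
align_labels <- function(labels, sample_ids) {
  labels <- as.integer(labels)
  if (length(labels) != length(sample_ids)) {
    stop("labels and samples differ in length (", length(labels), " vs ",
         length(sample_ids), ")", call. = FALSE)
  }
  names(labels) <- sample_ids
  assert_binary_labels(labels)
}

row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1L))
}
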