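#' Entropy-based pathway activity inference
#'
#' For each pathway, the per-sample activity aggregates its significant
#' member genes: with used genes `i = 1..nj` (members passing the raw
#' p < alpha filter that appear in the walked network and the normalized
#' expression),
#'
#' `a_k(Pj) = sum_i H_inf(g_i) * PCT(g_i) * z_k(g_i) / sqrt(sum_i ew(g_i)^2)`
#'
#' where `H_inf` is the walk's stationary weight, `PCT` the combined
#' t-and-correlation gene score, `z_k` the z-normalized expression of the
#' gene in sample k, and `ew` the entropy weight. With `sign_adjust` the
#' z-values are multiplied by the sign of the gene's t-statistic so genes
#' regulated in opposite directions reinforce rather than cancel. Pathways
#' with no usable gene are dropped (reported via message).
#'
#' @param pathways A [pathway_collection()].
#' @param walk An `edrw_walk` from [walk_with_restart()] or
#'   [bi_random_walk()].
#' @param gene_stats Data frame from [score_genes()].
#' @param znorm Z-normalized genes x samples matrix ([znormalize()]).
#' @param ew Named entropy-weight vector over the network's expressed genes
#'   ([entropy_weights()]).
#' @param alpha Gene-level significance threshold (raw p-values, no
#'   multiplicity correction).
#' @param sign_adjust Multiply z-values by `sign(t)` per gene.
#' @return Object of class `pathway_activity`: list with `activity`
#'   (pathways x samples matrix), `genes_used` (named list), `network`.
#' @export
infer_pathway_activity <- function(pathways, walk, gene_stats, znorm, ew,
                                   alpha = 0.05, sign_adjust = FALSE) {
  stopifnot(inherits(pathways, "pathway_collection"),
            inherits(walk, "edrw_walk"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!length(walk$h_inf)) stop("empty walk vector", call. = FALSE)
  sig <- gene_stats$gene_id[gene_stats$p_value < alpha]
  usable <- intersect(intersect(sig, names(walk$h_inf)),
                      intersect(rownames(znorm), names(ew)))
  stat_idx <- match(usable, gene_stats$gene_id)
  weight <- walk$h_inf[usable] * gene_stats$pct[stat_idx]
  if (sign_adjust) weight <- weight * sign(gene_stats$t[stat_idx])
  weight <- stats::setNames(as.numeric(weight), usable)

  rows <- lapply(pathways$pathway_ids, function(pid) {
    used <- intersect(pathways$members[[pid]], usable)
    if (!length(used)) return(NULL)
    denom <- sqrt(sum(ew[used]^2))
    if (denom == 0) return(NULL)
    num <- colSums(znorm[used, , drop = FALSE] * weight[used])
    list(id = pid, used = used, activity = num / denom)
  })
  kept <- !vapply(rows, is.null, TRUE)
  if (!any(kept)) {
    message("no pathway retained any significant gene on network '",
            walk$network, "'")
    return(structure(list(
      activity = matrix(numeric(0), nrow = 0L, ncol = ncol(znorm),
                        dimnames = list(NULL, colnames(znorm))),
      genes_used = list(), network = walk$network),
      class = "pathway_activity"))
  }
  if (any(!kept)) {
    message("dropping ", sum(!kept), " pathway(s) with no usable gene: ",
            paste(utils::head(pathways$pathway_ids[!kept], 5L),
                  collapse = ", "))
  }
  rows <- rows[kept]
  act <- do.call(rbind, lapply(rows, `[[`, "activity"))
  rownames(act) <- vapply(rows, `[[`, "", "id")
  colnames(act) <- colnames(znorm)
  structure(list(activity = act,
                 genes_used = stats::setNames(lapply(rows, `[[`, "used"),
                                              rownames(act)),
                 network = walk$network),
            class = "pathway_activity")
}

#' @export
print.pathway_activity <- function(x, ...) {
  cat("Pathway activity (", paste(unique(x$network), collapse = "+"), "): ",
      nrow(x$activity), " pathways x ", ncol(x$activity), " samples\n",
      sep = "")
  invisible(x)
}

#' Combine the activity profiles of two networks
#'
#' Row-binds the pathway activity matrices inferred on the two networks.
#' Pathway ids are prefixed with their source network name so the same
#' pathway name occurring in both sources stays distinct.
#'
#' @param a,b `pathway_activity` objects over identical samples in identical
#'   order.
#' @return A combined `pathway_activity`.
#' @export
combine_network_profiles <- function(a, b) {
  stopifnot(inherits(a, "pathway_activity"), inherits(b, "pathway_activity"))
  sa <- colnames(a$activity)
  sb <- colnames(b$activity)
  if (!identical(sa, sb)) {
    stop("sample mismatch between profiles; symmetric difference: ",
         paste(utils::head(c(setdiff(sa, sb), setdiff(sb, sa)), 10L),
               collapse = ", "), call. = FALSE)
  }
  tag <- function(x) {
    if (!nrow(x$activity)) return(x$activity)
    out <- x$activity
    rownames(out) <- paste(x$network, rownames(out), sep = ":")
    out
  }
  act <- rbind(tag(a), tag(b))
  used <- c(a$genes_used, b$genes_used)
  if (length(used)) {
    names(used) <- c(if (length(a$genes_used))
      paste(a$network, names(a$genes_used), sep = ":"),
      if (length(b$genes_used))
        paste(b$network, names(b$genes_used), sep = ":"))
  }
  structure(list(activity = act, genes_used = used,
                 network = c(a$network, b$network)),
            class = "pathway_activity")
}

#' Rank pathways by the t-statistic of their activity
#'
#' Orders pathways by decreasing absolute equal-variance t-statistic of
#' their activity vector between the two phenotype classes, computed on the
#' training samples only (leakage-safe), and returns the top `k` ids. Ties
#' are broken lexicographically by pathway id.
#'
#' @param a A `pathway_activity` (or plain pathways x samples matrix).
#' @param labels 0/1 phenotype vector aligned with the activity columns.
#' @param train_idx Indices (or names) of the training samples; must contain
#'   both classes.
#' @param k Number of pathways to return (capped at the number available).
#' @return Character vector of ranked pathway ids.
#' @export
rank_top_pathways <- function(a, labels, train_idx, k = 50L) {
  act <- if (inherits(a, "pathway_activity")) a$activity else a
  if (!nrow(act)) stop("no pathways to rank", call. = FALSE)
  labels <- align_labels(labels, colnames(act))
  sub <- act[, train_idx, drop = FALSE]
  ltr <- labels[train_idx]
  if (length(unique(ltr)) < 2L) {
    stop("training subset contains a single class", call. = FALSE)
  }
  tt <- row_ttest(sub, ltr)
  ord <- order_c(-abs(tt$t), rownames(sub))
  rownames(sub)[ord][seq_len(min(k, nrow(sub)))]
}
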