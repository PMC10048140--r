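# Independent brute-force oracles. These deliberately avoid the package's
# vectorized/sparse code paths: dense matrices, explicit loops, direct
# linear solves.

# AUC as the fraction of concordant (tumor, normal) score pairs, ties = 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# closed-form restart solve: H_inf = r (I - (1 - r) T')^{-1} H0
solve_walk <- function(trans, h0, r) {
  Td <- as.matrix(trans)
  n <- nrow(Td)
  as.numeric(r * solve(diag(n) - (1 - r) * t(Td), h0))
}

# random directed graph with entropy-weighted transition built by the package
random_walk_net <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  n_edges <- sample(n_nodes:(3 * n_nodes), 1)
  edges <- unique(cbind(sample(nodes, n_edges, replace = TRUE),
                        sample(nodes, n_edges, replace = TRUE)))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  net <- pathway_network("rand", edges, nodes = nodes)
  ew <- setNames(runif(n_nodes, 0.05, 1), nodes)
  ew <- ew / sum(ew)
  build_entropy_transition(net, ew)
}

# conventional DRW-style activity, written from scratch with loops:
# plain out-degree-normalized dense transition, explicit power iteration,
# sign-adjusted weighted sum with an equal-weight denominator
drw_reference_activity <- function(edges, nodes, pathways, gene_stats, znorm,
                                   h0, r, alpha = 0.05) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(edges))) A[edges[e, 1], edges[e, 2]] <- 1
  Td <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) {
    deg <- sum(A[i, ])
    if (deg == 0) Td[i, i] <- 1 else Td[i, ] <- A[i, ] / deg
  }
  h <- h0
  for (it in 1:10000) {
    h_new <- (1 - r) * as.numeric(t(Td) %*% h) + r * h0
    if (sum(abs(h_new - h)) < 1e-13) { h <- h_new; break }
    h <- h_new
  }
  names(h) <- nodes
  sig <- gene_stats$gene_id[gene_stats$p_value < alpha]
  scope <- intersect(nodes, rownames(znorm))
  ew_equal <- 1 / length(scope)
  out <- list()
  for (pid in names(pathways)) {
    used <- intersect(intersect(pathways[[pid]], sig), scope)
    if (!length(used)) next
    a <- numeric(ncol(znorm))
    for (g in used) {
      i <- match(g, gene_stats$gene_id)
      w <- h[g] * gene_stats$pct[i] * sign(gene_stats$t[i])
      a <- a + w * znorm[g, ]
    }
    out[[pid]] <- a / sqrt(length(used) * ew_equal^2)
  }
  do.call(rbind, out)
}
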