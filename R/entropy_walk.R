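#' Normalized Shannon entropy of each gene's expression distribution
#'
#' Following the entropy-weight method, each gene row is shifted to
#' non-negativity (`x - min(x) + eps`), normalized to a probability
#' distribution over the m samples, and scored by
#' `E = -sum(p * log p) / log(m)`, so `E` lies in \[0, 1\]: a uniform row
#' (no information) scores 1, a row concentrating its shifted mass on a
#' single sample scores near 0. Entropy is computed on the cleaned
#' (pre-z-score) matrix because z-scored rows are zero-mean with negative
#' entries.
#'
#' @param m Complete numeric genes x samples matrix.
#' @param eps Positive shift guard keeping the distribution well defined for
#'   constant rows.
#' @return Named entropy vector in \[0, 1\].
#' @export
gene_entropy <- function(m, eps = 1e-12) {
  if (ncol(m) < 2L) stop("entropy needs at least 2 samples", call. = FALSE)
  if (anyNA(m)) stop("missing values present; run impute_row_mean() first", call. = FALSE)
  shifted <- m - apply(m, 1L, min) + eps
  p <- shifted / rowSums(shifted)
  e <- -rowSums(p * log(p)) / log(ncol(m))
  pmin(pmax(e, 0), 1)
}

#' Entropy weights from node entropies
#'
#' The entropy-weight-method criterion weight: `ew_i = (1 - E_i) /
#' sum_j(1 - E_j)`. Genes whose expression varies informatively across
#' samples (low entropy) receive more weight; weights sum to one over the
#' genes supplied.
#'
#' @param E Named entropy vector in \[0, 1\] (see [gene_entropy()]).
#' @return Named weight vector summing to 1.
#' @export
entropy_weights <- function(E) {
  if (any(E < -1e-9 | E > 1 + 1e-9)) stop("entropies must lie in [0, 1]", call. = FALSE)
  d <- 1 - E
  s <- sum(d)
  if (s <= 0) {
    stop("all entropies are 1 (no information); use uniform weights instead",
         call. = FALSE)
  }
  d / s
}

#' Build the entropy edge-weighted transition matrix
#'
#' Converts a directed network into a row-stochastic transition matrix in
#' which a walker at gene `u` moves to out-neighbor `v` with probability
#' proportional to `v`'s entropy weight:
#' `T[u, v] = ew(v) / sum(ew over out-neighbors of u)`. Nodes without
#' out-edges receive a self-loop of weight 1 so probability mass is
#' conserved; a node whose out-neighbors all have zero weight falls back to
#' a uniform row over its out-neighbors (reported via message). Genes absent
#' from `ew` get weight 0. With all weights equal the matrix reduces to
#' plain out-degree normalization, i.e. the conventional directed random
#' walk transition.
#'
#' @param net A [pathway_network()].
#' @param ew Named entropy-weight vector (see [entropy_weights()]).
#' @return The network with its `transition` field set (sparse
#'   row-stochastic `dgCMatrix` over `net$nodes`).
#' @export
build_entropy_transition <- function(net, ew) {
  stopifnot(inherits(net, "pathway_network"))
  n <- length(net$nodes)
  node_w <- stats::setNames(numeric(n), net$nodes)
  common <- intersect(names(ew), net$nodes)
  node_w[common] <- ew[common]
  si <- match(net$edges[, 1L], net$nodes)
  ti <- match(net$edges[, 2L], net$nodes)
  w <- node_w[ti]
  rs <- rep(0, n)
  tab <- rowsum(w, group = si)
  rs[as.integer(rownames(tab))] <- tab[, 1L]
  outdeg <- tabulate(si, nbins = n)
  # uniform fallback for rows whose out-neighborhood carries no weight
  zero_rows <- which(outdeg > 0L & rs == 0)
  if (length(zero_rows)) {
    message("uniform fallback for ", length(zero_rows),
            " node(s) whose out-neighbors all have zero entropy weight")
    fix <- si %in% zero_rows
    w[fix] <- 1
    tab <- rowsum(w, group = si)
    rs[as.integer(rownames(tab))] <- tab[, 1L]
  }
  x <- w / rs[si]
  dangling <- which(outdeg == 0L)
  trans <- Matrix::sparseMatrix(
    i = c(si, dangling), j = c(ti, dangling),
    x = c(x, rep(1, length(dangling))),
    dims = c(n, n), dimnames = list(net$nodes, net$nodes)
  )
  bad <- abs(Matrix::rowSums(trans) - 1) > 1e-12
  if (any(bad)) stop("internal error: non-stochastic transition rows", call. = FALSE)
  net$transition <- trans
  net
}

#' Random walk with restart on a directed network
#'
#' Iterates `H_{t+1} = (1 - r) * t(T) %*% H_t + r * H_0` from `H_0` until the
#' L1 change drops below `tol` or `max_iter` is reached, where `T` is the
#' entropy edge-weighted row-stochastic transition matrix of the network and
#' `r` the restart probability. Because every row of `T` sums to one and
#' `H_0` is stochastic, total probability mass is conserved at every step.
#'
#' @param net A [pathway_network()] with its transition built
#'   (see [build_entropy_transition()]).
#' @param h0 Initial probability vector over `net$nodes` (named or in node
#'   order); non-negative, summing to 1.
#' @param r Restart probability in (0, 1\].
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap.
#' @param track_mass Record the total mass after every iteration (used by
#'   conservation checks).
#' @return Object of class `edrw_walk`: list with `network`, `r`, `h_inf`
#'   (named stationary vector), `iterations`, `converged` and, when tracked,
#'   `mass`.
#' @export
walk_with_restart <- function(net, h0, r = 0.5, tol = 1e-10, max_iter = 1000L,
                              track_mass = FALSE) {
  stopifnot(inherits(net, "pathway_network"))
  if (is.null(net$transition)) {
    stop("network '", net$name, "' has no transition matrix; ",
         "call build_entropy_transition() first", call. = FALSE)
  }
  if (r <= 0 || r > 1) stop("restart probability must lie in (0, 1]", call. = FALSE)
  n <- length(net$nodes)
  if (!is.null(names(h0))) h0 <- h0[net$nodes]
  h0 <- as.numeric(h0)
  if (length(h0) != n || anyNA(h0) || any(h0 < 0) || abs(sum(h0) - 1) > 1e-8) {
    stop("h0 must be a non-negative probability vector over the ", n,
         " network nodes", call. = FALSE)
  }
  tT <- Matrix::t(net$transition)
  h <- h0
  mass <- if (track_mass) numeric(max_iter) else NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    h_new <- (1 - r) * as.numeric(tT %*% h) + r * h0
    if (track_mass) mass[iter] <- sum(h_new)
    delta <- sum(abs(h_new - h))
    h <- h_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(network = net$name, r = r,
                 h_inf = stats::setNames(h, net$nodes),
                 iterations = iter, converged = converged,
                 mass = if (track_mass) mass[seq_len(iter)] else NULL),
            class = "edrw_walk")
}

#' @export
print.edrw_walk <- function(x, ...) {
  cat("e-DRW walk on '", x$network, "' (r = ", x$r, "): ",
      length(x$h_inf), " nodes, ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' Bi-random walk on two directed networks
#'
#' Runs the entropy-weighted random walk with restart independently on two
#' prepared networks (e.g. a KEGG-derived and a PID-derived graph). For each
#' network the start vector is the initial gene weight vector `w0` restricted
#' to that network's nodes (genes absent from the expression data contribute
#' 0) and renormalized to sum 1. The two walks are fully independent; their
#' stationary vectors feed separate pathway-activity profiles that are
#' combined afterwards ([combine_network_profiles()]).
#'
#' @param net_a,net_b [pathway_network()] objects with transitions built.
#' @param w0 Named initial gene weight vector (see
#'   [initial_weight_minmax()]).
#' @inheritParams walk_with_restart
#' @return Named list of two `edrw_walk` objects (names = network names).
#' @export
bi_random_walk <- function(net_a, net_b, w0, r = 0.5, tol = 1e-10,
                           max_iter = 1000L) {
  walks <- lapply(list(net_a, net_b), function(net) {
    h0 <- stats::setNames(numeric(length(net$nodes)), net$nodes)
    common <- intersect(names(w0), net$nodes)
    if (!length(common)) {
      stop("network '", net$name, "' shares no genes with the expression data",
           call. = FALSE)
    }
    h0[common] <- w0[common]
    s <- sum(h0)
    if (s <= 0) {
      stop("initial weights restricted to network '", net$name,
           "' are all zero", call. = FALSE)
    }
    walk_with_restart(net, h0 / s, r = r, tol = tol, max_iter = max_iter)
  })
  stats::setNames(walks, c(net_a$name, net_b$name))
}
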