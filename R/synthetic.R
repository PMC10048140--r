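#' Specification for a synthetic two-network cohort
#'
#' Describes a synthetic study: a gene universe split between two directed
#' pathway networks with a shared fraction, pathway memberships drawn from
#' each network's gene pool, directed Erdos-Renyi edges within pathways plus
#' sparse cross-pathway edges, and an expression cohort with standard-normal
#' baseline noise in which the member genes of a few planted pathways are
#' shifted by `delta` noise standard deviations in the tumor class. The
#' defaults describe the package's reference evaluation cohort: 2000 genes,
#' 50 pathways of 10-40 genes per network with 30% of genes shared between
#' networks, 3 planted pathways at effect size 1.5 with fully coherent
#' direction, and 60 normal + 60 tumor samples.
#'
#' @param n_genes Size of the gene universe.
#' @param n_pathways Pathways generated per network.
#' @param size_range Inclusive (min, max) pathway size.
#' @param p_within Directed edge probability inside a pathway.
#' @param p_between Directed edge probability between any two genes of a
#'   network's pool (sparse background edges).
#' @param shared_gene_frac Fraction of the universe shared by both networks.
#' @param n_planted Number of planted differentially expressed pathways
#'   (drawn from the first network).
#' @param delta Additive class shift, in units of the noise sd.
#' @param coherence Fraction of planted genes shifted upward (+delta); the
#'   rest are shifted downward.
#' @param n_normal,n_tumor Class sample counts.
#' @param missing_rate Fraction of cells masked as missing.
#' @param seed Master seed; generation is fully deterministic given the
#'   spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L, n_pathways = 50L,
                           size_range = c(10L, 40L), p_within = 0.1,
                           p_between = 5e-4, shared_gene_frac = 0.3,
                           n_planted = 3L, delta = 1.5, coherence = 1,
                           n_normal = 60L, n_tumor = 60L, missing_rate = 0,
                           seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_pathways = as.integer(n_pathways),
               size_range = as.integer(size_range),
               p_within = p_within, p_between = p_between,
               shared_gene_frac = shared_gene_frac,
               n_planted = as.integer(n_planted), delta = delta,
               coherence = coherence, n_normal = as.integer(n_normal),
               n_tumor = as.integer(n_tumor), missing_rate = missing_rate,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_genes >= 1L, n_pathways >= 0L,
              length(size_range) == 2L, size_range[1L] >= 1L,
              size_range[1L] <= size_range[2L],
              p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
              shared_gene_frac >= 0, shared_gene_frac <= 1,
              n_planted >= 0L, n_planted <= n_pathways, delta >= 0,
              coherence >= 0, coherence <= 1, n_normal >= 1L, n_tumor >= 1L,
              missing_rate >= 0, missing_rate < 1)
  })
  pool <- floor(spec$n_genes * spec$shared_gene_frac) +
    floor(spec$n_genes * (1 - spec$shared_gene_frac) / 2)
  if (spec$n_pathways > 0L && spec$size_range[2L] > pool) {
    stop("pathway size bound ", spec$size_range[2L],
         " exceeds the per-network gene pool (", pool, ")", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

#' Simulate two directed pathway networks with gene-set annotation
#'
#' Generates the topology side of a [synthetic_spec()]: two networks (named
#' `KEGG` and `PID` after the roles they emulate) over partially shared gene
#' pools. Each pathway is a directed Erdos-Renyi block over its member
#' genes; additional sparse directed edges connect arbitrary pool genes.
#' Pathway memberships are drawn independently, so moderate overlap between
#' pathways arises naturally. Deterministic given the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `networks` (two [pathway_network()]), `pathways` (two
#'   [pathway_collection()]), `planted` (planted pathway ids, all from the
#'   first network) and `planted_genes`.
#' @export
simulate_networks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, 1L))
  genes <- sprintf("g%05d", seq_len(spec$n_genes))
  shuffled <- sample(genes)
  n_shared <- floor(spec$n_genes * spec$shared_gene_frac)
  n_excl <- floor((spec$n_genes - n_shared) / 2)
  shared <- shuffled[seq_len(n_shared)]
  pools <- list(c(shared, shuffled[n_shared + seq_len(n_excl)]),
                c(shared, shuffled[n_shared + n_excl +
                                     seq_len(min(n_excl, spec$n_genes - n_shared - n_excl))]))
  names(pools) <- c("KEGG", "PID")
  prefixes <- c(KEGG = "K", PID = "P")

  networks <- vector("list", 2L)
  collections <- vector("list", 2L)
  for (i in 1:2) {
    nm <- names(pools)[i]
    pool <- pools[[i]]
    size_choices <- seq(spec$size_range[1L], spec$size_range[2L])
    sizes <- if (spec$n_pathways > 0L) {
      size_choices[sample.int(length(size_choices), spec$n_pathways,
                              replace = TRUE)]
    } else integer(0)
    members <- lapply(sizes, function(sz) sort_c(sample(pool, sz)))
    names(members) <- sprintf("%s%02d", prefixes[nm], seq_along(members))
    edges <- do.call(rbind, lapply(members, function(g) {
      er_directed_edges(g, spec$p_within)
    }))
    cross <- er_directed_edges(pool, spec$p_between)
    edges <- rbind(edges, cross)
    if (is.null(edges)) edges <- matrix(character(0), ncol = 2L)
    dup <- duplicated(paste(edges[, 1L], edges[, 2L], sep = "\r"))
    networks[[i]] <- pathway_network(nm, edges[!dup, , drop = FALSE],
                                     nodes = sort_c(pool))
    collections[[i]] <- if (length(members)) {
      pathway_collection(members, source = nm)
    } else {
      structure(list(pathway_ids = character(0), members = list(),
                     source = character(0), descriptions = character(0)),
                class = "pathway_collection")
    }
  }
  planted <- if (spec$n_planted > 0L) {
    sort_c(sample(collections[[1L]]$pathway_ids, spec$n_planted))
  } else character(0)
  planted_genes <- if (length(planted)) {
    sort_c(unique(unlist(collections[[1L]]$members[planted])))
  } else character(0)
  list(networks = networks, pathways = collections, planted = planted,
       planted_genes = planted_genes)
}

# directed Erdos-Renyi edges among `g` with probability p, no self-loops;
# pair enumeration order is fixed so generation is platform-deterministic
er_directed_edges <- function(g, p) {
  n <- length(g)
  if (n < 2L || p <= 0) return(NULL)
  n_pairs <- n * (n - 1)
  k <- stats::rbinom(1L, n_pairs, p)
  if (k == 0L) return(NULL)
  idx <- sample(n_pairs, k)
  i0 <- (idx - 1L) %/% (n - 1L)
  j0 <- (idx - 1L) %% (n - 1L)
  j0 <- j0 + (j0 >= i0)
  cbind(g[i0 + 1L], g[j0 + 1L])
}

#' Simulate an expression cohort with planted risk pathways
#'
#' Baseline expression is i.i.d. standard normal per gene and sample. The
#' member genes of the planted pathways receive an additive shift in the
#' tumor samples: a `coherence` fraction gets `+delta`, the rest `-delta`.
#' Cells are then masked as missing at `missing_rate`. Ground truth (planted
#' pathway ids and per-gene true effects) is returned alongside so recovery
#' metrics can be computed without further inputs.
#'
#' @param sim Output of [simulate_networks()], or `NULL` for a pure-noise
#'   cohort with no planted structure.
#' @param spec The same [synthetic_spec()].
#' @return List with `expr` (genes x samples matrix, `NA` where masked),
#'   `labels` (named 0/1 vector), `truth` (list: `planted`, `effects` data
#'   frame of shifted genes).
#' @export
simulate_expression <- function(sim, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, 2L))
  genes <- sprintf("g%05d", seq_len(spec$n_genes))
  n <- spec$n_normal + spec$n_tumor
  samples <- c(sprintf("N%03d", seq_len(spec$n_normal)),
               sprintf("T%03d", seq_len(spec$n_tumor)))
  labels <- align_labels(rep(c(0L, 1L), c(spec$n_normal, spec$n_tumor)),
                         samples)
  expr <- matrix(stats::rnorm(spec$n_genes * n), nrow = spec$n_genes,
                 dimnames = list(genes, samples))
  planted_genes <- if (is.null(sim)) character(0) else sim$planted_genes
  effects <- data.frame(gene_id = character(0), effect = numeric(0))
  if (length(planted_genes) && spec$delta > 0) {
    ord <- sample(planted_genes)
    n_up <- round(spec$coherence * length(ord))
    eff <- stats::setNames(rep(-spec$delta, length(ord)), ord)
    eff[seq_len(n_up)] <- spec$delta
    eff <- eff[sort_c(names(eff))]
    expr[names(eff), labels == 1L] <-
      expr[names(eff), labels == 1L] + eff
    effects <- data.frame(gene_id = names(eff), effect = unname(eff))
  }
  if (spec$missing_rate > 0) {
    mask <- stats::runif(length(expr)) < spec$missing_rate
    expr[mask] <- NA_real_
  }
  list(expr = expr, labels = labels,
       truth = list(planted = if (is.null(sim)) character(0) else sim$planted,
                    effects = effects))
}

#' Simulate a complete two-network cohort
#'
#' Convenience wrapper running [simulate_networks()] and
#' [simulate_expression()] for one [synthetic_spec()].
#'
#' @param spec A [synthetic_spec()] (default spec if omitted).
#' @return List with `networks`, `pathways`, `planted`, `planted_genes`,
#'   `expr`, `labels`, `truth` and the `spec`.
#' @export
simulate_cohort <- function(spec = synthetic_spec()) {
  sim <- simulate_networks(spec)
  cohort <- simulate_expression(sim, spec)
  c(sim, cohort, list(spec = spec))
}
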