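# one repeat of the evaluation protocol: split, train-only statistics,
# bi-walk, activity inference, ranking, greedy selection, test AUC

run_single_repeat <- function(expr, labels, networks, pathway_sets, seed,
                              r = 0.5, alpha = 0.05, top_k = 50L,
                              classifier = "knn", folds = 10L, knn_k = 5L,
                              w0_orientation = "inverse", sign_adjust = FALSE,
                              tol = 1e-10, max_iter = 1000L) {
  split <- stratified_split(labels, seed = seed)
  tr <- split$train
  # all per-gene statistics are estimated from the training samples only;
  # the fitted transform is then applied to every sample
  mu <- rowMeans(expr[, tr, drop = FALSE])
  sdv <- row_sds(expr[, tr, drop = FALSE])
  keep <- sdv > 1e-12
  zn <- (expr[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  gs <- score_genes(expr[keep, tr, drop = FALSE], labels[tr],
                    w0_orientation = w0_orientation)
  w0 <- stats::setNames(gs$w0, gs$gene_id)
  entropy <- gene_entropy(expr[keep, tr, drop = FALSE])

  prepared <- vector("list", 2L)
  ews <- vector("list", 2L)
  for (i in 1:2) {
    net <- networks[[i]]
    common <- intersect(net$nodes, names(entropy))
    if (!length(common)) {
      stop("network '", net$name, "' shares no genes with the expression data",
           call. = FALSE)
    }
    ews[[i]] <- entropy_weights(entropy[common])
    prepared[[i]] <- build_entropy_transition(net, ews[[i]])
  }
  walks <- bi_random_walk(prepared[[1L]], prepared[[2L]], w0, r = r,
                          tol = tol, max_iter = max_iter)
  acts <- lapply(1:2, function(i) {
    suppressMessages(
      infer_pathway_activity(pathway_sets[[i]], walks[[i]], gs, zn, ews[[i]],
                             alpha = alpha, sign_adjust = sign_adjust))
  })
  combined <- combine_network_profiles(acts[[1L]], acts[[2L]])
  if (!nrow(combined$activity)) {
    stop("no pathway retained any significant gene; cannot classify",
         call. = FALSE)
  }
  ranked <- rank_top_pathways(combined, labels, tr, k = top_k)
  sel <- greedy_forward_selection(combined, ranked, labels, tr,
                                  classifier = classifier, folds = folds,
                                  seed = seed, knn_k = knn_k)
  test_auc <- evaluate_test_auc(combined, sel$features, labels, tr,
                                split$test, classifier = classifier,
                                knn_k = knn_k)
  list(split = split, ranking = ranked, features = sel$features,
       cv_auc = sel$cv_auc, trajectory = sel$trajectory,
       test_auc = test_auc, activity = combined)
}

#' Repeated stratified evaluation of the e-DRW pathway classifier
#'
#' Runs the full protocol `repeats` times, each with a fresh seeded
#' 60/20/20 stratified split: gene scoring, entropy weighting, the bi-walk
#' and pathway ranking are recomputed per repeat from that repeat's training
#' samples only, the greedy forward selection optimizes mean AUC over
#' stratified k-fold cross-validation on the training set, and the optimized
#' feature set is evaluated once on the held-out test samples. Reported are
#' the per-repeat test AUCs, their mean and standard deviation, and how
#' often each pathway was selected across repeats (the "risk-active"
#' pathway frequency).
#'
#' @param expr Complete numeric genes x samples matrix (impute first; see
#'   [impute_row_mean()]).
#' @param labels 0/1 phenotype vector aligned with the columns of `expr`.
#' @param networks List of two [pathway_network()] objects.
#' @param pathway_sets List of two [pathway_collection()] objects, parallel
#'   to `networks`.
#' @param r Restart probability of the walk.
#' @param alpha Gene-level p-value threshold for pathway membership.
#' @param top_k Number of ranked pathways fed to the greedy selection.
#' @param classifier,folds,knn_k See [greedy_forward_selection()].
#' @param repeats Number of independent split-and-evaluate repetitions.
#' @param base_seed Master seed; per-repeat seeds are drawn from it.
#' @param w0_orientation,sign_adjust See [initial_weight_minmax()] and
#'   [infer_pathway_activity()].
#' @param tol,max_iter Walk convergence controls.
#' @return Object of class `edrw_experiment`: list with `results` (one row
#'   per repeat: seed, test AUC, CV AUC, number of features), `selected` and
#'   `rankings` (per-repeat lists), `selection_freq`, `mean_auc`, `sd_auc`
#'   and the call parameters.
#' @export
run_repeated_experiment <- function(expr, labels, networks, pathway_sets,
                                    r = 0.5, alpha = 0.05, top_k = 50L,
                                    classifier = "knn", folds = 10L,
                                    knn_k = 5L, repeats = 10L, base_seed = 1L,
                                    w0_orientation = "inverse",
                                    sign_adjust = FALSE, tol = 1e-10,
                                    max_iter = 1000L) {
  if (anyNA(expr)) stop("expression contains missing values; run impute_row_mean() first",
                        call. = FALSE)
  labels <- align_labels(labels, colnames(expr))
  set.seed(base_seed)
  rep_seeds <- sample.int(2147483646L, repeats)
  runs <- lapply(rep_seeds, function(s) {
    run_single_repeat(expr, labels, networks, pathway_sets, seed = s,
                      r = r, alpha = alpha, top_k = top_k,
                      classifier = classifier, folds = folds, knn_k = knn_k,
                      w0_orientation = w0_orientation,
                      sign_adjust = sign_adjust, tol = tol,
                      max_iter = max_iter)
  })
  results <- data.frame(
    repeat_id = seq_len(repeats),
    seed = rep_seeds,
    test_auc = vapply(runs, `[[`, 0, "test_auc"),
    cv_auc = vapply(runs, `[[`, 0, "cv_auc"),
    n_features = vapply(runs, function(x) length(x$features), 0L)
  )
  selected <- lapply(runs, `[[`, "features")
  freq_tab <- table(unlist(selected))
  freq <- stats::setNames(as.integer(freq_tab), names(freq_tab))
  freq <- freq[order_c(-freq, names(freq))]
  structure(list(results = results, selected = selected,
                 rankings = lapply(runs, `[[`, "ranking"),
                 selection_freq = freq,
                 mean_auc = mean(results$test_auc),
                 sd_auc = stats::sd(results$test_auc),
                 params = list(r = r, alpha = alpha, top_k = top_k,
                               classifier = classifier, folds = folds,
                               knn_k = knn_k, repeats = repeats,
                               base_seed = base_seed,
                               w0_orientation = w0_orientation,
                               sign_adjust = sign_adjust)),
            class = "edrw_experiment")
}

#' @export
print.edrw_experiment <- function(x, ...) {
  p <- x$params
  cat("e-DRW repeated experiment (", p$repeats, " repeats, ", p$classifier,
      ", r = ", p$r, ")\n", sep = "")
  cat("  mean test AUC: ", format(x$mean_auc, digits = 4),
      " (sd ", format(x$sd_auc, digits = 3), ")\n", sep = "")
  cat("  per-repeat AUC: ",
      paste(format(x$results$test_auc, digits = 3), collapse = " "), "\n",
      sep = "")
  top <- utils::head(x$selection_freq, 5L)
  cat("  most-selected pathways: ",
      paste(names(top), " (", top, "/", p$repeats, ")", sep = "",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
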