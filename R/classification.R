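#' Stratified train/validation/test split
#'
#' Splits samples within each phenotype class by a seeded shuffle into
#' train/validation/test fractions (default 60/20/20). Per class,
#' `n_train = round(f1 * n)`, `n_val = round(f2 * n)` and the remainder goes
#' to the test set, so e.g. classes of 58 and 49 samples split into
#' (35, 12, 11) and (29, 10, 10). The validation set is held out and unused
#' by the default protocol; it is available for tuning the restart
#' probability.
#'
#' @param labels 0/1 phenotype vector.
#' @param fractions Length-3 non-negative fractions summing to 1.
#' @param seed Integer seed controlling the within-class shuffle.
#' @return List with integer index vectors `train`, `validation`, `test`
#'   (each sorted) and the `seed`.
#' @export
stratified_split <- function(labels, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  labels <- as.integer(labels)
  assert_binary_labels(labels)
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0))
  set.seed(seed)
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    n <- length(idx)
    n_tr <- round(fractions[1L] * n)
    n_va <- round(fractions[2L] * n)
    n_te <- n - n_tr - n_va
    if (n_tr < 1L || n_te < 1L) {
      stop("class ", cls, " too small (", n, " samples) for a non-empty ",
           "train and test split", call. = FALSE)
    }
    perm <- idx[sample.int(length(idx))]
    out$train <- c(out$train, perm[seq_len(n_tr)])
    out$validation <- c(out$validation, perm[n_tr + seq_len(n_va)])
    out$test <- c(out$test, perm[n_tr + n_va + seq_len(n_te)])
  }
  list(train = sort(out$train), validation = sort(out$validation),
       test = sort(out$test), seed = seed)
}

# stratified fold assignment: within each class, seeded shuffle then
# round-robin fold ids; requires folds <= size of the smaller class
make_stratified_folds <- function(y, folds, seed) {
  y <- as.integer(y)
  mn <- min(table(y))
  if (folds > mn) {
    stop("cannot build ", folds, "-fold stratified CV: smallest class has ",
         "only ", mn, " samples", call. = FALSE)
  }
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    fold_id[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds),
                                                     length(idx))
  }
  fold_id
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of class-1 scores against 0/1 labels; tied
#' scores contribute 1/2, matching the pairwise-concordance definition
#' exactly.
#'
#' @param scores Numeric predicted scores (higher = more class 1).
#' @param labels 0/1 vector.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  assert_binary_labels(labels)
  n1 <- sum(labels == 1L)
  n0 <- length(labels) - n1
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# fit the chosen classifier on (xtr, ytr) and return class-1 scores for xte;
# feature names are replaced by syntactic placeholders for formula fitting
classifier_scores <- function(xtr, ytr, xte, classifier = c("nb", "knn", "lr"),
                              knn_k = 5L) {
  classifier <- match.arg(classifier)
  xtr <- as.matrix(xtr)
  xte <- as.matrix(xte)
  colnames(xtr) <- colnames(xte) <- paste0("f", seq_len(ncol(xtr)))
  yf <- factor(ytr, levels = c(0L, 1L))
  if (classifier == "knn") {
    k <- min(knn_k, nrow(xtr))
    pred <- class::knn(xtr, xte, yf, k = k, prob = TRUE)
    pwin <- attr(pred, "prob")
    return(ifelse(pred == "1", pwin, 1 - pwin))
  }
  if (classifier == "nb") {
    fit <- e1071::naiveBayes(x = as.data.frame(xtr), y = yf)
    return(predict(fit, as.data.frame(xte), type = "raw")[, "1"])
  }
  d <- as.data.frame(xtr)
  d$.y <- ytr
  fit <- suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(),
                                     data = d))
  as.numeric(suppressWarnings(predict(fit, newdata = as.data.frame(xte),
                                      type = "response")))
}

# mean AUC over pre-assigned stratified folds
cv_auc <- function(x, y, fold_id, classifier, knn_k = 5L) {
  aucs <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    sc <- classifier_scores(x[tr, , drop = FALSE], y[tr],
                            x[!tr, , drop = FALSE], classifier, knn_k)
    auc_score(sc, y[!tr])
  }, 0)
  mean(aucs)
}

#' Greedy forward selection of pathway features by cross-validated AUC
#'
#' Walks the ranked pathway list in order. The first pathway always
#' initializes the feature set; each subsequent candidate joins the set only
#' if it strictly increases the mean AUC over stratified k-fold
#' cross-validation on the training samples (ties reject the candidate, so
#' the trajectory of kept AUCs is strictly increasing after the first).
#' Fold assignment is seeded once and shared by all candidates so AUC
#' comparisons are like for like.
#'
#' @param a A `pathway_activity` (or pathways x samples matrix).
#' @param ranked Ordered candidate pathway ids ([rank_top_pathways()]).
#' @param labels 0/1 phenotype vector aligned with activity columns.
#' @param train_idx Training sample indices.
#' @param classifier `"nb"` (Gaussian naive Bayes), `"knn"`
#'   (k-nearest-neighbors; scores are the fraction of neighbors in class 1)
#'   or `"lr"` (logistic regression).
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @param knn_k Neighborhood size for `"knn"`.
#' @return List with `features` (selected ids in selection order),
#'   `cv_auc` (final mean CV AUC) and `trajectory` (kept-feature AUCs).
#' @export
greedy_forward_selection <- function(a, ranked, labels, train_idx,
                                     classifier = c("knn", "nb", "lr"),
                                     folds = 10L, seed = 1L, knn_k = 5L) {
  classifier <- match.arg(classifier)
  act <- if (inherits(a, "pathway_activity")) a$activity else a
  if (!length(ranked)) stop("ranked pathway list is empty", call. = FALSE)
  labels <- align_labels(labels, colnames(act))
  x <- t(act[ranked, train_idx, drop = FALSE])
  y <- as.integer(labels[train_idx])
  fold_id <- make_stratified_folds(y, folds, seed)
  selected <- character(0)
  best <- -Inf
  trajectory <- numeric(0)
  for (pid in ranked) {
    cand <- c(selected, pid)
    auc <- cv_auc(x[, cand, drop = FALSE], y, fold_id, classifier, knn_k)
    if (length(selected) == 0L || auc > best) {
      selected <- cand
      best <- auc
      trajectory <- c(trajectory, auc)
    }
  }
  list(features = selected, cv_auc = best, trajectory = trajectory)
}

#' Test-set AUC of a fitted pathway classifier
#'
#' Fits the classifier on the training samples using the selected pathway
#' features only, scores the test samples, and returns the AUC.
#'
#' @inheritParams greedy_forward_selection
#' @param features Selected pathway ids (non-empty).
#' @param test_idx Test sample indices; must contain both classes.
#' @return AUC in \[0, 1\].
#' @export
evaluate_test_auc <- function(a, features, labels, train_idx, test_idx,
                              classifier = c("knn", "nb", "lr"), knn_k = 5L) {
  classifier <- match.arg(classifier)
  act <- if (inherits(a, "pathway_activity")) a$activity else a
  if (!length(features)) stop("feature set is empty", call. = FALSE)
  labels <- align_labels(labels, colnames(act))
  yte <- as.integer(labels[test_idx])
  if (length(unique(yte)) < 2L) {
    stop("test set contains a single class; AUC undefined", call. = FALSE)
  }
  sc <- classifier_scores(t(act[features, train_idx, drop = FALSE]),
                          as.integer(labels[train_idx]),
                          t(act[features, test_idx, drop = FALSE]),
                          classifier, knn_k)
  auc_score(sc, yte)
}
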