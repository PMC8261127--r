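#' Location-scale batch harmonization
#'
#' Per gene, maps each batch's values to the pooled mean and standard
#' deviation: `out = m_g + s_g * (x - mean_batch) / sd_batch`. After
#' adjustment every batch has the same per-gene mean and (sample) variance.
#' No covariate of interest is protected, matching the harmonization used
#' before cross-platform classification. With a single batch the input is
#' returned unchanged.
#'
#' @param expr gene x sample matrix.
#' @param batch character/factor batch labels, one per sample; every batch
#'   needs at least two samples.
#' @return adjusted matrix of the same shape.
#' @export
combat_adjust <- function(expr, batch) {
  stopifnot(is.matrix(expr), length(batch) == ncol(expr))
  batch <- as.character(batch)
  sizes <- table(batch)
  if (any(sizes < 2)) {
    stop("single-sample batch: ", paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (length(sizes) == 1) return(expr)
  m <- rowMeans(expr)
  s <- apply(expr, 1, stats::sd)
  out <- expr
  for (b in names(sizes)) {
    cols <- batch == b
    xb <- expr[, cols, drop = FALSE]
    mb <- rowMeans(xb)
    sb <- apply(xb, 1, stats::sd)
    sb[sb == 0] <- 1 # constant gene within batch: centre only
    out[, cols] <- m + s * (xb - mb) / sb
  }
  out
}

#' Feature genes of a lncRNA's ceRNA pairs
#'
#' The lncRNA itself plus all its partner mRNAs in the network,
#' deduplicated and ID-sorted.
#'
#' @param network a `cerna_network` (see [build_module_cerna()] /
#'   [aggregate_networks()]).
#' @param lncrna lncRNA gene ID; must appear in the network.
#' @return character vector of feature genes (lncRNA first).
#' @export
extract_pair_features <- function(network, lncrna) {
  stopifnot(inherits(network, "cerna_network"))
  edges <- network$edges
  if (!lncrna %in% c(edges$lncrna, edges$mrna)) {
    stop("lncRNA ", lncrna, " absent from the network")
  }
  partners <- sort(unique(edges$mrna[edges$lncrna == lncrna]))
  if (!length(partners)) {
    warning("lncRNA ", lncrna, " has no partner mRNAs; using it alone")
  }
  c(lncrna, partners)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' `AUC = (sum of positive midranks - n1 (n1 + 1) / 2) / (n1 n0)`: the
#' probability that a random positive outscores a random negative, ties
#' counted half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1/TRUE = positive); both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  pos <- as.logical(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUC")
  r <- rank(scores) # midranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps the unique score thresholds from high to low and returns the
#' (FPR, TPR) staircase, starting at (0, 0) and ending at (1, 1); tied
#' scores move diagonally in one step.
#'
#' @inheritParams auc_rank
#' @return data.frame with columns `fpr`, `tpr`, monotone nondecreasing.
#' @export
roc_points <- function(scores, labels) {
  pos <- as.logical(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- pos[ord]
  grp <- cumsum(!duplicated(s)) # tie groups
  tp <- cumsum(y)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(!y)[!duplicated(grp, fromLast = TRUE)]
  data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

#' Trapezoidal AUC from ROC points
#'
#' Integration of the ROC staircase; with midrank tie handling this equals
#' [auc_rank()] exactly.
#'
#' @param roc data.frame from [roc_points()].
#' @return AUC in \[0, 1\].
#' @export
auc_from_roc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Train a random-forest rhythm classifier
#'
#' Thin adapter over `randomForest` (500 trees, default feature
#' subsampling); the contract is the class-probability output, not the tree
#' internals.
#'
#' @param x sample x feature matrix.
#' @param y binary labels (coerced to factor with positive level "1").
#' @param ntree number of trees (default 500).
#' @param seed RNG seed for reproducible forests.
#' @return a fitted `randomForest` object.
#' @export
train_rf <- function(x, y, ntree = 500, seed = 1) {
  y <- factor(as.integer(as.logical(y)), levels = c(0, 1))
  set.seed(seed)
  randomForest::randomForest(x, y, ntree = ntree)
}

#' Stratified k-fold cross-validated AUC
#'
#' Splits each class cyclically over `k` folds after a seeded shuffle,
#' trains on the remaining folds, pools the out-of-fold positive-class
#' probabilities and reports one AUC from the pooled predictions (per-fold
#' AUCs are also returned). Deterministic given the seed.
#'
#' @param x sample x feature matrix.
#' @param y binary labels; each class needs at least `k` samples.
#' @param k number of folds (default 6).
#' @param seed RNG seed.
#' @param ntree trees per forest.
#' @return list with `auc` (pooled), `fold_auc`, `oof` (out-of-fold
#'   probabilities) and `folds`.
#' @export
cross_validate_rf <- function(x, y, k = 6, seed = 1, ntree = 500) {
  y <- as.integer(as.logical(y))
  stopifnot(nrow(x) == length(y))
  if (min(table(y)) < k) stop("each class needs at least k = ", k, " samples")
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  oof <- numeric(length(y))
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- train_rf(x[!test, , drop = FALSE], y[!test],
                    ntree = ntree, seed = seed + f)
    oof[test] <- stats::predict(fit, x[test, , drop = FALSE],
                                type = "prob")[, "1"]
    fold_auc[f] <- auc_rank(oof[test], y[test])
  }
  list(auc = auc_rank(oof, y), fold_auc = fold_auc, oof = oof, folds = folds)
}

#' Evaluate a trained classifier on an independent test set
#'
#' Aligns features by gene ID (missing features are an error), predicts
#' positive-class probabilities and reports the rank-based AUC and the ROC
#' staircase.
#'
#' @param model a fitted `randomForest`.
#' @param x_test sample x feature matrix (columns must cover the model's
#'   features).
#' @param y_test binary labels, both classes present.
#' @return list with `auc`, `roc` and `prob`.
#' @export
evaluate_test <- function(model, x_test, y_test) {
  feats <- rownames(model$importance)
  missing <- setdiff(feats, colnames(x_test))
  if (length(missing)) {
    stop("test matrix lacks feature(s): ", paste(missing, collapse = ", "))
  }
  y <- as.integer(as.logical(y_test))
  if (length(unique(y)) < 2) stop("single-class test labels")
  prob <- stats::predict(model, x_test[, feats, drop = FALSE],
                         type = "prob")[, "1"]
  list(auc = auc_rank(prob, y), roc = roc_points(prob, y), prob = prob)
}

#' Batch-harmonized random-forest classification with held-out validation
#'
#' Merges the training samples (counts-derived expression, AF/AF and SR/SR
#' groups only) with the independent test cohort on the feature genes,
#' optionally removes batch effects with [combat_adjust()], cross-validates
#' on the training samples and evaluates on the test samples.
#'
#' @param train_expr feature x sample training matrix.
#' @param train_labels binary training labels.
#' @param test_expr feature x sample test matrix (same feature rows).
#' @param test_labels binary test labels.
#' @param train_batch batch labels of the training samples.
#' @param batch_removal harmonize batches before fitting (default TRUE).
#' @param k CV folds (default 6).
#' @param seed RNG seed.
#' @param ntree trees per forest.
#' @return object of class `classifier_report`: list with `features`,
#'   `cv_auc`, `fold_auc`, `test_auc`, `roc`, `batch_removal`, `seed`.
#' @export
classify_rhythm <- function(train_expr, train_labels, test_expr, test_labels,
                            train_batch, batch_removal = TRUE, k = 6,
                            seed = 1, ntree = 500) {
  stopifnot(identical(rownames(train_expr), rownames(test_expr)))
  merged <- cbind(train_expr, test_expr)
  batch <- c(as.character(train_batch), rep("test", ncol(test_expr)))
  if (batch_removal) merged <- combat_adjust(merged, batch)
  x_train <- t(merged[, seq_len(ncol(train_expr)), drop = FALSE])
  x_test <- t(merged[, -seq_len(ncol(train_expr)), drop = FALSE])
  cv <- cross_validate_rf(x_train, train_labels, k = k, seed = seed,
                          ntree = ntree)
  fit <- train_rf(x_train, train_labels, ntree = ntree, seed = seed)
  ev <- evaluate_test(fit, x_test, test_labels)
  structure(list(
    features = rownames(train_expr), cv_auc = cv$auc, fold_auc = cv$fold_auc,
    test_auc = ev$auc, roc = ev$roc, batch_removal = batch_removal,
    seed = seed
  ), class = "classifier_report")
}
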