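# Classification metrics and stratified cross-validation folds.

#' Stratified k-fold cross-validation indices
#'
#' Partitions the indices of `labels` into `k` disjoint folds, each
#' containing every class label, with per-class counts differing by at most
#' one between folds. Errors if any class has fewer than `k` members.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds.
#' @param seed RNG seed for the within-class shuffles.
#' @return List of `k` integer index vectors.
#' @export
#' @examples
#' folds <- stratified_folds(rep(0:2, c(60, 30, 9)), k = 3, seed = 1)
#' sapply(folds, length)
stratified_folds <- function(labels, k = 3L, seed = 1L) {
  assert_that(is_count(k) && k >= 2, "k must be an integer >= 2")
  tab <- table(labels)
  short <- names(tab)[tab < k]
  if (length(short) > 0) {
    rlang::abort(sprintf("class %s has fewer than k = %d members",
                         paste(short, collapse = ", "), k))
  }
  folds <- vector("list", k)
  with_seed(derive_seed(seed, "folds"), {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      assign_to <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
      }
    }
  })
  lapply(folds, sort)
}

#' Classification accuracy
#'
#' Fraction of predictions exactly matching the true labels.
#'
#' @param pred,true Equal-length label vectors.
#' @return A fraction in `[0, 1]`.
#' @export
accuracy <- function(pred, true) {
  assert_that(length(pred) == length(true) && length(true) > 0,
              "pred and true must be non-empty and of equal length")
  mean(pred == true)
}

#' Confusion matrix
#'
#' @param pred,true Equal-length label vectors.
#' @param levels Class levels defining row/column order (default: sorted
#'   union of observed labels).
#' @return Square matrix with true classes in rows and predicted classes
#'   in columns.
#' @export
confusion_matrix <- function(pred, true, levels = sort(unique(c(pred, true)))) {
  assert_that(length(pred) == length(true) && length(true) > 0,
              "pred and true must be non-empty and of equal length")
  tab <- table(factor(true, levels = levels), factor(pred, levels = levels))
  m <- matrix(as.integer(tab), length(levels), length(levels),
              dimnames = list(true = levels, pred = levels))
  m
}

#' Macro-averaged precision, recall and F1
#'
#' Per-class one-vs-rest precision (`TP / (TP + FP)`), recall
#' (`TP / (TP + FN)`) and their harmonic mean F1, averaged with equal class
#' weight (macro). A class with a zero denominator contributes 0 — this is
#' what makes macro-F1 collapse for near-constant predictors under heavy
#' class imbalance.
#'
#' @param pred,true Equal-length label vectors.
#' @param levels Class levels; defaults to the sorted union of observed
#'   labels.
#' @return Named list with `precision`, `recall`, `f1` (macro averages) and
#'   a `per_class` tibble.
#' @export
#' @examples
#' precision_recall_f1(c(0, 0, 1), c(0, 1, 1))$f1
precision_recall_f1 <- function(pred, true,
                                levels = sort(unique(c(pred, true)))) {
  cm <- confusion_matrix(pred, true, levels)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       per_class = tibble(class = levels, precision = unname(prec),
                          recall = unname(rec), f1 = unname(f1)))
}
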