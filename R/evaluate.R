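#' Evaluate predicted activity labels
#'
#' Builds the confusion matrix and the four standard indicators.  Each
#' class is scored one-vs-rest (TP, FP, FN, TN), giving per-class
#' precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and F-measure
#' `2 * precision * recall / (precision + recall)`; report-level values
#' are unweighted (macro) means over the classes, and accuracy is the
#' overall fraction correct.  A class with no predicted (or no true)
#' positives scores 0 on the affected indicator rather than NaN.  All
#' metrics are returned in percent.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes class order (default: activity codes present in
#'   `y_true`, otherwise sorted unique labels of both vectors).
#' @return object of class `har_eval`: list with `counts` (`C x C`
#'   confusion matrix, rows = truth), `percent` (row-normalized, %),
#'   `accuracy`, `precision`, `recall`, `f_measure` (macro, %), and
#'   `per_class` (data frame of per-class indicators).
#' @export
evaluate <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  if (is.null(classes)) classes <- .default_classes(c(y_true, y_pred))
  ft <- factor(y_true, levels = classes)
  fp <- factor(y_pred, levels = classes)
  if (anyNA(ft) || anyNA(fp))
    stop("labels outside the class set", call. = FALSE)
  counts <- table(truth = ft, predicted = fp)
  counts <- matrix(counts, length(classes), length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  n <- length(y_true)
  tp <- diag(counts)
  fp_ <- colSums(counts) - tp
  fn_ <- rowSums(counts) - tp
  prec <- ifelse(tp + fp_ > 0, tp / (tp + fp_), 0)
  rec <- ifelse(tp + fn_ > 0, tp / (tp + fn_), 0)
  f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  rowsum_ <- rowSums(counts)
  percent <- 100 * counts / ifelse(rowsum_ > 0, rowsum_, 1)
  structure(
    list(counts = counts,
         percent = percent,
         accuracy = 100 * sum(tp) / n,
         precision = 100 * mean(prec),
         recall = 100 * mean(rec),
         f_measure = 100 * mean(f),
         per_class = data.frame(class = classes,
                                precision = 100 * prec,
                                recall = 100 * rec,
                                f_measure = 100 * f,
                                support = rowsum_,
                                row.names = NULL)),
    class = "har_eval")
}

#' @export
print.har_eval <- function(x, digits = 2, ...) {
  cat(sprintf(
    "accuracy %.2f%% | macro precision %.2f%% recall %.2f%% F %.2f%%\n",
    x$accuracy, x$precision, x$recall, x$f_measure))
  print(round(x$percent, digits))
  invisible(x)
}

#' Rebuild label vectors from a row-percentage confusion matrix
#'
#' Published confusion matrices are often printed as row percentages.
#' Given the per-class truth counts, this reconstructs a pair of label
#' vectors whose confusion matrix reproduces the printed one, so the
#' printed table can be re-scored with [evaluate()].
#'
#' @param percent `C x C` matrix of row percentages (rows sum to 100).
#' @param n_per_class true count per class (scalar or length-`C`).
#' @param classes class names (default rownames of `percent`).
#' @return list with `y_true` and `y_pred`.
#' @export
labels_from_confusion <- function(percent, n_per_class,
                                  classes = rownames(percent)) {
  percent <- as.matrix(percent)
  C <- nrow(percent)
  if (is.null(classes)) classes <- as.character(seq_len(C))
  n_per_class <- rep_len(n_per_class, C)
  counts <- percent * n_per_class / 100
  if (max(abs(counts - round(counts))) > 1e-8)
    stop("percentages are not consistent with the class counts",
         call. = FALSE)
  counts <- round(counts)
  y_true <- rep(classes, rowSums(counts))
  y_pred <- unlist(lapply(seq_len(C), function(i)
    rep(classes, counts[i, ])))
  list(y_true = y_true, y_pred = y_pred)
}

#' k-nearest-neighbour classification
#'
#' Thin wrapper over an exact neighbour search; columns are samples.
#'
#' @param Xtrain `d x n` training matrix, `ytrain` labels.
#' @param Xtest `d x m` test matrix.
#' @param k neighbours (default 1).
#' @return character predictions of length `m`.
#' @export
knn_classify <- function(Xtrain, ytrain, Xtest, k = 1L) {
  pred <- FNN::knn(t(as.matrix(Xtrain)), t(as.matrix(Xtest)),
                   cl = factor(as.character(ytrain)), k = k)
  as.character(pred)
}
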