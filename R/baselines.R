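#' Baseline classifiers
#'
#' The comparison classifiers used alongside the adaptation method:
#' k-nearest-neighbour, a linear max-margin classifier (one-vs-rest
#' hinge loss, full-batch Pegasos-style subgradient descent -- no SVM
#' package ships with the target environment, so the optimizer is
#' built in) and a CART-style decision tree (greedy Gini splits).
#' Inputs are z-scored with training statistics; trees are scale
#' invariant but get the same treatment for uniformity.
#'
#' @param kind one of `"knn"`, `"svm"`, `"tree"`.
#' @param Xtrain `d x n` training feature matrix (columns = segments).
#' @param ytrain training labels.
#' @param Xtest `d x m` test feature matrix.
#' @param knn_k neighbours for `"knn"` (default 1).
#' @param ... tuning parameters passed to the underlying fitter
#'   (`lambda`, `epochs` for `"svm"`; `max_depth`, `min_split` for
#'   `"tree"`).
#' @return character predictions of length `m`.
#' @export
baseline_fit_predict <- function(kind = c("knn", "svm", "tree"),
                                 Xtrain, ytrain, Xtest, knn_k = 1L, ...) {
  kind <- match.arg(kind)
  Xtrain <- as.matrix(Xtrain); Xtest <- as.matrix(Xtest)
  nrm <- normalize_features(Xtrain)
  Xtr <- nrm$X
  Xte <- normalize_features(Xtest, nrm$model)$X
  switch(kind,
         knn = knn_classify(Xtr, ytrain, Xte, k = knn_k),
         svm = .linear_svm_predict(Xtr, ytrain, Xte, ...),
         tree = .tree_predict(Xtr, ytrain, Xte, ...))
}

# one-vs-rest linear hinge-loss classifier, deterministic full-batch
# subgradient descent with Pegasos step sizes
.linear_svm_predict <- function(Xtr, ytrain, Xte, lambda = 1e-3,
                                epochs = 200L) {
  classes <- .default_classes(as.character(ytrain))
  d <- nrow(Xtr); n <- ncol(Xtr)
  Xa <- rbind(Xtr, 1)                       # bias via augmented feature
  scores_te <- matrix(0, ncol(Xte), length(classes))
  Xa_te <- rbind(Xte, 1)
  for (ci in seq_along(classes)) {
    y <- ifelse(as.character(ytrain) == classes[ci], 1, -1)
    w <- numeric(d + 1L)
    for (t in seq_len(epochs)) {
      marg <- y * drop(crossprod(Xa, w))
      viol <- marg < 1
      grad <- lambda * w -
        if (any(viol)) rowMeans(Xa[, viol, drop = FALSE] *
                                  rep(y[viol], each = d + 1L))
        else numeric(d + 1L)
      w <- w - (1 / (lambda * t)) * grad
    }
    scores_te[, ci] <- drop(crossprod(Xa_te, w))
  }
  classes[max.col(scores_te, ties.method = "first")]
}

# greedy Gini decision tree on columns-as-samples matrices
.tree_predict <- function(Xtr, ytrain, Xte, max_depth = 12L,
                          min_split = 5L) {
  y <- factor(as.character(ytrain))
  classes <- levels(y)
  yi <- as.integer(y)
  Xtr <- t(Xtr); Xte <- t(Xte)              # rows = samples
  C <- length(classes)

  best_split <- function(idx) {
    n <- length(idx)
    parent_counts <- tabulate(yi[idx], C)
    best <- list(gain = 0)
    for (j in seq_len(ncol(Xtr))) {
      v <- Xtr[idx, j]
      o <- order(v)
      vs <- v[o]; ys <- yi[idx][o]
      cum <- apply(one_hot(ys, C), 2L, cumsum)  # n x C left counts
      nl <- seq_len(n)
      valid <- which(diff(vs) > 0)
      if (!length(valid)) next
      gl <- 1 - rowSums((cum / nl)^2)
      cr <- matrix(parent_counts, n, C, byrow = TRUE) - cum
      nr <- n - nl
      gr <- 1 - rowSums((cr / pmax(nr, 1))^2)
      g0 <- 1 - sum((parent_counts / n)^2)
      gain <- g0 - (nl * gl + nr * gr) / n
      gain[setdiff(seq_len(n), valid)] <- -Inf
      i <- which.max(gain)
      if (gain[i] > best$gain + 1e-12) {
        best <- list(gain = gain[i], feature = j,
                     threshold = (vs[i] + vs[i + 1L]) / 2)
      }
    }
    if (best$gain > 1e-12) best else NULL
  }

  grow <- function(idx, depth) {
    counts <- tabulate(yi[idx], C)
    node <- list(label = which.max(counts))
    if (depth >= max_depth || length(idx) < min_split ||
        sum(counts > 0) == 1L)
      return(node)
    sp <- best_split(idx)
    if (is.null(sp)) return(node)
    left <- idx[Xtr[idx, sp$feature] <= sp$threshold]
    right <- setdiff(idx, left)
    if (!length(left) || !length(right)) return(node)
    node$feature <- sp$feature
    node$threshold <- sp$threshold
    node$left <- grow(left, depth + 1L)
    node$right <- grow(right, depth + 1L)
    node
  }

  tree <- grow(seq_len(nrow(Xtr)), 0L)
  classify <- function(x, node) {
    while (!is.null(node$feature)) {
      node <- if (x[node$feature] <= node$threshold) node$left
      else node$right
    }
    node$label
  }
  classes[vapply(seq_len(nrow(Xte)),
                 function(i) classify(Xte[i, ], tree), integer(1))]
}
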