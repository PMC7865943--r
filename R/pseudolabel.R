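#' Per-class source prototypes in the projected subspace
#'
#' The prototype of class `y` is the mean of the projected source
#' columns labeled `y`.  The source domain must cover the whole label
#' space.
#'
#' @param Zs `m x ns` projected source samples.
#' @param ys their labels.
#' @param classes class order (default [har_activities()] intersected
#'   with the labels present, otherwise sorted unique labels).
#' @return `m x C` matrix of prototypes, columns named by class.
#' @export
class_prototypes <- function(Zs, ys, classes = NULL) {
  Zs <- as.matrix(Zs)
  ys <- as.character(ys)
  if (is.null(classes)) classes <- .default_classes(ys)
  absent <- setdiff(classes, unique(ys))
  if (length(absent))
    stop("source domain has no samples for class(es): ",
         paste(absent, collapse = ", "), call. = FALSE)
  proto <- vapply(classes,
                  function(cl) rowMeans(Zs[, ys == cl, drop = FALSE]),
                  numeric(nrow(Zs)))
  matrix(proto, nrow = nrow(Zs), dimnames = list(NULL, classes))
}

.default_classes <- function(y) {
  acts <- har_activities()
  if (all(y %in% acts)) acts[acts %in% y] else sort(unique(y))
}

#' Nearest-class-prototype probabilities
#'
#' Soft class assignment of each target sample by a softmax over
#' negative Euclidean distances to the source prototypes:
#' `p1(y|x) = exp(-||z - proto_y||) / sum_y' exp(-||z - proto_y'||)`.
#' Computed stably by shifting with the smallest distance; rows sum to 1.
#'
#' @param Zt `m x nt` projected target samples.
#' @param prototypes `m x C` prototype matrix from [class_prototypes()].
#' @return `nt x C` probability matrix.
#' @export
ncp_probabilities <- function(Zt, prototypes) {
  # .cross_dist2 compares columns, so this is already [nt x C]
  D <- sqrt(.cross_dist2(as.matrix(Zt), prototypes))
  P <- .softmax_neg_dist(D)
  dimnames(P) <- list(NULL, colnames(prototypes))
  P
}

#' Structured-prediction probabilities via K-means
#'
#' Clusters the projected target samples into `C` groups with Lloyd's
#' algorithm, initializing the centers at the source prototypes.  Each
#' cluster inherits the class identity of the prototype that seeded it
#' (never re-matched); a cluster that empties keeps its center frozen.
#' Probabilities are the same softmax as [ncp_probabilities()] but
#' against the final cluster centers.
#'
#' @param Zt `m x nt` projected target samples (`nt >= C`).
#' @param prototypes `m x C` initial centers.
#' @param max_iter,tol Lloyd iteration cap and center-shift tolerance.
#' @return list with `p2` (`nt x C`), `centers` (`m x C`), `iterations`.
#' @export
sp_probabilities <- function(Zt, prototypes, max_iter = 100L, tol = 1e-6) {
  Zt <- as.matrix(Zt)
  C <- ncol(prototypes)
  if (ncol(Zt) < C)
    stop("need at least as many target samples as classes", call. = FALSE)
  centers <- prototypes
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    D2 <- .cross_dist2(centers, Zt)          # C x nt
    assign <- max.col(-t(D2), ties.method = "first")
    new_centers <- centers
    for (c in seq_len(C)) {
      idx <- assign == c
      if (any(idx)) new_centers[, c] <- rowMeans(Zt[, idx, drop = FALSE])
    }
    shift <- sqrt(max(colSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  D <- sqrt(.cross_dist2(Zt, centers))       # nt x C
  p2 <- .softmax_neg_dist(D)
  dimnames(p2) <- list(NULL, colnames(prototypes))
  list(p2 = p2, centers = centers, iterations = iterations)
}

#' Combine prototype and clustering probabilities into pseudo-labels
#'
#' Takes the element-wise maximum `p = max(p1, p2)` and assigns each
#' target sample the arg-max class, ties going to the lowest class
#' index.  The combined `p` need not normalize and is kept as-is.
#'
#' @param p1,p2 `nt x C` probability matrices over the same class order.
#' @return object of class `pseudo_labels`: list with `labels`
#'   (character), `p` (`nt x C`), `winner` (`"NCP"`/`"SP"` per sample,
#'   the branch achieving the winning probability), `classes`.
#' @export
combine_probabilities <- function(p1, p2) {
  stopifnot(all(dim(p1) == dim(p2)))
  p <- pmax(p1, p2)
  idx <- max.col(p, ties.method = "first")
  classes <- colnames(p1)
  winner <- ifelse(p1[cbind(seq_len(nrow(p)), idx)] >=
                     p2[cbind(seq_len(nrow(p)), idx)], "NCP", "SP")
  structure(list(labels = classes[idx], p = p, winner = winner,
                 classes = classes),
            class = "pseudo_labels")
}

#' @export
print.pseudo_labels <- function(x, ...) {
  cat("<pseudo_labels>", length(x$labels), "samples;",
      sum(x$winner == "NCP"), "NCP /", sum(x$winner == "SP"), "SP\n")
  invisible(x)
}

#' Improved pseudo-labels for an unlabeled target domain
#'
#' The two-pass pseudo-labeling stage: PCA on the pooled (normalized)
#' source + target features, a first SLPP projection learned from the
#' source only, initial pseudo-labels from the combined nearest-class-
#' prototype / structured-prediction rule, then an SLPP refit on the
#' source plus pseudo-labeled target and a second labeling pass.  The
#' refined labels initialize the joint-probability adaptation loop and
#' protect it from error accumulation due to bad initial labels.
#'
#' @param Xs,Xt normalized `d x ns` / `d x nt` feature matrices.
#' @param ys source labels.
#' @param k PCA dimensionality (default `min(128, d, n - 1)`).
#' @param m SLPP dimensionality (default `k`).
#' @param classes class order.
#' @param min_confidence optional confidence floor in `[0, 1)`; samples
#'   whose winning probability falls below it keep their label but are
#'   flagged in `confident`.  Default 0 (label every sample).
#' @return list with `labels` (refined labels, class `pseudo_labels`),
#'   `initial` (first-pass `pseudo_labels`), `slpp` (refit `slpp_model`),
#'   `pca` (`pca_model`), `classes`, `confident`.
#' @export
improved_pseudo_labels <- function(Xs, ys, Xt, k = NULL, m = NULL,
                                   classes = NULL, min_confidence = 0) {
  Xs <- as.matrix(Xs); Xt <- as.matrix(Xt)
  ys <- as.character(ys)
  if (is.null(classes)) classes <- .default_classes(ys)
  ns <- ncol(Xs); nt <- ncol(Xt)
  pca <- pca_fit_transform(cbind(Xs, Xt), k)
  Xbar_s <- pca$Xbar[, seq_len(ns), drop = FALSE]
  Xbar_t <- pca$Xbar[, ns + seq_len(nt), drop = FALSE]

  label_pass <- function(model) {
    Zs <- slpp_project(model, Xbar_s)
    Zt <- slpp_project(model, Xbar_t)
    proto <- class_prototypes(Zs, ys, classes)
    p1 <- ncp_probabilities(Zt, proto)
    sp <- sp_probabilities(Zt, proto)
    combine_probabilities(p1, sp$p2)
  }

  P0 <- slpp_fit(Xbar_s, ys, m)
  y0 <- label_pass(P0)
  P1 <- slpp_fit(cbind(Xbar_s, Xbar_t), c(ys, y0$labels), m)
  y1 <- label_pass(P1)
  conf <- y1$p[cbind(seq_len(nt), match(y1$labels, classes))]
  list(labels = y1, initial = y0, slpp = P1, pca = pca$model,
       classes = classes, confident = conf >= min_confidence)
}
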