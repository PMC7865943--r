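#' Pooled z-score normalization of a feature matrix
#'
#' Each feature row is centered and scaled to unit standard deviation
#' over the pooled columns (source and target together, the transductive
#' convention: both are on hand when the adaptation runs).  Rows with
#' zero variance map to all zeros rather than NaN.
#'
#' @param X numeric `d x n` feature matrix (or `har_features`).
#' @param model optional stored normalization model to re-apply.
#' @return list with `X` (normalized matrix) and `model`
#'   (`feature_norm`: `center`, `scale` vectors).
#' @export
normalize_features <- function(X, model = NULL) {
  if (inherits(X, "har_features")) X <- X$X
  X <- as.matrix(X)
  if (is.null(model)) {
    if (ncol(X) < 2L) stop("need at least 2 columns to normalize",
                           call. = FALSE)
    center <- rowMeans(X)
    scale <- matrixStats::rowSds(X)
    model <- structure(list(center = center, scale = scale),
                       class = "feature_norm")
  }
  sc <- ifelse(model$scale > 0, model$scale, 1)
  Xn <- (X - model$center) / sc
  Xn[model$scale == 0, ] <- 0
  list(X = Xn, model = model)
}

#' Fit PCA and reduce a normalized feature matrix
#'
#' Components are the leading eigenvectors of the sample covariance of
#' the columns; the projected rows are ordered by decreasing explained
#' variance.  Used to take the `d`-dimensional feature vectors down to
#' `k` dimensions (default `min(128, d, n - 1)`) before the supervised
#' locality preserving projection.
#'
#' @param X numeric `d x n` matrix (columns are samples).
#' @param k retained dimensionality, `k <= min(d, n)`.
#' @return list with `model` (`pca_model`: `center`, `components`
#'   `[d x k]`, `variances`, `k`) and `Xbar` (`k x n` scores).
#' @export
pca_fit_transform <- function(X, k = NULL) {
  X <- as.matrix(X)
  d <- nrow(X); n <- ncol(X)
  if (is.null(k)) k <- min(128L, d, n - 1L)
  if (k > min(d, n)) stop("k must be <= min(d, n)", call. = FALSE)
  center <- rowMeans(X)
  Xc <- X - center
  CV <- tcrossprod(Xc) / (n - 1)
  e <- eigen(.sym(CV), symmetric = TRUE)
  W <- .fix_signs(e$vectors[, seq_len(k), drop = FALSE])
  model <- structure(list(center = center, components = W,
                          variances = pmax(e$values[seq_len(k)], 0), k = k),
                     class = "pca_model")
  list(model = model, Xbar = crossprod(W, Xc))
}

#' Apply a fitted PCA model
#' @param model a `pca_model`.
#' @param X `d x n` matrix on the original feature scale.
#' @return `k x n` score matrix.
#' @export
pca_transform <- function(model, X) {
  crossprod(model$components, as.matrix(X) - model$center)
}

#' Class-membership similarity matrix
#'
#' `S[i, j] = 1` when samples `i` and `j` carry the same label, else 0 --
#' the supervision used by the locality preserving projection to pull
#' same-class samples together regardless of their domain.
#'
#' @param labels label vector over the labeled columns.
#' @return symmetric 0/1 matrix with unit diagonal.
#' @export
build_similarity <- function(labels) {
  y <- as.character(labels)
  outer(y, y, "==") * 1
}

#' Fit a supervised locality preserving projection (SLPP)
#'
#' Learns the projection `P` that maps same-class samples close together
#' by solving the generalized eigenproblem
#' `Xl D Xl' p = lambda (Xl L Xl' + I) p`, where `S` is the 0/1
#' same-class similarity matrix, `D = diag(rowSums(S))` and `L = D - S`
#' is the graph Laplacian.  `P` collects the eigenvectors of the `m`
#' largest eigenvalues (descending).  Both sides are symmetrized and a
#' `1e-8` ridge is always added to the right-hand side for stability.
#'
#' @param Xl `k x n_l` matrix of labeled (PCA-reduced) samples.
#' @param labels their labels.
#' @param m subspace dimensionality (default `k`, so no further
#'   information is lost after PCA).
#' @return object of class `slpp_model`: `P` (`k x m`), `values`
#'   (eigenvalues used, descending), `m`.
#' @export
slpp_fit <- function(Xl, labels, m = NULL) {
  Xl <- as.matrix(Xl)
  k <- nrow(Xl)
  if (ncol(Xl) < 2L) stop("need at least 2 labeled samples", call. = FALSE)
  if (ncol(Xl) != length(labels))
    stop("labels length must match the number of columns", call. = FALSE)
  if (is.null(m)) m <- k
  if (m > k) stop("m must be <= k", call. = FALSE)
  S <- build_similarity(labels)
  Dg <- diag(rowSums(S))
  L <- Dg - S
  A <- Xl %*% Dg %*% t(Xl)
  B <- Xl %*% L %*% t(Xl) + diag(k)
  e <- .geigen(A, B, ridge_always = TRUE)
  P <- e$vectors[, seq_len(m), drop = FALSE]
  # eigenvectors are defined up to scale; unit columns keep the projected
  # metric comparable across directions (B-orthonormal scaling would
  # inflate low-scatter directions and with them the domain displacement)
  P <- sweep(P, 2L, sqrt(colSums(P^2)), "/")
  structure(list(P = P, values = e$values[seq_len(m)], m = m),
            class = "slpp_model")
}

#' Project reduced samples into the SLPP subspace
#'
#' @param model an `slpp_model`.
#' @param Xbar `k x n` matrix of PCA-reduced samples.
#' @return `m x n` matrix `P' Xbar`.
#' @export
slpp_project <- function(model, Xbar) {
  Xbar <- as.matrix(Xbar)
  if (nrow(Xbar) != nrow(model$P))
    stop("Xbar has ", nrow(Xbar), " rows but the projection expects ",
         nrow(model$P), call. = FALSE)
  crossprod(model$P, Xbar)
}
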