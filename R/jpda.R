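#' One-hot label matrix
#'
#' @param labels integer labels in `1..C`, or characters matched against
#'   `classes`.
#' @param C number of classes (or supply `classes`).
#' @param classes optional class order for character labels.
#' @return `n x C` 0/1 matrix with unit row sums.
#' @export
one_hot <- function(labels, C = NULL, classes = NULL) {
  if (!is.null(classes)) {
    labels <- .encode_labels(labels, classes)
    C <- length(classes)
  }
  labels <- as.integer(labels)
  if (is.null(C)) C <- max(labels)
  if (any(labels < 1L | labels > C))
    stop("labels must lie in 1..C", call. = FALSE)
  Y <- matrix(0, length(labels), C)
  Y[cbind(seq_along(labels), labels)] <- 1
  if (!is.null(classes)) colnames(Y) <- classes
  Y
}

#' Discriminative label expansions for the joint-probability MMD
#'
#' Builds the block matrices that enter the class-discrepancy
#' (maximization) term: block `c` of `Fs` repeats column `c` of the
#' source one-hot matrix `C - 1` times, while block `c` of `Ft` collects
#' the target one-hot columns of every class except `c` in ascending
#' class order.  Both have `C (C - 1)` columns, so each same-class source
#' block faces all different-class target columns.
#'
#' @param Ys `ns x C` source one-hot matrix.
#' @param Yt_hat `nt x C` target (pseudo-label) one-hot matrix.
#' @return list with `Fs` and `Ft`.
#' @export
build_F <- function(Ys, Yt_hat) {
  C <- ncol(Ys)
  if (ncol(Yt_hat) != C) stop("class counts differ", call. = FALSE)
  if (C < 2L)
    stop("the discriminative term needs at least 2 classes", call. = FALSE)
  Fs <- matrix(0, nrow(Ys), C * (C - 1L))
  Ft <- matrix(0, nrow(Yt_hat), C * (C - 1L))
  for (c in seq_len(C)) {
    block <- (c - 1L) * (C - 1L) + seq_len(C - 1L)
    Fs[, block] <- Ys[, rep(c, C - 1L)]
    Ft[, block] <- Yt_hat[, setdiff(seq_len(C), c)]
  }
  list(Fs = Fs, Ft = Ft)
}

#' Joint-probability coefficient matrices
#'
#' Normalizes the label matrices by their domain sizes
#' (`Ns = Ys / ns`, `Nt = Yt / nt`, and likewise `Ms`, `Mt` for the
#' discriminative expansions) and assembles the two `n x n` quadratic
#' forms of the joint-probability MMD: `Rmin` (same-class cross-domain
#' discrepancy, to be minimized) and `Rmax` (different-class
#' discrepancy, to be maximized).  Both are symmetric PSD by
#' construction, being Gram matrices of `[Ns; -Nt]` and `[Ms; -Mt]`.
#'
#' @param Ys `ns x C` source one-hot matrix.
#' @param Yt_hat `nt x C` target one-hot matrix.
#' @return list with `Rmin`, `Rmax` (`n x n`), and the factors
#'   `Ns`, `Nt`, `Ms`, `Mt`.
#' @export
build_R <- function(Ys, Yt_hat) {
  ns <- nrow(Ys); nt <- nrow(Yt_hat)
  Ns <- Ys / ns
  Nt <- Yt_hat / nt
  Fm <- build_F(Ys, Yt_hat)
  Ms <- Fm$Fs / ns
  Mt <- Fm$Ft / nt
  Un <- rbind(Ns, -Nt)
  Um <- rbind(Ms, -Mt)
  list(Rmin = tcrossprod(Un), Rmax = tcrossprod(Um),
       Ns = Ns, Nt = Nt, Ms = Ms, Mt = Mt)
}

#' One joint-probability adaptation step
#'
#' Solves the generalized eigenproblem
#' `(X (Rmin - mu Rmax) X' + lambda I) a = eta X H X' a`,
#' with `H = I - (1/n) 11'` the centering matrix, and takes the
#' eigenvectors of the `p` smallest (trailing) eigenvalues, ascending,
#' as the columns of the adaptation matrix `A`.  A classifier trained on
#' `A' Xs` then transfers to `A' Xt`.  Internally the `n x n` matrices
#' are never formed: `X Rmin X'` is computed from its low-rank factor
#' `Xs Ns - Xt Nt` (and likewise for `Rmax`), so the step scales with
#' `d`, not `n`.
#'
#' @param Xs,Xt normalized `d x ns` / `d x nt` feature matrices.
#' @param Ys,Yt_hat one-hot label matrices.
#' @param p subspace dimensionality (default `min(100, d, n - 1)`).
#' @param mu trade-off between the transfer and discriminative terms
#'   (default 0.1).
#' @param lambda ridge regularization (default 0.1).
#' @return list with `A` (`d x p`), `values` (ascending generalized
#'   eigenvalues of the returned pairs), `lhs`, `rhs` (the two `d x d`
#'   matrices actually solved, for diagnostics), and `mmd_min`,
#'   `mmd_max` (the two joint-MMD terms evaluated at `A`).
#' @export
jpda_step <- function(Xs, Xt, Ys, Yt_hat, p = NULL, mu = 0.1,
                      lambda = 0.1) {
  Xs <- as.matrix(Xs); Xt <- as.matrix(Xt)
  d <- nrow(Xs)
  if (nrow(Xt) != d) stop("feature dimensions differ", call. = FALSE)
  ns <- ncol(Xs); nt <- ncol(Xt); n <- ns + nt
  if (is.null(p)) p <- min(20L, d, n - 1L)
  if (p < 1L || p > d) stop("p must be in 1..d", call. = FALSE)
  R <- build_R(Ys, Yt_hat)
  Gmin <- Xs %*% R$Ns - Xt %*% R$Nt          # d x C
  Gmax <- Xs %*% R$Ms - Xt %*% R$Mt          # d x C(C-1)
  lhs <- tcrossprod(Gmin) - mu * tcrossprod(Gmax) + lambda * diag(d)
  X <- cbind(Xs, Xt)
  Xc <- X - rowMeans(X)
  rhs <- tcrossprod(Xc)                      # X H X' ; H idempotent
  e <- .geigen(lhs, rhs)
  # When d > n - 1 the right-hand side is rank deficient and the ridge
  # creates eigenpairs living in its null space; those directions are
  # orthogonal to the centered data (X'H a = 0, every sample projects to
  # a constant) and must not be picked.  Keep only eigenvectors with
  # non-negligible data energy a' X H X' a (the constraint wants it = 1).
  energy <- colSums(crossprod(Xc, e$vectors)^2)
  keep <- which(energy > 0.5)
  if (length(keep) < p) {
    p <- length(keep)
    if (p < 1L) stop("no usable eigen-directions", call. = FALSE)
  }
  ord <- keep[seq.int(length(keep), by = -1L, length.out = p)]
  A <- e$vectors[, ord, drop = FALSE]
  list(A = A,
       values = e$values[ord],
       lhs = lhs, rhs = .sym(rhs),
       mmd_min = sum(crossprod(A, Gmin)^2),
       mmd_max = sum(crossprod(A, Gmax)^2))
}

#' Fit IPL-JPDA: personalize a source-trained activity model to a new
#' unlabeled subject
#'
#' The full algorithm.  Iteration 1 generates improved pseudo-labels for
#' the target with [improved_pseudo_labels()] (PCA + supervised locality
#' preserving projection, nearest-class-prototype and K-means structured
#' prediction combined by an element-wise probability maximum).  Each
#' later iteration rebuilds the joint-probability MMD matrices from the
#' current pseudo-labels, solves the [jpda_step()] eigenproblem for the
#' adaptation matrix `A`, trains a k-nearest-neighbour classifier on the
#' projected source and re-labels the projected target, until `T`
#' iterations are done (a fixed point short-circuits: once the labels
#' stop changing every later iteration reproduces them).
#'
#' @param x_source,x_target feature matrices (`d x n`, columns are
#'   segments) or `har_features` objects with a shared feature layout.
#' @param y_source source labels (required if `x_source` is a bare
#'   matrix; taken from the `har_features` object otherwise).
#' @param mu trade-off parameter of the discriminative term
#'   (default 0.1).
#' @param lambda regularization parameter (default 0.1).
#' @param p adaptation subspace dimensionality
#'   (default `min(100, d, n - 1)`).
#' @param T_iter number of iterations (default 10).
#' @param k PCA dimensionality for the pseudo-label stage
#'   (default `min(128, d, n - 1)`).
#' @param m SLPP dimensionality (default `k`).
#' @param knn_k neighbours for the inner classifier (default 1).
#' @param y_target optional true target labels, used only to score each
#'   iteration for diagnostics -- never shown to the algorithm.
#' @param normalize pooled z-score normalization before everything
#'   (default TRUE; disable if the inputs are already normalized).
#' @param classes class order (default: activity codes present in the
#'   source).
#' @return object of class `ipl_jpda` with elements `labels` (final
#'   target labels), `history` (`nt x T` label matrix per iteration),
#'   `accuracy` (per-iteration % accuracy when `y_target` given),
#'   `mmd` (per-iteration transfer/discriminative joint-MMD terms),
#'   `A`, `ipl` (the pseudo-label stage result), `norm`, `config`,
#'   `classes`, `converged_at`.
#' @examples
#' cohort <- generate_cohort(n_subjects = 2, difficulty = 0.5, seed = 1,
#'                           segments_per_class = 6)
#' fs <- featurize_segments(segment_recording(cohort$recordings[[1]]))
#' ft <- featurize_segments(segment_recording(cohort$recordings[[2]]))
#' fit <- ipl_jpda(fs, x_target = ft, T_iter = 3, y_target = ft$y)
#' print(fit)
#' @export
ipl_jpda <- function(x_source, y_source = NULL, x_target, mu = 0.1,
                     lambda = 0.1, p = NULL, T_iter = 10L, k = NULL,
                     m = NULL, knn_k = 1L, y_target = NULL,
                     normalize = TRUE, classes = NULL) {
  if (inherits(x_source, "har_features")) {
    if (is.null(y_source)) y_source <- x_source$y
    x_source <- x_source$X
  }
  if (inherits(x_target, "har_features")) {
    x_target <- x_target$X
  }
  Xs <- as.matrix(x_source); Xt <- as.matrix(x_target)
  if (nrow(Xs) != nrow(Xt))
    stop("source and target must share one feature layout", call. = FALSE)
  if (is.null(y_source)) stop("y_source is required", call. = FALSE)
  ys <- as.character(y_source)
  if (is.null(classes)) classes <- .default_classes(ys)
  if (T_iter < 1L) stop("T_iter must be >= 1", call. = FALSE)
  ns <- ncol(Xs); nt <- ncol(Xt)

  norm <- NULL
  if (normalize) {
    nrm <- normalize_features(cbind(Xs, Xt))
    Xs <- nrm$X[, seq_len(ns), drop = FALSE]
    Xt <- nrm$X[, ns + seq_len(nt), drop = FALSE]
    norm <- nrm$model
  }

  ipl <- improved_pseudo_labels(Xs, ys, Xt, k = k, m = m, classes = classes)
  history <- matrix(NA_character_, nt, T_iter)
  history[, 1L] <- ipl$labels$labels
  acc <- rep(NA_real_, T_iter)
  mmd <- matrix(NA_real_, T_iter, 2,
                dimnames = list(NULL, c("transfer", "discriminative")))
  score <- function(lab) {
    if (is.null(y_target)) NA_real_
    else 100 * mean(lab == as.character(y_target))
  }
  acc[1L] <- score(history[, 1L])

  Ys1 <- one_hot(ys, classes = classes)
  A <- NULL
  step <- NULL
  converged_at <- NA_integer_
  current <- history[, 1L]
  if (T_iter >= 2L) {
    for (it in 2:T_iter) {
      if (!is.na(converged_at)) {       # fixed point: labels cannot change
        history[, it] <- current
        acc[it] <- acc[it - 1L]
        mmd[it, ] <- mmd[it - 1L, ]
        next
      }
      Yt1 <- one_hot(current, classes = classes)
      step <- jpda_step(Xs, Xt, Ys1, Yt1, p = p, mu = mu, lambda = lambda)
      A <- step$A
      Zs <- crossprod(A, Xs)
      Zt <- crossprod(A, Xt)
      pred <- knn_classify(Zs, ys, Zt, k = knn_k)
      history[, it] <- pred
      acc[it] <- score(pred)
      mmd[it, ] <- c(step$mmd_min, step$mmd_max)
      if (identical(pred, current)) converged_at <- it
      current <- pred
    }
  }

  structure(
    list(labels = current, history = history, accuracy = acc, mmd = mmd,
         A = A, ipl = ipl, norm = norm,
         source = list(X = Xs, y = ys),
         config = list(mu = mu, lambda = lambda, p = p, T_iter = T_iter,
                       k = k, m = m, knn_k = knn_k),
         classes = classes, converged_at = converged_at),
    class = "ipl_jpda")
}

#' @export
print.ipl_jpda <- function(x, ...) {
  cat("IPL-JPDA fit:", length(x$labels), "target segments,",
      length(x$classes), "classes,", x$config$T_iter, "iterations\n")
  if (!all(is.na(x$accuracy)))
    cat("  per-iteration accuracy (%):",
        paste(sprintf("%.1f", x$accuracy), collapse = " "), "\n")
  tab <- table(factor(x$labels, levels = x$classes))
  cat("  predicted:", paste(names(tab), tab, sep = ":", collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.ipl_jpda <- function(object, ...) {
  cat("IPL-JPDA: joint-probability domain adaptation",
      "with improved pseudo-labels\n")
  cfg <- object$config
  cat(sprintf("  mu = %g, lambda = %g, T = %d, knn_k = %d\n",
              cfg$mu, cfg$lambda, cfg$T_iter, cfg$knn_k))
  cat("  adaptation subspace:",
      if (is.null(object$A)) "(T = 1, pseudo-label stage only)"
      else paste0(nrow(object$A), " -> ", ncol(object$A)), "\n")
  if (!is.na(object$converged_at))
    cat("  labels converged at iteration", object$converged_at, "\n")
  if (!all(is.na(object$mmd[, 1L]))) {
    last <- max(which(!is.na(object$mmd[, 1L])))
    cat(sprintf("  final joint-MMD transfer term: %.3e\n",
                object$mmd[last, 1L]))
  }
  changed <- sum(object$history[, 1L] != object$labels)
  cat("  labels revised after the pseudo-label stage:", changed, "of",
      length(object$labels), "\n")
  invisible(object)
}

#' @export
coef.ipl_jpda <- function(object, ...) object$A

#' @export
fitted.ipl_jpda <- function(object, ...) object$labels

#' Predict activity labels for new target segments
#'
#' Applies the stored normalization and adaptation matrix, then the
#' k-nearest-neighbour rule against the projected source samples.
#'
#' @param object an `ipl_jpda` fit with `T_iter >= 2`.
#' @param newdata `d x n` feature matrix or `har_features` object on the
#'   original feature scale.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.ipl_jpda <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$labels)
  if (inherits(newdata, "har_features")) newdata <- newdata$X
  X <- as.matrix(newdata)
  if (!is.null(object$norm)) X <- normalize_features(X, object$norm)$X
  if (is.null(object$A))
    stop("fit has no adaptation matrix (T_iter = 1); refit with T >= 2",
         call. = FALSE)
  Z <- crossprod(object$A, X)
  Zs <- crossprod(object$A, object$source$X)
  knn_classify(Zs, object$source$y, Z, k = object$config$knn_k)
}

#' Plot IPL-JPDA diagnostics
#'
#' Left axis: per-iteration accuracy (when the fit was scored); right
#' axis: the joint-MMD transfer term, which the adaptation drives down.
#'
#' @param x an `ipl_jpda` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ipl_jpda <- function(x, ...) {
  T_iter <- x$config$T_iter
  it <- seq_len(T_iter)
  has_acc <- !all(is.na(x$accuracy))
  if (has_acc) {
    graphics::plot(it, x$accuracy, type = "b", pch = 16,
                   xlab = "iteration", ylab = "target accuracy (%)", ...)
  } else {
    graphics::plot(it, x$mmd[, 1L], type = "b", pch = 16,
                   xlab = "iteration", ylab = "joint-MMD transfer term",
                   ...)
    return(invisible(x))
  }
  ok <- which(!is.na(x$mmd[, 1L]))
  if (length(ok)) {
    graphics::par(new = TRUE)
    graphics::plot(it[ok], x$mmd[ok, 1L], type = "l", lty = 2, col = 2,
                   axes = FALSE, xlab = "", ylab = "",
                   xlim = range(it))
    graphics::axis(4, col.axis = 2)
    graphics::mtext("joint-MMD transfer term", side = 4, line = 2,
                    col = 2, cex = 0.8)
  }
  invisible(x)
}
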