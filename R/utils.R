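# internal numerical helpers

.sym <- function(M) (M + t(M)) / 2

# Generalized symmetric eigenproblem A v = lambda B v with B (near) PD.
# Solved by Cholesky whitening: B = U'U, C = U^-T A U^-1, eigen(C),
# v = U^-1 y.  A ridge (1e-8 scaled to the diagonal) is added to B when
# the factorization fails; `ridge_always` adds it unconditionally.
# Returns values (descending) and B-orthonormal vectors with a fixed sign
# convention (largest-magnitude entry of each vector positive).
.geigen <- function(A, B, ridge_always = FALSE, ridge = 1e-8) {
  A <- .sym(A)
  B <- .sym(B)
  if (ridge_always) B <- B + ridge * diag(nrow(B))
  U <- NULL
  for (attempt in 0:6) {
    U <- tryCatch(chol(B), error = function(e) NULL)
    if (!is.null(U)) break
    B <- B + ridge * max(1, mean(diag(B))) * diag(nrow(B))
    ridge <- ridge * 100
  }
  if (is.null(U))
    stop("right-hand matrix is numerically singular beyond repair",
         call. = FALSE)
  Ui <- backsolve(U, diag(nrow(B)))
  C <- .sym(t(Ui) %*% A %*% Ui)
  e <- eigen(C, symmetric = TRUE)
  V <- Ui %*% e$vectors
  V <- .fix_signs(V)
  list(values = e$values, vectors = V)
}

# make the largest-|entry| of every column positive (deterministic signs)
.fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# squared Euclidean cross-distance matrix between columns of A and B
.cross_dist2 <- function(A, B) {
  d2 <- outer(colSums(A^2), colSums(B^2), "+") - 2 * crossprod(A, B)
  pmax(d2, 0)
}

# row-wise softmax of exp(-dist) computed stably via min-distance shift
.softmax_neg_dist <- function(D) {
  # D: [n x C] Euclidean distances; returns [n x C] rows summing to 1
  shift <- matrixStats::rowMins(D)
  E <- exp(-(D - shift))
  E / rowSums(E)
}
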