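# joint-probability adaptation: label algebra, R matrices, eigen step,
# full driver

test_that("one-hot coding is exact", {
  expect_identical(one_hot(c(1, 2), C = 2),
                   matrix(c(1, 0, 0, 1), 2, 2))
  expect_identical(one_hot(rep(1, 4), C = 3)[, 1], rep(1, 4))
  Y <- one_hot(sample(1:5, 20, replace = TRUE), C = 5)
  expect_identical(rowSums(Y), rep(1, 20))
  expect_error(one_hot(c(1, 6), C = 5), "1..C")
  Yc <- one_hot(c("RUN", "SIT"), classes = c("SIT", "RUN"))
  expect_identical(unname(Yc), matrix(c(0, 1, 1, 0), 2, 2))
})

test_that("discriminative expansions follow the hand-expanded C = 2 case", {
  Ys <- one_hot(c(1, 2), C = 2)
  Yt <- one_hot(2, C = 2)
  Fm <- build_F(Ys, Yt)
  # block c repeats the class-c source column (C - 1 = 1 time)
  expect_identical(Fm$Fs, matrix(c(1, 0, 0, 1), 2, 2))
  # target block c holds the non-c columns ascending: class-2 col, then
  # class-1 col
  expect_identical(Fm$Ft, matrix(c(1, 0), 1, 2))
  # widths are C(C-1); for the 7 activities that is 42
  Ys7 <- one_hot(rep(1:7, 2), C = 7)
  Fm7 <- build_F(Ys7, Ys7)
  expect_identical(ncol(Fm7$Fs), 42L)
  expect_identical(ncol(Fm7$Ft), 42L)
  expect_error(build_F(matrix(1, 3, 1), matrix(1, 3, 1)), "2 classes")
  # a C = 3 row by hand: source class 2 -> block pattern 0 0 | 1 1 | 0 0
  F3 <- build_F(one_hot(2, C = 3), one_hot(3, C = 3))
  expect_identical(F3$Fs[1, ], c(0, 0, 1, 1, 0, 0))
  # target class 3: block 1 = cols (2,3) -> (0,1); block 2 = cols (1,3)
  # -> (0,1); block 3 = cols (1,2) -> (0,0)
  expect_identical(F3$Ft[1, ], c(0, 1, 0, 1, 0, 0))
})

test_that("R matrices are PSD Gram forms of the stacked factors", {
  set.seed(1)
  for (i in 1:20) {
    C <- sample(2:5, 1)
    ns <- sample(C:12, 1); nt <- sample(C:12, 1)
    Ys <- one_hot(sample(1:C, ns, replace = TRUE), C = C)
    Yt <- one_hot(sample(1:C, nt, replace = TRUE), C = C)
    R <- build_R(Ys, Yt)
    n <- ns + nt
    expect_identical(dim(R$Rmin), c(n, n))
    expect_identical(dim(R$Rmax), c(n, n))
    expect_equal(R$Rmin, t(R$Rmin), tolerance = 1e-12)
    expect_gte(min(eigen(R$Rmin, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
    expect_gte(min(eigen(R$Rmax, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
    # block identity against the definition
    expect_equal(R$Rmin[1:ns, 1:ns], tcrossprod(Ys / ns),
                 tolerance = 1e-12)
    expect_equal(R$Rmin[1:ns, ns + 1:nt], -tcrossprod(Ys / ns, Yt / nt),
                 tolerance = 1e-12)
  }
})

test_that("copied domains give a vanishing joint-MMD term", {
  set.seed(2)
  d <- 6; n <- 14; C <- 2
  Xs <- matrix(rnorm(d * n), d, n)
  y <- rep(1:2, 7)
  Ys <- one_hot(y, C = C)
  step <- jpda_step(Xs, Xs, Ys, Ys, p = 3)
  expect_lt(step$mmd_min, 1e-18)
  # also via the explicit n x n form for an arbitrary projection
  R <- build_R(Ys, Ys)
  X <- cbind(Xs, Xs)
  A <- matrix(rnorm(d * 3), d, 3)
  expect_lt(sum(diag(t(A) %*% X %*% R$Rmin %*% t(X) %*% A)), 1e-12)
  # mu = 0, identical domains: optimum objective is the lambda ridge only
  step0 <- jpda_step(Xs, Xs, Ys, Ys, p = 3, mu = 0)
  expect_lt(step0$mmd_min, 1e-18)
})

test_that("jpda_step matches a dense generalized-eigensolve oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    d <- 6; ns <- 10; nt <- 10; C <- 2
    Xs <- matrix(rnorm(d * ns), d, ns)
    Xt <- matrix(rnorm(d * nt), d, nt) + 0.5
    Ys <- one_hot(rep(1:2, 5), C = C)
    Yt <- one_hot(sample(1:2, nt, replace = TRUE), C = C)
    p <- 3
    step <- jpda_step(Xs, Xt, Ys, Yt, p = p, mu = 0.1, lambda = 0.1)
    # oracle: explicitly assemble every matrix of the eigenproblem from
    # the n x n forms and solve the product form densely
    R <- build_R(Ys, Yt)
    X <- cbind(Xs, Xt); n <- ns + nt
    H <- diag(n) - matrix(1 / n, n, n)
    lhs <- X %*% (R$Rmin - 0.1 * R$Rmax) %*% t(X) + 0.1 * diag(d)
    rhs <- X %*% H %*% t(X)
    expect_equal(step$lhs, (lhs + t(lhs)) / 2, tolerance = 1e-9)
    expect_equal(step$rhs, (rhs + t(rhs)) / 2, tolerance = 1e-9)
    eg <- eigen(solve(rhs) %*% lhs)
    ord <- order(Re(eg$values))[1:p]
    expect_equal(step$values, Re(eg$values)[ord], tolerance = 1e-6)
    for (j in 1:p) {
      w <- Re(eg$vectors[, ord[j]]); w <- w / sqrt(sum(w^2))
      v <- step$A[, j]; v <- v / sqrt(sum(v^2))
      if (sum(w * v) < 0) w <- -w
      expect_equal(v, w, tolerance = 1e-8)
    }
  }
})

test_that("every returned eigenpair satisfies the eigen equation", {
  set.seed(11)
  d <- 8; ns <- 15; nt <- 12
  Xs <- matrix(rnorm(d * ns), d, ns)
  Xt <- matrix(rnorm(d * nt), d, nt) + 1
  Ys <- one_hot(sample(1:3, ns, replace = TRUE), C = 3)
  Yt <- one_hot(sample(1:3, nt, replace = TRUE), C = 3)
  step <- jpda_step(Xs, Xt, Ys, Yt, p = 4)
  for (j in seq_len(ncol(step$A))) {
    a <- step$A[, j]
    resid <- step$lhs %*% a - step$values[j] * (step$rhs %*% a)
    expect_lt(sqrt(sum(resid^2)) / sqrt(sum(a^2)), 1e-6)
  }
  expect_identical(ncol(step$A), 4L)
  expect_true(all(is.finite(step$A)))
})

test_that("the driver reaches a fixed point on copied domains", {
  co <- small_cohort(n_subjects = 2, difficulty = 0,
                     segments_per_class = 8)
  fs <- co$features[[1]]
  fit <- ipl_jpda(fs, x_target = fs, T_iter = 5, y_target = fs$y)
  expect_equal(unname(fit$accuracy), rep(100, 5))
  expect_identical(fit$labels, fs$y)
  expect_identical(ncol(fit$history), 5L)
  # labels constant after convergence
  expect_false(is.na(fit$converged_at))
  for (it in seq(fit$converged_at, 5))
    expect_identical(fit$history[, it], fit$labels)
})

test_that("the pipeline is invariant to permuting source columns", {
  co <- small_cohort(n_subjects = 2, difficulty = 1,
                     segments_per_class = 8)
  fs <- co$features[[1]]; ft <- co$features[[2]]
  set.seed(3)
  perm <- sample(ncol(fs$X))
  fit1 <- ipl_jpda(fs$X, fs$y, ft$X, T_iter = 3)
  fit2 <- ipl_jpda(fs$X[, perm], fs$y[perm], ft$X, T_iter = 3)
  expect_identical(fit1$labels, fit2$labels)
})

test_that("S3 surface behaves: print, summary, coef, predict, plot", {
  co <- small_cohort(n_subjects = 2, difficulty = 0.5,
                     segments_per_class = 8)
  fs <- co$features[[1]]; ft <- co$features[[2]]
  fit <- ipl_jpda(fs, x_target = ft, T_iter = 3, y_target = ft$y)
  expect_output(print(fit), "IPL-JPDA fit")
  expect_output(summary(fit), "adaptation subspace")
  expect_identical(dim(coef(fit)), c(184L, 20L))
  expect_identical(fitted(fit), fit$labels)
  # predict on the training target reproduces the final labels
  expect_identical(predict(fit, ft), fit$labels)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  # T = 1 returns the pseudo-label stage result directly
  fit1 <- ipl_jpda(fs, x_target = ft, T_iter = 1)
  expect_null(fit1$A)
  expect_identical(fit1$labels, fit1$history[, 1])
})
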