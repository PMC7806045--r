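test_that("shrinkage LDA separates Gaussian classes and matches the
           closed-form discriminant", {
  set.seed(10)
  # 1-D: sign of w points from the non-target to the target mean
  x <- matrix(c(rnorm(50, 1, 0.5), rnorm(50, -1, 0.5)), ncol = 1)
  y <- rep(c(TRUE, FALSE), each = 50)
  m <- fit_lda(x, y)
  expect_gt(m$w[1], 0)
  expect_gt(mean(predict(m, x[y, , drop = FALSE])), 0)
  expect_lt(mean(predict(m, x[!y, , drop = FALSE])), 0)

  # identical class means: near-zero weights, chance-level AUC
  x0 <- matrix(rnorm(400), ncol = 2)
  y0 <- rep(c(TRUE, FALSE), 100)
  m0 <- fit_lda(x0, y0)
  sc <- predict(m0, x0)
  expect_lt(abs(auc(sc, y0) - 0.5), 0.15)

  # 2-D with known covariance: w parallel to solve(Sigma, delta-mu)
  n <- 10000
  Sigma <- matrix(c(2, 1.2, 1.2, 1.5), 2)
  L <- chol(Sigma)
  mu <- c(1, -0.5)
  X <- rbind(matrix(rnorm(2 * n), ncol = 2) %*% L +
               matrix(mu, n, 2, byrow = TRUE),
             matrix(rnorm(2 * n), ncol = 2) %*% L)
  yy <- rep(c(TRUE, FALSE), each = n)
  mm <- fit_lda(X, yy)
  w_true <- solve(Sigma, mu)
  cosang <- sum(mm$w * w_true) / sqrt(sum(mm$w^2) * sum(w_true^2))
  expect_gt(cosang, cos(5 * pi / 180))

  expect_error(fit_lda(x0[1:3, ], c(TRUE, FALSE, FALSE)), "two members")
})

test_that("LDA-based AUC is invariant under joint affine transforms", {
  set.seed(11)
  n <- 200
  X <- rbind(matrix(rnorm(5 * n, 0.4), ncol = 5),
             matrix(rnorm(5 * n, 0), ncol = 5))
  y <- rep(c(TRUE, FALSE), each = n)
  Xtest <- rbind(matrix(rnorm(5 * n, 0.4), ncol = 5),
                 matrix(rnorm(5 * n, 0), ncol = 5))
  A <- random_invertible(5)
  b <- rnorm(5)
  tf <- function(M) M %*% t(A) + matrix(b, nrow(M), 5, byrow = TRUE)
  pooled_cov <- function(M) {
    Mc <- M
    Mc[y, ] <- sweep(M[y, , drop = FALSE], 2, colMeans(M[y, , drop = FALSE]))
    Mc[!y, ] <- sweep(M[!y, , drop = FALSE], 2,
                      colMeans(M[!y, , drop = FALSE]))
    crossprod(Mc) / nrow(M)
  }
  # exact equivariance of the unshrunk discriminant
  base <- auc(predict(fit_lda(X, y, Clda = pooled_cov(X)), Xtest), y)
  trans <- auc(predict(fit_lda(tf(X), y, Clda = pooled_cov(tf(X))),
                       tf(Xtest)), y)
  expect_equal(trans, base, tolerance = 1e-10)
  # the shrunk discriminant deviates only mildly at this sample size
  base_s <- auc(predict(fit_lda(X, y), Xtest), y)
  trans_s <- auc(predict(fit_lda(tf(X), y), tf(Xtest)), y)
  expect_lt(abs(trans_s - base_s), 0.1)
})

test_that("MTS weights solve the estimated-MSE program exactly", {
  set.seed(12)
  # grid-search oracle over the constrained simplex, N_sub <= 3
  for (rep_i in 1:10) {
    n_sub <- sample(2:3, 1)
    X <- NULL; y <- NULL; j <- NULL
    for (s in seq_len(n_sub)) {
      ns <- sample(8:20, 1)
      X <- rbind(X, matrix(rnorm(2 * ns * 4, mean = rnorm(1)), ncol = 4))
      y <- c(y, rep(c(TRUE, FALSE), each = ns))
      j <- c(j, rep(as.character(s), 2 * ns))
    }
    wts <- mts_weights(X, y, j, "1", "t")
    m <- length(wts$others)
    grid1 <- seq(0, 1, by = 0.02)
    if (m == 1) {
      grid_obj <- min(vapply(grid1, function(a)
        mts_objective(wts, a), numeric(1)))
    } else {
      grid_obj <- Inf
      for (a1 in grid1) for (a2 in grid1) {
        if (a1 + a2 <= 1)
          grid_obj <- min(grid_obj, mts_objective(wts, c(a1, a2)))
      }
    }
    expect_lte(mts_objective(wts, wts$alpha), grid_obj + 1e-6)
    expect_true(all(wts$alpha >= 0))
    expect_lte(sum(wts$alpha), 1 + 1e-12)
  }
})

test_that("MTS agrees with an interior-point QP solver", {
  library(kernlab)
  set.seed(13)
  for (rep_i in 1:10) {
    X <- NULL; y <- NULL; j <- NULL
    for (s in 1:4) {
      X <- rbind(X, matrix(rnorm(2 * 12 * 6, mean = rnorm(1, sd = 0.5)),
                           ncol = 6))
      y <- c(y, rep(c(TRUE, FALSE), each = 12))
      j <- c(j, rep(as.character(s), 24))
    }
    wts <- mts_weights(X, y, j, "2", "nt")
    m <- length(wts$others)
    H <- 2 * (wts$V_own * matrix(1, m, m) + diag(wts$V, m) + wts$B)
    c0 <- rep(-2 * wts$V_own, m)
    sol <- kernlab::ipop(c0, H, matrix(1, 1, m), 0, rep(0, m), rep(1, m),
                         1, sigf = 9, maxiter = 100)
    expect_lte(mts_objective(wts, wts$alpha),
               mts_objective(wts, pmax(kernlab::primal(sol), 0)) + 1e-6)
  }
})

test_that("MTS weights vanish for a distant subclass and never hurt the
           estimated risk for i.i.d. subclasses", {
  set.seed(14)
  # one distant subclass gets negligible weight
  X <- rbind(matrix(rnorm(40 * 4), ncol = 4),
             matrix(rnorm(40 * 4), ncol = 4),
             matrix(rnorm(40 * 4, mean = 500), ncol = 4))
  y <- rep(rep(c(TRUE, FALSE), each = 20), 3)
  j <- rep(c("a", "b", "far"), each = 40)
  wts <- mts_weights(X, y, j, "a", "t")
  expect_lt(wts$alpha[["far"]], 1e-4)
  expect_gt(wts$alpha[["b"]], 0.05)

  # i.i.d. subclasses: optimized objective never above the alpha = 0 value
  for (seed in 1:50) {
    set.seed(100 + seed)
    X <- matrix(rnorm(3 * 30 * 5), ncol = 5)
    y <- rep(rep(c(TRUE, FALSE), each = 15), 3)
    j <- rep(c("a", "b", "c"), each = 30)
    wts <- mts_weights(X, y, j, "b", "t")
    expect_lte(mts_objective(wts, wts$alpha),
               mts_objective(wts, rep(0, 2)) + 1e-12)
  }
})

test_that("shrunk means are exact convex combinations", {
  set.seed(15)
  X <- matrix(rnorm(60 * 3), ncol = 3)
  y <- rep(rep(c(TRUE, FALSE), each = 10), 3)
  j <- rep(c("a", "b", "c"), each = 20)
  mu_a <- colMeans(X[y & j == "a", ])
  # alpha = 0 leaves the subclass mean untouched
  expect_equal(mts_shrunk_mean(X, y, j, "a", "t", c(0, 0)), mu_a)
  # single subclass: empty alpha
  w1 <- mts_weights(X[j == "a", ], y[j == "a"], j[j == "a"], "a", "t")
  expect_length(w1$alpha, 0)
  # two subclasses at alpha = 0.5: midpoint
  mu_b <- colMeans(X[y & j == "b", ])
  got <- mts_shrunk_mean(X[j != "c", ], y[j != "c"], j[j != "c"],
                         "a", "t", c(b = 0.5))
  expect_equal(got, (mu_a + mu_b) / 2)
  # equal subclass means are a fixed point for any valid alpha
  Xeq <- rbind(X[j == "a", ], X[j == "a", ])
  jeq <- rep(c("a", "b"), each = 20)
  yeq <- rep(rep(c(TRUE, FALSE), each = 10), 2)
  expect_equal(mts_shrunk_mean(Xeq, yeq, jeq, "a", "t", c(b = 0.7)), mu_a)
  expect_error(mts_shrunk_mean(X, y, j, "a", "t", c(0.8, 0.5)), "sum")
})
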