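## xDAWN spatial filtering, prototype augmentation (the block-structured
## surrogate-channel representation), and Ledoit-Wolf shrunk window
## covariances.

#' Fit xDAWN spatial filters for target and non-target responses
#'
#' Per class, the evoked response is estimated by least squares under a
#' stimulus-onset (Toeplitz) design that models the overlap of responses to
#' neighbouring stimuli -- at 250 ms SOA each 1 s window contains several
#' responses, so unmodelled overlap would bias the estimate. The spatial
#' filters then solve the generalized eigenproblem maximizing the power of
#' the estimated evoked component against the total signal covariance; the
#' leading `n_components_per_class` eigenvectors are kept as filter rows.
#'
#' @param ep training [epoch_set()]; rejected windows are excluded. The
#'   epoch schedule supplies onsets and classes of neighbouring stimuli.
#' @param n_components_per_class number of filters per class (default 2).
#' @return Object of class `"xdawn_model"`: `Wt`, `Wnt`
#'   (`n_components_per_class` x channels, unit-norm rows) and the
#'   generalized eigenvalue spectra `evals_t`, `evals_nt`.
#' @references Rivet, B. et al. (2009). xDAWN algorithm to enhance evoked
#'   potentials. IEEE Trans. Biomed. Eng. 56(8).
#' @export
fit_xdawn <- function(ep, n_components_per_class = 2L) {
  stopifnot(inherits(ep, "epoch_set"))
  ep <- retained(ep)
  sched <- ep$schedule
  y <- sched$is_target
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("need at least 2 windows per class to fit xDAWN")
  nc <- dim(ep$windows)[2]
  nt <- dim(ep$windows)[3]
  if (n_components_per_class > nc)
    stop("n_components_per_class must not exceed the channel count")
  K <- dim(ep$windows)[1]
  rate <- ep$rate

  ## Sparse design: column block 1 = target evoked (nt lags), block 2 =
  ## non-target. A stimulus at onset o_j contributes to window k whenever
  ## the 1 s response model overlaps the window.
  onset_smp <- round(sched$onset_s * rate)
  ri <- vector("list", K); ci <- vector("list", K)
  for (k in seq_len(K)) {
    d <- onset_smp - onset_smp[k]              # lag of stimulus j vs window k
    nb <- which(d > -nt & d < nt)
    rows <- integer(0); cols <- integer(0)
    for (j in nb) {
      t1 <- max(1L, 1L + d[j]); t2 <- min(nt, nt + d[j])
      tt <- t1:t2
      rows <- c(rows, (k - 1L) * nt + tt)
      cols <- c(cols, (if (y[j]) 0L else nt) + (tt - d[j]))
    }
    ri[[k]] <- rows; ci[[k]] <- cols
  }
  D <- Matrix::sparseMatrix(i = unlist(ri), j = unlist(ci), x = 1,
                            dims = c(K * nt, 2L * nt))
  Y <- matrix(aperm(ep$windows, c(3, 1, 2)), nrow = K * nt, ncol = nc)

  DtD <- as.matrix(Matrix::crossprod(D))
  DtY <- as.matrix(Matrix::crossprod(D, Y))
  ridge <- 1e-8 * mean(diag(DtD))
  A <- solve(DtD + diag(ridge, 2L * nt), DtY)   # stacked evoked estimates

  N <- K * nt
  Cx <- crossprod(Y) / N
  R <- tryCatch(chol(Cx), error = function(e)
    stop("total covariance is rank-deficient; apply shrinkage or reduce ",
         "the channel count"))

  one_class <- function(block) {
    Ai <- A[block, , drop = FALSE]
    Ce <- t(Ai) %*% (DtD[block, block] %*% Ai) / N
    Ce <- (Ce + t(Ce)) / 2
    M <- backsolve(R, t(backsolve(R, t(Ce), transpose = TRUE)),
                   transpose = TRUE)
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    W <- backsolve(R, e$vectors[, seq_len(n_components_per_class),
                                drop = FALSE])
    W <- apply(W, 2L, function(w) w / sqrt(sum(w^2)))
    list(W = t(W), evals = e$values)
  }
  ct <- one_class(seq_len(nt))
  cn <- one_class(nt + seq_len(nt))
  structure(list(Wt = ct$W, Wnt = cn$W, evals_t = ct$evals,
                 evals_nt = cn$evals, n_channels = nc),
            class = "xdawn_model")
}

#' Augment a window with filtered class prototypes
#'
#' Stacks the xDAWN-filtered class prototypes on top of the xDAWN-filtered
#' window, giving the 8-surrogate-channel representation whose covariance
#' carries both spatial structure and signal-prototype cross-covariance
#' (temporal/phase) information:
#' rows are `Wt %*% target_mean`, `Wnt %*% nontarget_mean`, `Wt %*% Xk`,
#' `Wnt %*% Xk`. The first four rows are constant across windows.
#'
#' @param Xk channels x times window matrix.
#' @param proto a `"prototype_pair"` from [compute_prototypes()].
#' @param xd an `"xdawn_model"` from [fit_xdawn()].
#' @return The augmented window matrix (2 * 2 * n_components x times).
#' @export
augment_window <- function(Xk, proto, xd) {
  stopifnot(inherits(proto, "prototype_pair"), inherits(xd, "xdawn_model"))
  if (nrow(Xk) != xd$n_channels || ncol(Xk) != ncol(proto$target_mean))
    stop("window shape does not match the fitted prototypes/filters")
  rbind(xd$Wt %*% proto$target_mean,
        xd$Wnt %*% proto$nontarget_mean,
        xd$Wt %*% Xk,
        xd$Wnt %*% Xk)
}

#' Ledoit-Wolf analytic shrinkage toward scaled identity
#'
#' Closed-form convex shrinkage of the sample covariance toward
#' \eqn{\mu I} with \eqn{\mu = tr(S)/p}; the intensity minimizes the
#' expected Frobenius risk and lies in `[0, 1]`, guaranteeing a positive
#' definite result whenever the data are not identically zero.
#'
#' @param X n x p matrix, rows are observations.
#' @param center subtract column means first (default TRUE).
#' @return List with `sigma` (shrunk covariance), `shrinkage` (intensity)
#'   and `mu` (target scale).
#' @references Ledoit, O. and Wolf, M. (2004). A well-conditioned estimator
#'   for large-dimensional covariance matrices. J. Multivar. Anal. 88.
#' @export
ledoit_wolf <- function(X, center = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least two observations")
  if (center) X <- sweep(X, 2L, colMeans(X))
  S <- crossprod(X) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 < .Machine$double.eps) {
    shrink <- 0
  } else {
    ## sum_k ||x_k x_k' - S||_F^2 = sum_k ||x_k||^4 - n ||S||_F^2
    b2bar <- (sum(rowSums(X^2)^2) - n * sum(S^2)) / (n^2 * p)
    shrink <- min(b2bar, d2) / d2
  }
  sigma <- shrink * diag(mu, p) + (1 - shrink) * S
  list(sigma = (sigma + t(sigma)) / 2, shrinkage = shrink, mu = mu)
}

#' Shrunk covariance of an augmented window
#'
#' Sample covariance over time of the surrogate-channel rows with
#' Ledoit-Wolf shrinkage, so the result is SPD even though the four
#' prototype rows make the raw covariance rank-deficient in the noise-free
#' limit.
#'
#' @param Xa augmented window (surrogate channels x times), from
#'   [augment_window()].
#' @return SPD covariance matrix with attribute `"shrinkage"`.
#' @export
shrinkage_covariance <- function(Xa) {
  lw <- ledoit_wolf(t(Xa), center = TRUE)
  structure(lw$sigma, shrinkage = lw$shrinkage)
}
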