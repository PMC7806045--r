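## Multi-target shrinkage (MTS) of per-subclass class means: the class mean
## of subclass j is replaced by a convex combination with the corresponding
## class means of the other subclasses, with weights chosen to minimize an
## estimate of the mean squared error of the combined mean.

## Exact minimizer of 1/2 b'Hb + c'b subject to b >= 0, sum(b) <= 1 for a
## positive definite H, by enumerating the stationary point of every face of
## the feasible polytope and keeping the feasible minimum. The dimension is
## the number of other subclasses (<= 7 here), so 2^m * 2 tiny solves are
## exact and cheap; an iterative QP solver would only add approximation
## error.
.qp_simplex <- function(H, c0) {
  m <- length(c0)
  obj <- function(b) 0.5 * sum(b * (H %*% b)) + sum(c0 * b)
  best <- rep(0, m); fbest <- 0   # b = 0 is always feasible, objective 0
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  for (s in seq_len(nrow(subsets))) {
    f <- as.logical(subsets[s, ])
    if (!any(f)) next
    Hf <- H[f, f, drop = FALSE]; cf <- c0[f]
    ## face with the sum constraint inactive
    bf <- tryCatch(solve(Hf, -cf), error = function(e) NULL)
    if (!is.null(bf) && all(bf >= -1e-12) && sum(bf) <= 1 + 1e-12) {
      b <- rep(0, m); b[f] <- pmax(bf, 0)
      if (sum(b) > 1) b <- b / sum(b)
      if (obj(b) < fbest - 1e-15) { best <- b; fbest <- obj(b) }
    }
    ## face with the sum constraint active
    k <- sum(f)
    KKT <- rbind(cbind(Hf, rep(1, k)), c(rep(1, k), 0))
    sol <- tryCatch(solve(KKT, c(-cf, 1)), error = function(e) NULL)
    if (!is.null(sol)) {
      bf <- sol[seq_len(k)]
      if (all(bf >= -1e-12)) {
        b <- rep(0, m); b[f] <- pmax(bf, 0)
        b <- b / max(sum(b), 1)
        if (obj(b) < fbest - 1e-15) { best <- b; fbest <- obj(b) }
      }
    }
  }
  list(alpha = best, objective = fbest)
}

#' Multi-target shrinkage weights for one subclass and class
#'
#' Estimates, for subclass `j` and class `i`, how strongly the class mean
#' should be shrunk toward each other subclass's mean. The quadratic
#' objective is the estimated MSE of the combined mean: the variance of the
#' own mean (weight `1 - sum(alpha)`), the variances of the other means
#' (weights `alpha`), and a bias term built from debiased squared
#' distances/inner products between subclass means
#' (\eqn{\|\hat\mu_{j'} - \hat\mu_j\|^2 - \hat V_j - \hat V_{j'}}, floored
#' at zero on the diagonal; the bias matrix is projected to the PSD cone so
#' the program stays convex). Constraints: `alpha >= 0`,
#' `sum(alpha) <= 1`. Solved exactly by face enumeration (the dimension is
#' the number of other subclasses).
#'
#' Mean variances are estimated as the summed per-dimension sample
#' variances divided by the cell count.
#'
#' @param X n x p matrix of tangent vectors.
#' @param y logical target labels per row.
#' @param j_lab character subclass label per row.
#' @param j subclass whose classifier is being regularized.
#' @param i class, `"t"` or `"nt"`.
#' @return List of class `"mts_weights"`: `alpha` (named by the other
#'   subclasses), `objective` (achieved estimated MSE), and the `V`
#'   (variances), `B` (bias matrix) and `others` used, so the objective can
#'   be re-evaluated externally.
#' @export
mts_weights <- function(X, y, j_lab, j, i = c("t", "nt")) {
  i <- match.arg(i)
  X <- as.matrix(X)
  sel_class <- if (i == "t") as.logical(y) else !as.logical(y)
  labs <- sort(unique(j_lab))
  others <- setdiff(labs, j)
  m <- length(others)
  cell <- function(jj) X[sel_class & j_lab == jj, , drop = FALSE]
  own <- cell(j)
  if (nrow(own) < 2L)
    stop("subclass ", j, " has fewer than 2 windows of class ", i)
  if (m == 0L)
    return(structure(list(alpha = numeric(0), objective = NA_real_,
                          V = numeric(0), B = matrix(0, 0, 0),
                          others = character(0), V_own = NA_real_),
                     class = "mts_weights"))
  mu_j <- colMeans(own)
  Vhat <- function(M) sum(apply(M, 2L, var)) / nrow(M)
  V_j <- Vhat(own)
  mu_o <- matrix(NA_real_, m, ncol(X))
  V_o <- numeric(m)
  for (u in seq_len(m)) {
    Mo <- cell(others[u])
    if (nrow(Mo) < 2L)
      stop("subclass ", others[u], " has fewer than 2 windows of class ", i)
    mu_o[u, ] <- colMeans(Mo)
    V_o[u] <- Vhat(Mo)
  }
  delta <- sweep(mu_o, 2L, mu_j)              # rows: mu_j' - mu_j
  B <- delta %*% t(delta)
  ## debias: the shared mu_j inflates every entry by V_j; squared norms on
  ## the diagonal additionally carry the other mean's own variance
  B <- B - V_j
  diag(B) <- pmax(diag(B) - V_o, 0)
  eB <- eigen((B + t(B)) / 2, symmetric = TRUE)
  B <- eB$vectors %*% (pmax(eB$values, 0) * t(eB$vectors))
  H <- 2 * (V_j * matrix(1, m, m) + diag(V_o, m) + B)
  c0 <- rep(-2 * V_j, m)
  sol <- tryCatch(.qp_simplex((H + t(H)) / 2, c0), error = function(e) {
    warning("MTS weight solve failed (", conditionMessage(e),
            "); falling back to the pure subclass mean")
    list(alpha = rep(0, m), objective = 0)
  })
  alpha <- sol$alpha
  names(alpha) <- others
  structure(list(alpha = alpha, objective = V_j + sol$objective,
                 V = V_o, B = B, others = others, V_own = V_j),
            class = "mts_weights")
}

#' Evaluate the estimated-MSE objective of MTS weights
#'
#' Utility to score any feasible weight vector against the same objective
#' that [mts_weights()] minimizes; used e.g. for grid-search verification.
#'
#' @param wts an `"mts_weights"` object.
#' @param alpha weight vector over the other subclasses.
#' @return The estimated MSE at `alpha`.
#' @export
mts_objective <- function(wts, alpha) {
  stopifnot(inherits(wts, "mts_weights"), length(alpha) == length(wts$others))
  (1 - sum(alpha))^2 * wts$V_own + sum(alpha^2 * wts$V) +
    as.numeric(alpha %*% wts$B %*% alpha)
}

#' Convexly combined (shrunk) subclass class mean
#'
#' The exact convex combination
#' \eqn{(1 - \sum \alpha_{j'}) \hat\mu_{i,j} + \sum \alpha_{j'}
#' \hat\mu_{i,j'}}; the result lies in the convex hull of the subclass
#' means.
#'
#' @inheritParams mts_weights
#' @param alpha weights over the other subclasses (named, or ordered as
#'   `sort(setdiff(unique(j_lab), j))`), e.g. from [mts_weights()].
#' @return The combined mean vector.
#' @export
mts_shrunk_mean <- function(X, y, j_lab, j, i = c("t", "nt"), alpha) {
  i <- match.arg(i)
  if (inherits(alpha, "mts_weights")) alpha <- alpha$alpha
  if (any(alpha < -1e-12) || sum(alpha) > 1 + 1e-12)
    stop("alpha must be nonnegative with sum <= 1")
  X <- as.matrix(X)
  sel_class <- if (i == "t") as.logical(y) else !as.logical(y)
  others <- sort(setdiff(unique(j_lab), j))
  if (length(alpha) != length(others))
    stop("alpha must have one weight per other subclass")
  if (!is.null(names(alpha))) alpha <- alpha[others]
  mu <- (1 - sum(alpha)) * colMeans(X[sel_class & j_lab == j, , drop = FALSE])
  for (u in seq_along(others))
    if (alpha[u] != 0)
      mu <- mu + alpha[u] *
        colMeans(X[sel_class & j_lab == others[u], , drop = FALSE])
  mu
}
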