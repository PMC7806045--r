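## Shrinkage LDA on tangent-space feature vectors.

#' Fit a binary LDA with analytically shrunk within-class covariance
#'
#' Class means and the pooled within-class covariance (Ledoit-Wolf shrunk)
#' give the weight vector as the solution of
#' \eqn{C_{LDA} w = \mu_t - \mu_{nt}}; scores are \eqn{w^T x + b} with the
#' offset placed halfway between the class means (equal priors), so higher
#' scores mean more target-like.
#'
#' @param X n x p feature matrix (rows are windows).
#' @param y logical vector, `TRUE` for target windows.
#' @param mu_t,mu_nt optional replacement class means (used by the
#'   multi-target-shrinkage pipeline); defaults are the sample class means.
#' @param Clda optional replacement within-class covariance.
#' @return Object of class `"lda_model"` with `w`, `b`, `mu_t`, `mu_nt`,
#'   `C_lda` and the applied `shrinkage`.
#' @export
fit_lda <- function(X, y, mu_t = NULL, mu_nt = NULL, Clda = NULL) {
  X <- as.matrix(X)
  y <- as.logical(y)
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("each class needs at least two members to fit an LDA")
  m_t <- colMeans(X[y, , drop = FALSE])
  m_nt <- colMeans(X[!y, , drop = FALSE])
  shrink <- NA_real_
  if (is.null(Clda)) {
    Xc <- X
    Xc[y, ] <- sweep(X[y, , drop = FALSE], 2L, m_t)
    Xc[!y, ] <- sweep(X[!y, , drop = FALSE], 2L, m_nt)
    lw <- ledoit_wolf(Xc, center = FALSE)
    Clda <- lw$sigma
    shrink <- lw$shrinkage
  }
  if (is.null(mu_t)) mu_t <- m_t
  if (is.null(mu_nt)) mu_nt <- m_nt
  w <- solve(Clda, mu_t - mu_nt)
  b <- -sum(w * (mu_t + mu_nt)) / 2
  structure(list(w = w, b = b, mu_t = mu_t, mu_nt = mu_nt, C_lda = Clda,
                 shrinkage = shrink),
            class = "lda_model")
}

#' Decision values of a fitted LDA
#'
#' @param object an `"lda_model"`.
#' @param newdata n x p matrix of feature vectors.
#' @param ... ignored.
#' @return Numeric vector of decision values (higher = more target-like).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$w + object$b)
}
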