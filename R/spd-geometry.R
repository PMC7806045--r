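## Core operations on the cone of symmetric positive-definite (SPD) matrices
## under the affine-invariant Riemannian metric (AIRM). All matrix functions
## go through the symmetric eigendecomposition; eigenvalues below
## 1e-12 * max(eigenvalue) raise an error rather than being clipped, since
## shrinkage upstream guarantees strictly positive spectra and degeneracy
## here signals a pipeline bug.

.sym_check <- function(C, tol = 1e-8, what = "matrix") {
  if (!is.matrix(C) || nrow(C) != ncol(C) || !is.numeric(C))
    stop(what, " must be a square numeric matrix")
  scale <- max(abs(C), 1e-300)
  asym <- max(abs(C - t(C))) / scale
  if (asym > tol)
    stop(what, " is not symmetric (relative asymmetry ", format(asym), ")")
  (C + t(C)) / 2
}

.spd_eigen <- function(C, what = "matrix") {
  C <- .sym_check(C, what = what)
  e <- eigen(C, symmetric = TRUE)
  lmin <- min(e$values)
  if (lmin <= 1e-12 * max(e$values))
    stop(what, " is not positive definite (smallest eigenvalue ",
         format(lmin), ")")
  e
}

## f applied to the spectrum: Q f(L) Q'
.spd_fun <- function(e, f) {
  Q <- e$vectors
  S <- Q %*% (f(e$values) * t(Q))
  (S + t(S)) / 2
}

#' Matrix square root and inverse square root of an SPD matrix
#'
#' Both are computed from one symmetric eigendecomposition by applying the
#' scalar operation to the eigenvalues.
#'
#' @param C symmetric positive-definite matrix.
#' @return A list with components `sqrt` (\eqn{C^{1/2}}) and
#'   `invsqrt` (\eqn{C^{-1/2}}), both SPD.
#' @examples
#' s <- spd_sqrt_invsqrt(diag(c(4, 9)))
#' s$sqrt          # diag(2, 3)
#' @export
spd_sqrt_invsqrt <- function(C) {
  e <- .spd_eigen(C, what = "C")
  list(sqrt = .spd_fun(e, sqrt), invsqrt = .spd_fun(e, function(l) 1 / sqrt(l)))
}

.spd_logm <- function(C, what = "C") .spd_fun(.spd_eigen(C, what), log)

.sym_expm <- function(S) {
  e <- eigen(.sym_check(S, what = "S"), symmetric = TRUE)
  .spd_fun(e, exp)
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' \eqn{d(C_1, C_2) = \|\mathrm{logm}(C_1^{-1/2} C_2 C_1^{-1/2})\|_F}, the
#' geodesic distance on the SPD manifold. It is invariant under congruence
#' transforms \eqn{C \mapsto A C A^T} for any invertible \eqn{A}.
#'
#' @param C1,C2 SPD matrices of equal side.
#' @return Nonnegative scalar distance.
#' @export
airm_distance <- function(C1, C2) {
  if (!all(dim(C1) == dim(C2)))
    stop("C1 and C2 must have the same dimensions")
  isq <- spd_sqrt_invsqrt(C1)$invsqrt
  M <- isq %*% C2 %*% isq
  L <- .spd_logm((M + t(M)) / 2, what = "C1^{-1/2} C2 C1^{-1/2}")
  sqrt(sum(L^2))
}

#' Logarithmic map to the tangent space at a reference SPD matrix
#'
#' Maps `C` to \eqn{S = \mathrm{logm}(C_{ref}^{-1/2}\, C\, C_{ref}^{-1/2})},
#' the tangent-space representation used for linear classification.
#'
#' @param C SPD matrix to map.
#' @param Cref SPD reference point (e.g. a Frechet mean).
#' @return Object of class `"tangent_vector"`: a list with `matrix_form`
#'   (symmetric matrix) and `vector_form` (length n(n+1)/2, see
#'   [tangent_vectorize()]).
#' @seealso [exp_map()] for the inverse operation.
#' @export
log_map <- function(C, Cref) {
  if (!all(dim(C) == dim(Cref)))
    stop("C and Cref must have the same dimensions")
  isq <- spd_sqrt_invsqrt(Cref)$invsqrt
  M <- isq %*% C %*% isq
  S <- .spd_logm((M + t(M)) / 2, what = "whitened C")
  structure(list(matrix_form = S, vector_form = tangent_vectorize(S)),
            class = "tangent_vector")
}

#' Exponential map from a tangent space back to the SPD manifold
#'
#' Inverse of [log_map()] at the same reference point:
#' \eqn{C = C_{ref}^{1/2} \exp(S) C_{ref}^{1/2}}.
#'
#' @param S symmetric matrix, a `"tangent_vector"`, or a vector as produced
#'   by [tangent_vectorize()].
#' @param Cref SPD reference point.
#' @return SPD matrix.
#' @export
exp_map <- function(S, Cref) {
  if (inherits(S, "tangent_vector")) S <- S$matrix_form
  if (is.numeric(S) && is.null(dim(S))) S <- tangent_unvectorize(S)
  sq <- spd_sqrt_invsqrt(Cref)$sqrt
  C <- sq %*% .sym_expm(S) %*% sq
  (C + t(C)) / 2
}

#' Frechet (geometric) mean of SPD matrices under the AIRM
#'
#' Fixed-point iteration: project onto the tangent space at the current
#' estimate, average, and map back, until the Frobenius norm of the mean
#' tangent falls below `tol`. Initialized at the arithmetic mean.
#'
#' @param Cs list of SPD matrices of common side.
#' @param tol convergence tolerance on the mean tangent norm.
#' @param max_iter maximum number of fixed-point iterations; on
#'   non-convergence the current estimate is returned with a warning.
#' @return SPD matrix minimizing the summed squared AIRM distances.
#' @export
frechet_mean <- function(Cs, tol = 1e-8, max_iter = 50L) {
  if (!is.list(Cs) || length(Cs) == 0)
    stop("Cs must be a non-empty list of SPD matrices")
  n <- nrow(Cs[[1]])
  if (!all(vapply(Cs, function(C) all(dim(C) == c(n, n)), logical(1))))
    stop("all matrices must share a common side")
  if (length(Cs) == 1L) return(.sym_check(Cs[[1]]))
  arr <- array(unlist(Cs), dim = c(n, n, length(Cs)))
  out <- .frechet_mean_cpp(arr, tol, as.integer(max_iter))
  if (!out$converged)
    warning("frechet_mean did not converge (final residual ",
            format(out$residual), ")")
  out$mean
}

#' Parallel transport of SPD matrices to the identity
#'
#' Transports each matrix along the geodesic from `Cm` to the identity using
#' the congruence \eqn{C \mapsto C_m^{-1/2} C C_m^{-1/2}}. When `Cm` is the
#' Frechet mean of the set, the transported set has Frechet mean I; pairwise
#' AIRM distances are preserved exactly.
#'
#' @param Cs list of SPD matrices (or a single matrix).
#' @param Cm SPD transport origin, typically the subclass Frechet mean.
#' @return List of transported SPD matrices (or a single matrix if `Cs` was
#'   one).
#' @export
transport_to_identity <- function(Cs, Cm) {
  single <- is.matrix(Cs)
  if (single) Cs <- list(Cs)
  isq <- spd_sqrt_invsqrt(Cm)$invsqrt
  out <- lapply(Cs, function(C) {
    if (!all(dim(C) == dim(Cm))) stop("matrix side mismatch with Cm")
    M <- isq %*% C %*% isq
    (M + t(M)) / 2
  })
  if (single) out[[1]] else out
}

## Index helpers for the fixed vectorization ordering: diagonal first, then
## the upper triangle row by row. Fixed and documented for serialization
## stability.
.vec_index <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  list(diag = cbind(seq_len(n), seq_len(n)), upper = ut)
}

#' Vectorize a symmetric matrix preserving the Frobenius inner product
#'
#' Returns the length n(n+1)/2 vector holding the diagonal entries followed
#' by the upper-triangular entries (row-major) scaled by \eqn{\sqrt 2}, so
#' that the Euclidean norm of the vector equals the Frobenius norm of the
#' matrix. Linear classification on these vectors is then congruent to
#' matrix-space computation.
#'
#' @param S symmetric matrix.
#' @return Numeric vector of length n(n+1)/2.
#' @seealso [tangent_unvectorize()]
#' @export
tangent_vectorize <- function(S) {
  S <- .sym_check(S, what = "S")
  n <- nrow(S)
  ix <- .vec_index(n)
  c(S[ix$diag], sqrt(2) * S[ix$upper])
}

#' Invert [tangent_vectorize()]
#'
#' @param v numeric vector of length n(n+1)/2 for some integer n.
#' @return The symmetric matrix whose vectorization is `v`.
#' @export
tangent_unvectorize <- function(v) {
  m <- length(v)
  n <- (sqrt(8 * m + 1) - 1) / 2
  if (abs(n - round(n)) > 1e-9)
    stop("length ", m, " is not n(n+1)/2 for any integer n")
  n <- as.integer(round(n))
  ix <- .vec_index(n)
  S <- matrix(0, n, n)
  S[ix$diag] <- v[seq_len(n)]
  off <- v[-seq_len(n)] / sqrt(2)
  S[ix$upper] <- off
  S[ix$upper[, c(2, 1), drop = FALSE]] <- off
  S
}
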