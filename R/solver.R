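#' Weighted minimum-norm solve (dense path)
#'
#' Closed-form solution of the weighted equality-constrained problem
#' \deqn{\min_U \mathrm{Tr}(U^T Q U) \quad \mathrm{s.t.}\; B U = X,}
#' with \eqn{Q = \mathrm{diag}(q)}:
#' \deqn{U = Q^{-1} B^T (B Q^{-1} B^T)^{-1} X.}
#' This is the inner step of the iteratively reweighted algorithm; the weights
#' come from [build_reweighting()]. Q is never inverted explicitly: rows of
#' \eqn{B^T} are divided by q.
#'
#' @param B Numeric n x b matrix with full row rank after weighting.
#' @param q Strictly positive weight vector of length b.
#' @param X Numeric n x c right-hand side.
#' @return The b x c minimizer `U`, satisfying `B %*% U == X` to numerical
#'   tolerance.
#' @examples
#' B <- cbind(diag(2), 0.5 * diag(2))
#' U <- weighted_minnorm_solve(B, rep(1, 4), diag(2))
#' max(abs(B %*% U - diag(2)))
#' @export
weighted_minnorm_solve <- function(B, q, X) {
  B <- as.matrix(B)
  X <- as.matrix(X)
  if (length(q) != ncol(B)) stop("length(q) must equal ncol(B)")
  if (any(!is.finite(q)) || any(q <= 0)) stop("weights 'q' must be strictly positive and finite")
  if (nrow(X) != nrow(B)) stop("nrow(X) must equal nrow(B)")
  BQinv <- sweep(B, 2L, q, "/")        # B Q^{-1}
  G <- BQinv %*% t(B)                  # B Q^{-1} B^T, n x n, sym. pos. def.
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R)) {
    stop("singular system B Q^{-1} B^T: B has lost row rank after weighting")
  }
  W <- backsolve(R, forwardsolve(t(R), X))   # (B Q^{-1} B^T)^{-1} X
  t(BQinv) %*% W                             # Q^{-1} B^T W
}

#' Weighted minimum-norm solve (diagonal-plus-low-rank fast path)
#'
#' Same contract as [weighted_minnorm_solve()] specialized to the structured
#' constraint matrix `B = [A, lam * I]`, where A is the n x d fixed basis and
#' I the n x n identity. Then
#' \deqn{B Q^{-1} B^T = A\,\mathrm{diag}(1/q_Y)\,A^T + \lambda^2 \mathrm{diag}(1/q_E),}
#' a diagonal-plus-rank-d matrix that is inverted through the matrix-inversion
#' (Woodbury) lemma: only d x d systems are factorized and no n x n matrix is
#' ever formed, so cost is linear in the number of genes n.
#'
#' @param A Numeric n x d nonnegative basis.
#' @param lam Positive scalar; scaling of the identity block.
#' @param qY Strictly positive weights for the d coefficient rows.
#' @param qE Strictly positive weights for the n sparse-component rows.
#' @param X Numeric n x c right-hand side.
#' @return The (d + n) x c minimizer `U`, rows 1..d the coefficient block Y,
#'   rows d+1..d+n the sparse component E.
#' @export
woodbury_minnorm_solve <- function(A, lam, qY, qE, X) {
  A <- as.matrix(A)
  X <- as.matrix(X)
  n <- nrow(A)
  d <- ncol(A)
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop("'lam' must be a single positive number")
  }
  if (length(qY) != d || length(qE) != n) stop("weight lengths must match dim(A)")
  if (any(!is.finite(qY)) || any(qY <= 0) || any(!is.finite(qE)) || any(qE <= 0)) {
    stop("weights must be strictly positive and finite")
  }
  if (nrow(X) != n) stop("nrow(X) must equal nrow(A)")
  # M = D + A Dy A^T with D = lam^2 / qE (diagonal, n-vector), Dy = diag(1/qY).
  # Woodbury: M^{-1} Z = D^{-1}Z - D^{-1} A (Dy^{-1} + A^T D^{-1} A)^{-1} A^T D^{-1} Z
  dinv <- qE / lam^2                         # D^{-1} as a vector
  ADi <- A * dinv                            # D^{-1} A (row scaling)
  S <- diag(qY, d) + crossprod(A, ADi)       # Dy^{-1} + A^T D^{-1} A, d x d
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    stop("singular system B Q^{-1} B^T: ill-conditioned capacitance matrix in fast path")
  }
  minv <- function(Z) {
    DiZ <- Z * dinv
    DiZ - ADi %*% backsolve(R, forwardsolve(t(R), crossprod(A, DiZ)))
  }
  W <- minv(X)                               # (B Q^{-1} B^T)^{-1} X
  Y <- crossprod(A, W) / qY                  # Q_Y^{-1} A^T W
  E <- lam * W / qE                          # Q_E^{-1} lam I W
  rbind(Y, E)
}
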