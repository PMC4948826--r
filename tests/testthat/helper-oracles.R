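# Independent oracles for the solver and enrichment tests. These must never
# share code with the package's own solution paths.

# Equality-constrained QP oracle: minimize Tr(U^T Q U) s.t. B U = X by solving
# the full KKT system [2Q, B^T; B, 0] [u; nu] = [0; x] column by column with
# a generic dense solve.
oracle_kkt_solve <- function(B, q, X) {
  b <- ncol(B)
  n <- nrow(B)
  KKT <- rbind(
    cbind(2 * diag(q, b), t(B)),
    cbind(B, matrix(0, n, n))
  )
  U <- matrix(0, b, ncol(X))
  for (j in seq_len(ncol(X))) {
    sol <- solve(KKT, c(rep(0, b), X[, j]))
    U[, j] <- sol[seq_len(b)]
  }
  U
}

# Generic convex oracle for the smoothed problem
#   min sum_i sqrt(||u^i||^2 + eps)  s.t.  B U = X  (no sign constraint):
# parameterize the affine feasible set as U = U0 + reshape(N w) with N an
# orthonormal null-space basis of the column-replicated constraint, then run
# quasi-Newton (BFGS) from the min-norm particular solution.
oracle_smoothed_fit <- function(B, X, eps, reltol = 1e-14) {
  b <- ncol(B)
  cc <- ncol(X)
  sv <- svd(B, nu = nrow(B), nv = b)
  r <- sum(sv$d > max(dim(B)) * max(sv$d) * 1e-12)
  Vnull <- sv$v[, -seq_len(r), drop = FALSE]      # null space of B
  U0 <- MASS_ginv_mult(B, X)                      # min-Frobenius particular solution
  obj <- function(w) {
    W <- matrix(w, ncol = cc)
    U <- U0 + Vnull %*% W
    sum(sqrt(rowSums(U^2) + eps))
  }
  k <- ncol(Vnull) * cc
  fit <- stats::optim(rep(0, k), obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = reltol))
  U0 + Vnull %*% matrix(fit$par, ncol = cc)
}

# Moore-Penrose pseudoinverse applied to X, via SVD (avoids a MASS dependency).
MASS_ginv_mult <- function(B, X) {
  sv <- svd(B)
  pos <- sv$d > max(dim(B)) * max(sv$d) * 1e-12
  sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*% X) / sv$d[pos])
}

# Exact hypergeometric upper tail by direct enumeration with choose();
# safe for N <= ~60 where choose() is exact in double precision.
oracle_hyper_enum <- function(k, nq, K, N) {
  jmax <- min(nq, K)
  if (k > jmax) return(0)
  j <- k:jmax
  sum(choose(K, j) * choose(N - K, nq - j)) / choose(N, nq)
}

# Random well-conditioned weighted min-norm instance.
random_instance <- function(n, b, cc, seed) {
  set.seed(seed)
  list(
    B = matrix(stats::rnorm(n * b), n, b) + diag(1, n, b),
    q = stats::runif(b, 0.2, 3),
    X = matrix(stats::rnorm(n * cc), n, cc)
  )
}

# Smoothed objective value, recomputed locally so tests do not depend on the
# package's internal helper.
smoothed_l21_for_test <- function(U, eps) sum(sqrt(rowSums(U^2) + eps))
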