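#' Solver configuration
#'
#' Bundles the tunable parameters of the robust factorization. Defaults follow
#' the published protocol: `lam = 0.3` (the value the lambda grid search picks
#' for nearly all plant stress datasets), smoothing `epsilon = 1e-8`, and a
#' relative-change stopping rule.
#'
#' @param lam Positive regularization weight lambda trading off the sparse
#'   component against the coefficient matrix.
#' @param d Positive integer factorization rank; should satisfy
#'   `d < min(n, c)` (a warning is issued otherwise).
#' @param epsilon Small positive smoothing constant in the row-norm weights;
#'   keeps the reweighting finite when rows collapse to zero.
#' @param max_iter Maximum number of reweighting iterations.
#' @param tol Convergence tolerance on the relative Frobenius change of U.
#' @param seed Integer seed for the one-time random nonnegative basis draw.
#' @param clamp If `TRUE` (default), negative entries of U are projected to
#'   zero after each closed-form solve, enforcing nonnegativity.
#' @param fast_path If `TRUE` (default), use the diagonal-plus-low-rank solve
#'   (linear in genes); otherwise form the dense constraint matrix.
#' @return A list of class `"solver_config"`.
#' @export
solver_config <- function(lam = 0.3, d = 3L, epsilon = 1e-8, max_iter = 100L,
                          tol = 1e-6, seed = 1L, clamp = TRUE,
                          fast_path = TRUE) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop("'lam' must be a single positive number (lambda > 0 is required)")
  }
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d != round(d)) {
    stop("'d' must be a positive integer rank")
  }
  if (!is.numeric(epsilon) || epsilon <= 0) stop("'epsilon' must be > 0")
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0")
  if (!is.numeric(max_iter) || max_iter < 1) stop("'max_iter' must be >= 1")
  structure(
    list(
      lam = as.numeric(lam), d = as.integer(d), epsilon = as.numeric(epsilon),
      max_iter = as.integer(max_iter), tol = as.numeric(tol),
      seed = as.integer(seed), clamp = isTRUE(clamp),
      fast_path = isTRUE(fast_path)
    ),
    class = "solver_config"
  )
}

#' Draw the fixed nonnegative basis
#'
#' The basis A is initialized once from a seeded uniform(0, 1) draw and never
#' updated; the iteration only re-estimates the stacked [Y; E].
#'
#' @param n,d Basis dimensions (genes x rank).
#' @param seed Integer seed.
#' @return An n x d matrix with entries in (0, 1).
#' @keywords internal
init_basis <- function(n, d, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  matrix(stats::runif(n * d), n, d)
}

#' Robust L2,1-norm nonnegative factorization
#'
#' Decomposes a nonnegative gene-by-sample matrix X as
#' \deqn{A Y + \lambda E = X,} minimizing the joint row-sparsity objective
#' \deqn{\|E\|_{2,1} + \|Y\|_{2,1}} (equivalently
#' \eqn{\|X - AY\|_{2,1} + \lambda \|Y\|_{2,1}}) over the stacked unknown
#' `U = rbind(Y, E)` subject to `B U = X` with `B = [A, lam I]`. The basis A
#' is a fixed seeded nonnegative draw; each iteration solves the weighted
#' minimum-norm problem in closed form, optionally clamps U at zero, and
#' refreshes the row weights. Rows of E with large Euclidean norm flag genes
#' poorly explained by the low-rank background — the characteristic genes.
#'
#' @param X An [expression_matrix()] (or plain nonnegative numeric matrix),
#'   genes x samples.
#' @param config A [solver_config()].
#' @param A Optional fixed basis to use instead of the seeded draw (n x d,
#'   nonnegative); used e.g. when the generating basis of synthetic data is
#'   known.
#' @param verbose If `TRUE`, print per-iteration objective and constraint
#'   residual.
#' @return An object of class `"nmf_l21_fit"`: a list with the basis `A`, the
#'   coefficient block `Y` (d x c), sparse component `E` (n x c), stacked `U`,
#'   `b = d + n`, the per-iteration smoothed objective `objective_trace`, the
#'   unscaled-loss diagnostic `objective_eq_loss`
#'   (\eqn{\|X - AY\|_{2,1} + \lambda\|Y\|_{2,1}}), iteration count, and a
#'   convergence flag.
#' @examples
#' sim <- generate_synthetic(n = 60, c = 6, d = 2, k_outliers = 4, seed = 1)
#' fit <- nmf_l21_fit(sim$X, solver_config(lam = 0.3, d = 2, seed = 1))
#' fit
#' @export
nmf_l21_fit <- function(X, config = solver_config(), A = NULL, verbose = FALSE) {
  if (!inherits(X, "expression_matrix")) {
    X <- expression_matrix(as.matrix(X))
  }
  stopifnot(inherits(config, "solver_config"))
  n <- nrow(X)
  c_ <- ncol(X)
  d <- config$d
  if (d >= min(n, c_)) {
    warning(sprintf("rank d = %d is not < min(n, c) = %d; the factorization is over-parameterized", d, min(n, c_)))
  }
  if (is.null(A)) {
    A <- init_basis(n, d, config$seed)
  } else {
    A <- as.matrix(A)
    if (nrow(A) != n || ncol(A) != d) stop("supplied basis A must be n x d")
    if (any(A < 0)) stop("supplied basis A must be nonnegative")
  }
  lam <- config$lam
  eps <- config$epsilon
  Xv <- unclass(X)
  dimnames(Xv) <- NULL
  b <- d + n

  q <- rep(1, b)                     # Q starts as the identity
  U <- matrix(0, b, c_)
  trace_obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  Bdense <- if (!config$fast_path) cbind(A, lam * diag(n)) else NULL

  for (t in seq_len(config$max_iter)) {
    iter <- t
    U_new <- if (config$fast_path) {
      woodbury_minnorm_solve(A, lam, q[seq_len(d)], q[d + seq_len(n)], Xv)
    } else {
      weighted_minnorm_solve(Bdense, q, Xv)
    }
    dimnames(U_new) <- NULL
    if (config$clamp) U_new[U_new < 0] <- 0
    q <- build_reweighting(U_new, eps)
    obj <- smoothed_l21(U_new, eps)
    trace_obj <- c(trace_obj, obj)
    if (verbose) {
      resid <- sqrt(sum((A %*% U_new[seq_len(d), , drop = FALSE] +
                           lam * U_new[d + seq_len(n), , drop = FALSE] - Xv)^2))
      message(sprintf("iter %3d  objective %.8g  ||BU - X||_F %.3g", t, obj, resid))
    }
    delta <- sqrt(sum((U_new - U)^2)) / max(1, sqrt(sum(U^2)))
    U <- U_new
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }

  Y <- U[seq_len(d), , drop = FALSE]
  E <- U[d + seq_len(n), , drop = FALSE]
  rownames(E) <- gene_ids(X)
  colnames(E) <- sample_ids(X)
  colnames(Y) <- sample_ids(X)
  structure(
    list(
      A = A, Y = Y, E = E, U = U, b = b,
      gene_ids = gene_ids(X), sample_ids = sample_ids(X),
      config = config,
      objective_trace = trace_obj,
      objective_eq_loss = l21_norm(Xv - A %*% Y) + lam * l21_norm(Y),
      constraint_residual = sqrt(sum((A %*% Y + lam * E - Xv)^2)),
      n_iter = iter, converged = converged
    ),
    class = "nmf_l21_fit"
  )
}

#' @export
print.nmf_l21_fit <- function(x, ...) {
  cat(sprintf(
    "nmf_l21_fit: %d genes x %d samples, rank %d, lambda = %g\n",
    length(x$gene_ids), length(x$sample_ids), x$config$d, x$config$lam
  ))
  cat(sprintf(
    "  %d iteration(s), %s; smoothed objective %.6g; ||X - AY||_{2,1} + lam ||Y||_{2,1} = %.6g\n",
    x$n_iter, if (x$converged) "converged" else "max_iter reached",
    utils::tail(x$objective_trace, 1L), x$objective_eq_loss
  ))
  invisible(x)
}
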