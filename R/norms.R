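#' L2,1 norm of a matrix
#'
#' The L2,1 norm is the sum over rows of each row's Euclidean (L2) norm,
#' \deqn{\|M\|_{2,1} = \sum_i \|m^i\|_2.} Minimizing it drives whole rows to
#' zero, which is what makes the sparse component's rows usable as a gene
#' score: a gene either carries signal across samples or is zeroed as a group.
#'
#' @param M Numeric matrix (a vector is treated as a single-column matrix).
#' @return A nonnegative scalar; zero iff `M` is all zeros.
#' @examples
#' l21_norm(rbind(c(3, 4), c(0, 0)))  # 5
#' @export
l21_norm <- function(M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  if (!is.numeric(M)) stop("'M' must be numeric")
  if (any(!is.finite(M))) stop("l21_norm: non-finite entries in input")
  sum(sqrt(rowSums(M^2)))
}

#' Smoothed L2,1 objective value
#'
#' \eqn{\sum_i \sqrt{\|u^i\|_2^2 + \epsilon}}: the epsilon-smoothed surrogate
#' of the L2,1 norm whose value the reweighting iteration provably decreases.
#'
#' @param U Numeric matrix.
#' @param epsilon Positive smoothing constant.
#' @return Scalar objective value.
#' @keywords internal
smoothed_l21 <- function(U, epsilon) {
  sum(sqrt(rowSums(U^2) + epsilon))
}

#' Reweighting vector for the iteratively reweighted solve
#'
#' Computes the diagonal of the weight matrix Q from the current stacked
#' solution U: element i is \eqn{1 / (2 \sqrt{\|u^i\|_2^2 + \epsilon})}.
#' The smoothing constant epsilon keeps every weight finite when a row of U
#' has collapsed to zero.
#'
#' @param U Numeric matrix, one weight per row.
#' @param epsilon Positive smoothing constant.
#' @return Numeric vector of strictly positive, finite weights, length
#'   `nrow(U)`.
#' @examples
#' build_reweighting(rbind(c(3, 0), c(0, 4)), epsilon = 0)  # 1/6, 1/8
#' @export
build_reweighting <- function(U, epsilon) {
  if (!is.matrix(U)) U <- as.matrix(U)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) || epsilon < 0) {
    stop("'epsilon' must be a single nonnegative number")
  }
  if (epsilon == 0 && any(rowSums(U^2) == 0)) {
    stop("'epsilon' must be > 0 when U has zero rows")
  }
  1 / (2 * sqrt(rowSums(U^2) + epsilon))
}
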