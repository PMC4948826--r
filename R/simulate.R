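#' Generate a synthetic expression matrix with planted characteristic genes
#'
#' Emulates the data regime the factorization assumes: a nonnegative low-rank
#' background `A_true %*% Y_true` (uniform nonnegative factors), a small set
#' of "characteristic" gene rows carrying an additive nonnegative bump, and
#' truncated-Gaussian noise (clipped at zero to respect nonnegativity). Bump
#' and noise magnitudes are parameterized relative to the background scale so
#' defaults are scale-free: each planted row's bump has Euclidean norm
#' `outlier_magnitude` times the median background row norm, and the noise
#' standard deviation is `noise_sd` times the median background entry.
#'
#' `A_true` is drawn exactly as the solver's own seeded basis
#' (uniform(0, 1) with `set.seed(seed)`), so a fit with `seed = seed` and
#' rank `d` — or one given `A = truth$A_true` — uses a basis that can
#' represent the background exactly.
#'
#' @param n Number of genes.
#' @param c Number of samples.
#' @param d Background rank, `d < min(n, c)`.
#' @param k_outliers Number of planted characteristic genes, `< n`.
#' @param outlier_magnitude Bump size relative to the median background row
#'   norm.
#' @param noise_sd Noise standard deviation relative to the median background
#'   entry.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A list with `X` (an [expression_matrix()]) and `truth`, a list of
#'   class `"synthetic_truth"` carrying `outlier_rows` (integer indices),
#'   `outlier_gene_ids`, `A_true`, `Y_true`, `noise_sd`, `outlier_magnitude`.
#' @examples
#' sim <- generate_synthetic(n = 100, c = 8, d = 3, k_outliers = 5, seed = 0)
#' sim$truth$outlier_gene_ids
#' @export
generate_synthetic <- function(n, c, d, k_outliers, outlier_magnitude = 5,
                               noise_sd = 0.05, seed = 0L) {
  if (n < 2 || c < 1 || d < 1) stop("invalid sizes: need n >= 2, c >= 1, d >= 1")
  if (d >= min(n, c)) stop(sprintf("rank d = %d must be < min(n, c) = %d", d, min(n, c)))
  if (k_outliers < 0 || k_outliers >= n) stop("'k_outliers' must be in [0, n)")
  if (outlier_magnitude <= 0) stop("'outlier_magnitude' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  A_true <- init_basis(n, d, seed)    # same draw as the solver's fixed basis
  set.seed(seed + 1L)
  Y_true <- matrix(stats::runif(d * c), d, c)
  background <- A_true %*% Y_true

  med_row_norm <- stats::median(sqrt(rowSums(background^2)))
  med_entry <- stats::median(background)

  outlier_rows <- if (k_outliers > 0) sort(sample.int(n, k_outliers)) else integer(0)
  O <- matrix(0, n, c)
  for (i in outlier_rows) {
    bump <- stats::runif(c)
    O[i, ] <- bump / sqrt(sum(bump^2)) * outlier_magnitude * med_row_norm
  }

  noise <- if (noise_sd > 0) {
    matrix(stats::rnorm(n * c, sd = noise_sd * med_entry), n, c)
  } else {
    matrix(0, n, c)
  }

  X <- pmax(background + O + noise, 0)
  gene_ids <- sprintf("gene_%04d", seq_len(n))
  Xm <- expression_matrix(X, gene_ids = gene_ids,
                          sample_ids = sprintf("sample_%02d", seq_len(c)))
  truth <- structure(
    list(
      outlier_rows = outlier_rows,
      outlier_gene_ids = gene_ids[outlier_rows],
      A_true = A_true, Y_true = Y_true,
      noise_sd = noise_sd, outlier_magnitude = outlier_magnitude
    ),
    class = "synthetic_truth"
  )
  list(X = Xm, truth = truth)
}

#' Generate a toy GMT annotation collection from a synthetic truth
#'
#' Builds a small annotation collection for enrichment tests: one term
#' enriched in the planted characteristic genes (the planted set plus a few
#' background genes), one depleted term (background genes only), and a number
#' of random terms. The background is all genes of the synthetic matrix.
#'
#' @param X The synthetic [expression_matrix()].
#' @param truth The matching `"synthetic_truth"`.
#' @param n_random Number of random decoy terms.
#' @param term_size Size of each decoy term.
#' @param seed Integer seed.
#' @return An [annotation_collection()].
#' @export
simulate_gmt <- function(X, truth, n_random = 5L, term_size = 20L, seed = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ids <- gene_ids(X)
  planted <- truth$outlier_gene_ids
  bg_genes <- setdiff(ids, planted)
  terms <- list(
    planted_response = c(planted, sample(bg_genes, min(5L, length(bg_genes)))),
    background_only = sample(bg_genes, min(term_size, length(bg_genes)))
  )
  for (i in seq_len(n_random)) {
    terms[[sprintf("random_%02d", i)]] <- sample(ids, min(term_size, length(ids)))
  }
  annotation_collection(terms, background = ids)
}
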