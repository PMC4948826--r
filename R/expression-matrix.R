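#' Construct a validated expression matrix
#'
#' An expression matrix is a nonnegative numeric matrix of genes (rows) by
#' samples (columns), carrying unique gene and sample identifiers as dimnames.
#' It is the data container consumed by [nmf_l21_fit()] and produced by
#' [read_expression()] and [generate_synthetic()].
#'
#' @param values Numeric matrix, genes x samples. All entries must be finite
#'   and >= 0 (unless `clamp_negative = TRUE`, in which case negatives are set
#'   to zero).
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to existing rownames, or `gene_1..gene_n`.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   column. Defaults to existing colnames, or `sample_1..sample_c`.
#' @param clamp_negative If `TRUE`, negative entries are clamped to zero
#'   instead of raising an error.
#' @return A numeric matrix of class `"expression_matrix"` with gene ids as
#'   rownames and sample ids as colnames.
#' @examples
#' x <- expression_matrix(matrix(1:6, 3, 2), gene_ids = c("g1", "g2", "g3"))
#' gene_ids(x)
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL,
                              clamp_negative = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("expression matrix must have at least one gene and one sample")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite entry at row %d, column %d", bad[1L], bad[2L]))
  }
  if (any(values < 0)) {
    if (clamp_negative) {
      values[values < 0] <- 0
    } else {
      bad <- which(values < 0, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "negative entry at gene row %d, sample column %d; expression values must be >= 0 (use clamp_negative = TRUE to clamp)",
        bad[1L], bad[2L]
      ))
    }
  }
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length of 'gene_ids' must equal the number of rows")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length of 'sample_ids' must equal the number of columns")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @export
gene_ids <- function(x) rownames(x)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d genes x %d samples (range %.4g .. %.4g)\n",
    nrow(x), ncol(x), min(x), max(x)
  ))
  invisible(x)
}
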