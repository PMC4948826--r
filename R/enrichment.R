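#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X hypergeometric: a query of `n_query` genes drawn without
#' replacement from a background of `N` genes of which `K` carry the
#' annotation. This is the over-representation statistic behind GO-term
#' P-values. The sum is computed exactly in log space via log-gamma
#' (no normal approximation), so tail probabilities of order 1e-150 and
#' smaller are representable.
#'
#' @param k Observed overlap (query genes carrying the annotation).
#' @param n_query Query size.
#' @param K Annotated genes in the background.
#' @param N Background (universe) size.
#' @param log_p If `TRUE`, return the natural log of the tail probability.
#' @return The tail probability in (0, 1] (or its log).
#' @examples
#' hypergeom_sf(2, 2, 2, 5)  # choose(2,2)/choose(5,2) = 0.1
#' @export
hypergeom_sf <- function(k, n_query, K, N, log_p = FALSE) {
  for (v in list(k = k, n_query = n_query, K = K, N = N)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v != round(v)) {
      stop("counts must be single nonnegative integers")
    }
  }
  if (k > n_query) stop("k must be <= n_query")
  if (n_query > N) stop("n_query must be <= N")
  if (K > N) stop("K must be <= N")
  if (k == 0) return(if (log_p) 0 else 1)
  jmax <- min(n_query, K)
  if (k > jmax) return(if (log_p) -Inf else 0)
  j <- k:jmax
  # log P(X = j) = log C(K, j) + log C(N-K, n-j) - log C(N, n), via lchoose
  logp <- lchoose(K, j) + lchoose(N - K, n_query - j) - lchoose(N, n_query)
  m <- max(logp)
  ls <- m + log(sum(exp(logp - m)))          # log-sum-exp over the upper tail
  if (log_p) min(ls, 0) else min(exp(ls), 1)
}

#' Build an annotation collection from term gene sets
#'
#' @param terms Named list: term id -> character vector of member gene ids.
#' @param term_names Optional named character vector of human-readable term
#'   names (defaults to the ids).
#' @param background Character vector giving the gene universe. Defaults to
#'   the union of all annotated genes. Term members outside the background are
#'   dropped (with a message giving the count).
#' @return A list of class `"annotation_collection"` with elements `terms`,
#'   `term_names`, `background`.
#' @export
annotation_collection <- function(terms, term_names = NULL, background = NULL) {
  if (!is.list(terms) || is.null(names(terms)) || anyDuplicated(names(terms))) {
    stop("'terms' must be a list with unique term-id names")
  }
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (is.null(background)) {
    background <- sort(unique(unlist(terms, use.names = FALSE)))
  }
  background <- unique(as.character(background))
  n_dropped <- 0L
  terms <- lapply(terms, function(g) {
    keep <- g %in% background
    n_dropped <<- n_dropped + sum(!keep)
    g[keep]
  })
  if (n_dropped > 0L) {
    message(sprintf("annotation_collection: dropped %d term members outside the background", n_dropped))
  }
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(terms), names(terms))
  } else {
    term_names <- stats::setNames(as.character(term_names)[match(names(terms), names(term_names))], names(terms))
    term_names[is.na(term_names)] <- names(terms)[is.na(term_names)]
  }
  structure(
    list(terms = terms, term_names = term_names, background = background),
    class = "annotation_collection"
  )
}

#' Hypergeometric term enrichment of a gene list
#'
#' For every term, counts the overlap with the query and computes the
#' upper-tail hypergeometric P-value against the collection's background.
#' Defaults replicate the published evaluation thresholds: terms are kept
#' when the overlap has at least `min_genes = 2` genes and the raw P-value is
#' at most `max_p = 0.01`. A Bonferroni-adjusted column (multiplier = number
#' of terms tested) is always emitted alongside the raw P-value; filtering
#' uses the raw value unless `use_bonferroni = TRUE`.
#'
#' @param query Character vector of gene ids. Genes outside the background
#'   are dropped (with a message giving the count).
#' @param annotations An [annotation_collection()] (or the path of a GMT
#'   file, read via [read_gmt()]).
#' @param max_p Maximum P-value for a term to be reported.
#' @param min_genes Minimum overlap count for a term to be reported.
#' @param use_bonferroni Filter on the Bonferroni-adjusted P-value instead of
#'   the raw one.
#' @return A `data.frame` with columns `term_id`, `term_name`, `k` (overlap),
#'   `n_query`, `K` (term size in background), `N` (background size), `p`,
#'   `p_bonferroni`, `genes` (comma-separated overlap), sorted by ascending
#'   `p`.
#' @export
enrich <- function(query, annotations, max_p = 0.01, min_genes = 2L,
                   use_bonferroni = FALSE) {
  if (is.character(annotations) && length(annotations) == 1L && file.exists(annotations)) {
    annotations <- read_gmt(annotations)
  }
  stopifnot(inherits(annotations, "annotation_collection"))
  query <- unique(as.character(query))
  if (length(query) == 0L) stop("'query' must be non-empty")
  bg <- annotations$background
  if (length(bg) == 0L) stop("annotation background is empty")
  in_bg <- query %in% bg
  if (any(!in_bg)) {
    message(sprintf("enrich: dropped %d query genes outside the background", sum(!in_bg)))
  }
  query <- query[in_bg]
  if (length(query) == 0L) stop("no query genes remain inside the background")
  N <- length(bg)
  nq <- length(query)
  n_terms <- length(annotations$terms)
  rows <- lapply(names(annotations$terms), function(tid) {
    members <- annotations$terms[[tid]]
    ov <- intersect(query, members)
    k <- length(ov)
    K <- length(members)
    p <- hypergeom_sf(k, nq, K, N)
    data.frame(
      term_id = tid, term_name = unname(annotations$term_names[tid]),
      k = k, n_query = nq, K = K, N = N,
      p = p, p_bonferroni = min(1, p * n_terms),
      genes = paste(sort(ov), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  p_filter <- if (use_bonferroni) out$p_bonferroni else out$p
  out <- out[out$k >= min_genes & p_filter <= max_p, , drop = FALSE]
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
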