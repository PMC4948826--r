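#' Read an expression matrix from delimited text
#'
#' Expects a rectangular table whose first column holds gene ids and whose
#' first row holds sample ids; remaining cells are numeric expression values.
#' The delimiter is inferred from the extension (`.csv` -> comma, anything
#' else -> tab) unless given explicitly.
#'
#' @param path Path of the TSV/CSV file.
#' @param delimiter Field delimiter; `NULL` to infer from the extension.
#' @param clamp_negative Clamp negative values to zero instead of failing.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, delimiter = NULL, clamp_negative = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- tryCatch(
    utils::read.table(path, sep = delimiter, header = TRUE, check.names = FALSE,
                      row.names = NULL, stringsAsFactors = FALSE,
                      comment.char = "", quote = "\""),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  if (ncol(df) < 2L) stop("expected a gene-id column plus at least one sample column in ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  samples <- colnames(vals)
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) & vals[[j]] != "NA")
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric cell at gene '%s', sample '%s' in %s",
                   ids[bad[1L]], samples[j], path))
    }
    if (anyNA(v)) {
      stop(sprintf("missing value at gene '%s', sample '%s' in %s",
                   ids[which(is.na(v))[1L]], samples[j], path))
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L && !clamp_negative) {
    stop(sprintf("negative value at gene '%s', sample '%s' in %s",
                 ids[neg[1L, 1L]], samples[neg[1L, 2L]], path))
  }
  expression_matrix(m, gene_ids = ids, sample_ids = samples,
                    clamp_negative = clamp_negative)
}

#' Write a gene ranking as TSV
#'
#' Columns, in fixed order: `gene_id`, `score`, `rank`.
#'
#' @param ranked A `"ranked_genes"` data frame.
#' @param path Output path.
#' @param k Optionally truncate to the top k rows before writing.
#' @export
write_ranking <- function(ranked, path, k = NULL) {
  stopifnot(inherits(ranked, "ranked_genes"))
  if (!is.null(k)) ranked <- ranked[seq_len(min(k, nrow(ranked))), , drop = FALSE]
  utils::write.table(ranked[, c("gene_id", "score", "rank")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene ranking written by [write_ranking()]
#'
#' @param path TSV path.
#' @return A `"ranked_genes"` data frame.
#' @export
read_ranking <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "score", "rank") %in% colnames(df))) {
    stop("not a ranking file (need columns gene_id, score, rank): ", path)
  }
  df$gene_id <- as.character(df$gene_id)
  class(df) <- c("ranked_genes", class(df))
  df
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated fields
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Lines with fewer than
#' three fields are a parse error (a gene set needs at least one member).
#'
#' @param path GMT file path.
#' @param background Optional gene universe; defaults to the union of all
#'   annotated genes.
#' @return An [annotation_collection()].
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  terms <- list()
  term_names <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT parse error at line %d of %s: expected >= 3 tab-separated fields, got %d",
                   i, path, length(fields)))
    }
    tid <- fields[[1L]]
    terms[[tid]] <- fields[-(1:2)]
    term_names[tid] <- fields[[2L]]
  }
  annotation_collection(terms, term_names = term_names, background = background)
}

#' Write an annotation collection as GMT
#'
#' @param annotations An [annotation_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_collection"))
  lines <- vapply(names(annotations$terms), function(tid) {
    paste(c(tid, unname(annotations$term_names[tid]), annotations$terms[[tid]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write enrichment results as TSV
#'
#' Fixed column order: `term_id`, `term_name`, `k`, `n_query`, `K`, `N`, `p`,
#' `p_bonferroni`, `genes`.
#'
#' @param results Data frame from [enrich()].
#' @param path Output path.
#' @export
write_enrichment <- function(results, path) {
  cols <- c("term_id", "term_name", "k", "n_query", "K", "N", "p",
            "p_bonferroni", "genes")
  if (!all(cols %in% colnames(results))) stop("not an enrichment result table")
  utils::write.table(results[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value configuration file into a solver_config
#'
#' Lines look like `lambda=0.3`; `#` starts a comment. Recognized keys:
#' lambda, rank, epsilon, max_iter, tol, seed, clamp, fast_path. Unknown keys
#' are an error. A `.json` extension is also accepted (same keys).
#'
#' @param path Config file path.
#' @param base A [solver_config()] supplying values for keys the file omits.
#' @return A [solver_config()].
#' @export
read_solver_config <- function(path, base = solver_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  kv <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
    parts <- strsplit(lines, "=", fixed = TRUE)
    stats::setNames(
      lapply(parts, function(p) trimws(paste(p[-1L], collapse = "="))),
      trimws(vapply(parts, `[[`, character(1), 1L))
    )
  }
  key_map <- c(lambda = "lam", lam = "lam", rank = "d", d = "d",
               epsilon = "epsilon", max_iter = "max_iter", tol = "tol",
               seed = "seed", clamp = "clamp", fast_path = "fast_path")
  cfg <- unclass(base)
  for (key in names(kv)) {
    if (!key %in% names(key_map)) stop("unknown config key: ", key)
    field <- key_map[[key]]
    val <- kv[[key]]
    cfg[[field]] <- if (field %in% c("clamp", "fast_path")) {
      tolower(as.character(val)) %in% c("true", "1", "yes", "on")
    } else {
      as.numeric(val)
    }
  }
  do.call(solver_config, cfg)
}

#' Write a run manifest alongside outputs
#'
#' Records input/output paths, the resolved solver configuration, selection
#' size, seed, package version and a timestamp as JSON, so any run can be
#' reproduced from its outputs.
#'
#' @param path Manifest output path (JSON).
#' @param inputs Named list/character of input paths.
#' @param outputs Named list/character of output paths.
#' @param config A [solver_config()] (optional).
#' @param extra Named list of extra fields (e.g. `k`, `max_p`).
#' @export
write_manifest <- function(path, inputs = list(), outputs = list(),
                           config = NULL, extra = list()) {
  manifest <- c(
    list(
      tool = "nmfl21",
      version = as.character(utils::packageVersion("nmfl21")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      inputs = as.list(inputs),
      outputs = as.list(outputs)
    ),
    if (!is.null(config)) list(config = unclass(config)),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
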