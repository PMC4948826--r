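test_that("hypergeom_sf matches enumeration across the support (N <= 60)", {
  cases <- expand.grid(N = c(5, 12, 30, 60), frac_K = c(0.2, 0.5, 0.9),
                       frac_n = c(0.1, 0.4, 0.8))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]
    K <- max(1L, round(cases$frac_K[i] * N))
    nq <- max(1L, round(cases$frac_n[i] * N))
    for (k in 0:min(nq, K)) {
      expect_equal(hypergeom_sf(k, nq, K, N), oracle_hyper_enum(k, nq, K, N),
                   tolerance = 1e-12,
                   label = sprintf("sf(k=%d, n=%d, K=%d, N=%d)", k, nq, K, N))
    }
  }
})

test_that("hypergeom_sf boundary values and count checks", {
  expect_equal(hypergeom_sf(0, 10, 5, 20), 1)
  expect_equal(hypergeom_sf(2, 2, 2, 5), 0.1)      # C(2,2)/C(5,2)
  expect_error(hypergeom_sf(3, 2, 2, 5), "k must be")
  expect_error(hypergeom_sf(1, 10, 2, 5), "n_query")
  expect_error(hypergeom_sf(1, 2, 9, 5), "K must be")
  expect_error(hypergeom_sf(-1, 2, 2, 5), "nonnegative")
})

test_that("hypergeom_sf properties: monotone in k, complements sum to one, log path", {
  N <- 40; K <- 15; nq <- 12
  sf <- vapply(0:min(nq, K), hypergeom_sf, numeric(1), n_query = nq, K = K, N = N)
  expect_true(all(diff(sf) <= 1e-15))
  for (k in 1:min(nq, K)) {
    cdf_km1 <- 1 - oracle_hyper_enum(k, nq, K, N)    # P(X <= k-1)
    expect_equal(hypergeom_sf(k, nq, K, N) + cdf_km1, 1, tolerance = 1e-12)
  }
  # log-space and linear paths agree where both are representable
  expect_equal(exp(hypergeom_sf(8, nq, K, N, log_p = TRUE)),
               hypergeom_sf(8, nq, K, N), tolerance = 1e-12)
  # deep tails stay representable (no underflow to 0)
  p <- hypergeom_sf(353, 500, 6617, 30320)
  expect_gt(p, 0)
  expect_lt(p, 1e-100)
  # cross-check against R's own distribution function
  expect_equal(log(p), phyper(352, 6617, 30320 - 6617, 500, lower.tail = FALSE,
                              log.p = TRUE), tolerance = 1e-8)
})

toy_collection <- function() {
  annotation_collection(
    terms = list(
      t1 = c("g1", "g2", "g3"),
      t2 = c("g4", "g5"),
      t3 = c("g1", "g6", "g7", "g8")
    ),
    term_names = c(t1 = "term one", t2 = "term two", t3 = "term three"),
    background = paste0("g", 1:12)
  )
}

test_that("enrich computes counts and p-values matching enumeration", {
  ann <- toy_collection()
  res <- enrich(c("g1", "g2", "g6"), ann, max_p = 1, min_genes = 0L)
  expect_equal(nrow(res), 3)
  r1 <- res[res$term_id == "t1", ]
  expect_equal(r1$k, 2)
  expect_equal(r1$K, 3)
  expect_equal(r1$N, 12)
  expect_equal(r1$p, oracle_hyper_enum(2, 3, 3, 12), tolerance = 1e-12)
  expect_equal(res[res$term_id == "t3", ]$p, oracle_hyper_enum(2, 3, 4, 12),
               tolerance = 1e-12)
  expect_equal(res$p_bonferroni, pmin(1, res$p * 3), tolerance = 1e-12)
  expect_true(!is.unsorted(res$p))
})

test_that("enrich applies the published min-genes and max-p thresholds", {
  ann <- toy_collection()
  # t2 overlaps the query in exactly 1 gene -> dropped by min_genes = 2
  res <- enrich(c("g1", "g2", "g4"), ann, max_p = 1, min_genes = 2L)
  expect_false("t2" %in% res$term_id)
  expect_true("t1" %in% res$term_id)
  # query = background -> every k = K with p = 1, filtered by max_p
  res_all <- enrich(paste0("g", 1:12), ann, max_p = 0.01, min_genes = 0L)
  expect_equal(nrow(res_all), 0)
  res_all2 <- enrich(paste0("g", 1:12), ann, max_p = 1, min_genes = 0L)
  expect_equal(res_all2$k, res_all2$K)
  expect_true(all(res_all2$p == 1))
  # default thresholds replicate the protocol
  expect_equal(formals(enrich)$max_p, 0.01)
  expect_equal(formals(enrich)$min_genes, 2L)
})

test_that("enrich handles out-of-background queries and bad inputs", {
  ann <- toy_collection()
  expect_message(res <- enrich(c("g1", "g2", "not_a_gene"), ann, max_p = 1,
                               min_genes = 0L), "dropped 1")
  expect_equal(res$n_query[1], 2)
  expect_error(enrich(character(0), ann), "non-empty")
  expect_error(enrich("zz", ann), "background")
})

test_that("annotation_collection enforces subset and uniqueness invariants", {
  expect_message(
    ann <- annotation_collection(list(t1 = c("a", "b", "zzz")),
                                 background = c("a", "b", "c")),
    "dropped 1"
  )
  expect_equal(ann$terms$t1, c("a", "b"))
  expect_error(annotation_collection(list(a = "x", a = "y")), "unique")
  # default background = union of annotated genes
  ann2 <- annotation_collection(list(t1 = c("a", "b"), t2 = c("b", "c")))
  expect_setequal(ann2$background, c("a", "b", "c"))
})
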