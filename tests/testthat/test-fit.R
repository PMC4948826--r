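test_that("solver_config validates parameters", {
  expect_error(solver_config(lam = 0), "positive")
  expect_error(solver_config(lam = -0.5), "positive")
  expect_error(solver_config(epsilon = 0), "epsilon")
  expect_error(solver_config(tol = -1), "tol")
  cfg <- solver_config()
  expect_equal(cfg$lam, 0.3)
  expect_true(cfg$clamp && cfg$fast_path)
})

test_that("all-zero input collapses to the epsilon floor immediately", {
  X <- expression_matrix(matrix(0, 10, 4))
  fit <- nmf_l21_fit(X, solver_config(d = 2, seed = 1))
  expect_equal(fit$Y, matrix(0, 2, 4, dimnames = list(NULL, sample_ids(X))))
  expect_equal(unname(unclass(fit$E)), matrix(0, 10, 4))
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 2)
  # smoothed objective of an all-zero U is b * sqrt(eps)
  expect_equal(tail(fit$objective_trace, 1), 12 * sqrt(1e-8))
})

test_that("fit structure honors its invariants", {
  sim <- generate_synthetic(n = 50, c = 6, d = 2, k_outliers = 4, seed = 3)
  cfg <- solver_config(lam = 0.4, d = 2, seed = 3)
  fit <- nmf_l21_fit(sim$X, cfg)
  expect_equal(fit$b, 2 + 50)
  expect_equal(fit$U, rbind(unname(fit$Y), unname(unclass(fit$E))))
  expect_true(all(fit$A >= 0))
  expect_true(all(fit$U >= 0))          # clamp on
  expect_equal(dim(fit$Y), c(2, 6))
  expect_equal(dim(fit$E), c(50, 6))
  expect_equal(rownames(fit$E), gene_ids(sim$X))
  # determinism: same seed, same config -> identical result
  fit2 <- nmf_l21_fit(sim$X, cfg)
  expect_identical(fit$U, fit2$U)
})

test_that("fit rejects contract violations and warns on over-ranked d", {
  Xneg <- matrix(c(-1, 1, 1, 1), 2, 2)
  expect_error(nmf_l21_fit(Xneg, solver_config(d = 1)), "negative")
  sim <- generate_synthetic(n = 10, c = 4, d = 2, k_outliers = 0, seed = 1)
  expect_warning(nmf_l21_fit(sim$X, solver_config(d = 4, seed = 1)), "rank")
  expect_error(solver_config(lam = -1), "positive")
})

test_that("clamp-off solve stays feasible and descends monotonically", {
  for (seed in 1:6) {
    sim <- generate_synthetic(n = 30, c = 5, d = 2, k_outliers = 2, seed = seed)
    cfg <- solver_config(lam = 0.5, d = 2, seed = seed, clamp = FALSE,
                         max_iter = 40)
    fit <- nmf_l21_fit(sim$X, cfg)
    B <- cbind(fit$A, cfg$lam * diag(30))
    expect_lt(norm(B %*% fit$U - unclass(sim$X), "F") /
                norm(unclass(sim$X), "F"), 1e-8)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
  }
})

test_that("fast path and dense path agree through the full iteration", {
  sim <- generate_synthetic(n = 60, c = 6, d = 3, k_outliers = 5, seed = 11)
  f1 <- nmf_l21_fit(sim$X, solver_config(lam = 0.3, d = 3, seed = 11))
  f2 <- nmf_l21_fit(sim$X, solver_config(lam = 0.3, d = 3, seed = 11,
                                         fast_path = FALSE))
  expect_equal(f1$U, f2$U, tolerance = 1e-8)
  expect_equal(f1$objective_trace, f2$objective_trace, tolerance = 1e-8)
})

test_that("growing lambda shifts mass from Y into the residual", {
  # directional sanity of the loss/penalty trade-off, on the unconstrained
  # (clamp-off) path where the closed form is exact
  sim <- generate_synthetic(n = 40, c = 6, d = 2, k_outliers = 3, seed = 5)
  f_small <- nmf_l21_fit(sim$X, solver_config(lam = 0.1, d = 2, seed = 5,
                                              clamp = FALSE))
  f_big <- nmf_l21_fit(sim$X, solver_config(lam = 1.0, d = 2, seed = 5,
                                            clamp = FALSE))
  expect_lte(l21_norm(f_big$Y), l21_norm(f_small$Y) + 1e-8)
  resid <- function(f) l21_norm(unclass(sim$X) - f$A %*% f$Y)
  expect_gte(resid(f_big), resid(f_small) - 1e-8)
})

test_that("converged clamp-off solution matches the generic smoothed-objective oracle", {
  set.seed(20)
  n <- 4; cc <- 2; d <- 1
  A <- matrix(runif(n * d), n, d)
  X <- matrix(runif(n * cc) + 0.5, n, cc)
  eps <- 1e-8
  lam <- 0.3
  cfg <- solver_config(lam = lam, d = d, epsilon = eps, max_iter = 500,
                       tol = 1e-12, clamp = FALSE)
  fit <- nmf_l21_fit(expression_matrix(X), cfg, A = A)
  B <- cbind(A, lam * diag(n))
  expect_lt(norm(B %*% fit$U - X, "F"), 1e-6)
  U_star <- oracle_smoothed_fit(B, X, eps)
  expect_equal(smoothed_l21_for_test(fit$U, eps),
               smoothed_l21_for_test(U_star, eps), tolerance = 1e-6)
  expect_equal(fit$U, U_star, tolerance = 1e-3)
})
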