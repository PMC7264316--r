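# Symmetric normalization, the label-spreading iteration, its closed-form
# oracle, and two-sided relation scoring.

test_that("symmetric normalization rescales by degree and spares isolated nodes", {
  ids <- c("a", "b")
  S <- sym_sim(ids, edges("a", "b", 1))
  expect_equal(as.matrix(normalize_symmetric(S)), as.matrix(S))

  S2 <- methods::as(matrix(c(0, 2, 2, 0), 2, dimnames = list(ids, ids)),
                    "CsparseMatrix")
  expect_equal(as.matrix(normalize_symmetric(S2)),
               matrix(c(0, 1, 1, 0), 2, dimnames = list(ids, ids)))

  S3 <- sym_sim(c("a", "b", "iso"), edges("a", "b", 0.5))
  N <- as.matrix(normalize_symmetric(S3))
  expect_equal(N["iso", ], c(a = 0, b = 0, iso = 0))
  expect_false(anyNA(N))
})

test_that("propagation reaches the hand-computed two-node fixed point", {
  S <- methods::as(matrix(c(0, 1, 1, 0), 2), "CsparseMatrix")
  Y <- matrix(c(1, 0), ncol = 1)
  res <- propagate(normalize_symmetric(S), Y, alpha = 0.5, tol = 1e-12,
                   max_iter = 10000)
  expect_true(res$converged)
  expect_equal(as.numeric(res$scores), c(2 / 3, 1 / 3), tolerance = 1e-9)
  # and the closed form gives it exactly
  cf <- solve_closed_form(normalize_symmetric(S), Y, alpha = 0.5)
  expect_equal(as.numeric(cf), c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("restart-only and zero-label limits behave as stated", {
  set.seed(2)
  inst <- random_instance(10)
  res <- propagate(inst$S_norm, inst$Y, alpha = 0)
  expect_identical(res$iterations, 1L)
  expect_equal(res$scores, inst$Y, ignore_attr = TRUE)

  res0 <- propagate(inst$S_norm, inst$Y * 0, alpha = 0.5)
  expect_identical(res0$iterations, 1L)
  expect_true(res0$converged)
  expect_true(all(res0$scores == 0))
})

test_that("invalid alpha and shape mismatches raise errors", {
  inst <- random_instance(5)
  expect_error(propagate(inst$S_norm, inst$Y, alpha = 1), "alpha")
  expect_error(propagate(inst$S_norm, inst$Y, alpha = -0.1), "alpha")
  expect_error(propagate(inst$S_norm, matrix(0.5, 3, 1)), "Shape mismatch")
  expect_error(propagate(inst$S_norm, inst$Y + 5), "\\[0, 1\\]")
  expect_error(heterolp_config(alpha = 0), "alpha")
})

test_that("iterative propagation agrees with the closed-form oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    inst <- random_instance(n)
    for (alpha in c(0.1, 0.5, 0.9)) {
      res <- propagate(inst$S_norm, inst$Y, alpha = alpha, tol = 1e-8,
                       max_iter = 5000)
      expect_true(res$converged)
      oracle <- pmin(pmax(solve_closed_form(inst$S_norm, inst$Y, alpha), 0), 1)
      expect_lt(max(abs(res$scores - oracle)), 10 * 1e-8)
    }
  }
})

test_that("adding label mass never decreases any score", {
  set.seed(8)
  inst <- random_instance(15)
  base <- propagate(inst$S_norm, inst$Y, alpha = 0.6, tol = 1e-10)$scores
  Y2 <- inst$Y
  zero_cells <- which(Y2 == 0)
  Y2[sample(zero_cells, 3)] <- 0.8
  more <- propagate(inst$S_norm, Y2, alpha = 0.6, tol = 1e-10)$scores
  expect_true(all(more >= base - 1e-12))
})

test_that("known labels keep at least their restart mass", {
  set.seed(13)
  inst <- random_instance(20)
  alpha <- 0.7
  res <- propagate(inst$S_norm, inst$Y, alpha = alpha, tol = 1e-10)
  lab <- inst$Y > 0
  expect_true(all(res$scores[lab] >= (1 - alpha) * inst$Y[lab] - 1e-12))
})

test_that("two-sided relation scoring averages both propagation views", {
  net <- toy_network()
  cfg <- heterolp_config(alpha = 0.5, tol = 1e-10)
  fused <- fused_similarities(net, cfg)
  pr <- predict_relation(fused$drug, fused$disease, net$A_drug_disease, cfg)
  fr <- propagate(normalize_symmetric(fused$drug),
                  as.matrix(net$A_drug_disease), 0.5, 1e-10, 1000)
  fc <- propagate(normalize_symmetric(fused$disease),
                  t(as.matrix(net$A_drug_disease)), 0.5, 1e-10, 1000)
  expect_equal(pr$scores, pmin(pmax((fr$scores + t(fc$scores)) / 2, 0), 1),
               ignore_attr = TRUE)
  # zero labels in -> zero scores out
  pr0 <- predict_relation(fused$drug, fused$disease,
                          net$A_drug_disease * 0, cfg)
  expect_true(all(pr0$scores == 0))
})

test_that("similar drugs inherit association scores in a 3x2 toy", {
  # d1 is associated with x1; d2 is similar to d1; d3 is unrelated.
  net <- toy_network()
  fit <- heterolp(net, heterolp_config(alpha = 0.5, tol = 1e-10))
  sc <- fit$scores$drug_disease
  expect_gt(sc["d1", "x1"], sc["d2", "x1"])  # known pair ranks highest
  expect_gt(sc["d2", "x1"], sc["d3", "x1"])  # similarity beats no signal
  # brute-force check of the row-side view on the same instance
  fused <- fused_similarities(net, heterolp_config())
  oracle <- pmin(pmax((
    solve_closed_form(normalize_symmetric(fused$drug),
                      as.matrix(net$A_drug_disease), 0.5) +
      t(solve_closed_form(normalize_symmetric(fused$disease),
                          t(as.matrix(net$A_drug_disease)), 0.5))) / 2, 0), 1)
  expect_equal(as.matrix(sc), oracle, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("non-convergence is a warning with a partial result", {
  set.seed(21)
  inst <- random_instance(12)
  ids <- rownames(inst$S_norm)
  S <- methods::as(inst$S_norm, "CsparseMatrix")
  A <- methods::as(matrix(stats::runif(12 * 3) < 0.3, 12, 3) * 1,
                   "CsparseMatrix")
  dimnames(A) <- list(ids, c("c1", "c2", "c3"))
  Scol <- sym_sim(c("c1", "c2", "c3"), edges("c1", "c2", 0.5))
  cfg <- heterolp_config(alpha = 0.9, tol = 1e-14, max_iter = 3L)
  expect_warning(pr <- predict_relation(S, Scol, A, cfg), "did not converge")
  expect_false(pr$converged)
  expect_identical(dim(pr$scores), dim(as.matrix(A)))
})
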