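# Block-structured generator, hold-out machinery and rank AUC.

test_that("generation is deterministic in the seed", {
  spec <- synthetic_spec(n_drugs = 20, n_diseases = 15, n_targets = 10,
                         n_blocks = 3, seed = 7)
  a <- generate_network(spec)
  b <- generate_network(spec)
  expect_identical(as.matrix(a$S_drug), as.matrix(b$S_drug))
  expect_identical(as.matrix(a$A_drug_target), as.matrix(b$A_drug_target))
  c_ <- generate_network(synthetic_spec(n_drugs = 20, n_diseases = 15,
                                        n_targets = 10, n_blocks = 3,
                                        seed = 8))
  expect_false(identical(as.matrix(a$A_drug_target),
                         as.matrix(c_$A_drug_target)))
})

test_that("the noiseless limit is block-diagonal", {
  spec <- synthetic_spec(n_drugs = 12, n_diseases = 9, n_targets = 6,
                         n_blocks = 3, p_in = 1, p_out = 0, sim_noise = 0,
                         seed = 5)
  net <- generate_network(spec)
  blocks <- attr(net, "blocks")
  A <- as.matrix(net$A_drug_disease)
  same <- outer(blocks$drug, blocks$disease, "==")
  expect_true(all(A[same] == 1))
  expect_true(all(A[!same] == 0))
  S <- as.matrix(net$S_drug)
  same_d <- outer(blocks$drug, blocks$drug, "==")
  diag(same_d) <- FALSE
  expect_true(all(S[same_d] == 0.8))
  offdiag <- !diag(TRUE, nrow(S))
  expect_true(all(S[!same_d & offdiag] == 0))
})

test_that("association density matches the binomial expectation within 3 sigma", {
  spec <- synthetic_spec(seed = 2)  # 50 x 40 x 30, 5 blocks, 0.6 / 0.02
  net <- generate_network(spec)
  blocks <- attr(net, "blocks")
  same <- outer(blocks$drug, blocks$disease, "==")
  p_cell <- ifelse(same, spec$p_in, spec$p_out)
  expected <- sum(p_cell)
  sigma <- sqrt(sum(p_cell * (1 - p_cell)))
  observed <- Matrix::nnzero(net$A_drug_disease)
  expect_lt(abs(observed - expected), 3 * sigma)
})

test_that("generated networks pass the model validators unmodified", {
  for (seed in 1:3) {
    net <- generate_network(synthetic_spec(n_drugs = 15, n_diseases = 12,
                                           n_targets = 9, n_blocks = 3,
                                           seed = seed))
    expect_no_error(validate_network(net))
  }
  # partial overlap still aligns into a valid network
  net <- generate_network(synthetic_spec(n_drugs = 20, n_diseases = 16,
                                         n_targets = 12, n_blocks = 4,
                                         overlap_frac = 0.7, seed = 3))
  expect_no_error(validate_network(net))
  expect_lte(length(net$drugs), 20)
})

test_that("hold-out removes the exact count and reconstructs the source", {
  net <- generate_network(synthetic_spec(n_drugs = 20, n_diseases = 15,
                                         n_targets = 10, n_blocks = 3,
                                         seed = 1))
  nnz <- Matrix::nnzero(net$A_drug_disease)
  split <- make_holdout(net, "drug_disease", fraction = 0.1, seed = 4)
  expect_identical(nrow(split$held_out), as.integer(round(0.1 * nnz)))
  expect_identical(nrow(split$negatives), nrow(split$held_out))
  # train nonzeros + held-out pairs == source nonzeros
  key <- function(m) {
    t <- methods::as(methods::as(Matrix::drop0(m), "CsparseMatrix"),
                     "TsparseMatrix")
    paste(rownames(m)[t@i + 1], colnames(m)[t@j + 1])
  }
  src <- key(net$A_drug_disease)
  trn <- key(split$train$A_drug_disease)
  held <- paste(split$held_out$row_id, split$held_out$col_id)
  expect_setequal(c(trn, held), src)
  expect_length(intersect(trn, held), 0)
  # negatives are true zeros of the source layer
  negv <- net$A_drug_disease[cbind(match(split$negatives$row_id, net$drugs),
                                   match(split$negatives$col_id, net$diseases))]
  expect_true(all(negv == 0))
  # determinism and seed sensitivity
  split2 <- make_holdout(net, "drug_disease", fraction = 0.1, seed = 4)
  expect_identical(split$held_out, split2$held_out)
  split3 <- make_holdout(net, "drug_disease", fraction = 0.1, seed = 5)
  expect_false(identical(split$held_out, split3$held_out))
})

test_that("hold-out refuses layers with fewer than two links", {
  net <- toy_network()
  expect_error(make_holdout(net, "disease_target", fraction = 0.5),
               "fewer than 2")
  expect_error(make_holdout(net, "drug_disease", fraction = 1.5), "\\(0, 1\\)")
})

test_that("rank AUC handles perfect, reversed and random orderings", {
  net <- generate_network(synthetic_spec(n_drugs = 20, n_diseases = 15,
                                         n_targets = 10, n_blocks = 3,
                                         seed = 6))
  split <- make_holdout(net, "drug_disease", fraction = 0.2, seed = 2)
  A <- net$A_drug_disease
  perfect <- as.matrix(A)  # source weights: positives 1, negatives 0
  expect_equal(holdout_auc(perfect, split), 1.0)
  expect_equal(holdout_auc(1 - perfect, split), 0.0)
  expect_equal(holdout_auc(perfect * 0, split), 0.5)  # all ties

  # permutation null: random scores hover near 0.5
  set.seed(99)
  aucs <- replicate(50, {
    r <- matrix(stats::runif(length(A)), nrow(A), ncol(A),
                dimnames = dimnames(A))
    holdout_auc(r, split)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("spec invariants are enforced", {
  expect_error(synthetic_spec(p_in = 0.2, p_out = 0.5), "p_out < p_in")
  expect_error(synthetic_spec(overlap_frac = 0), "overlap_frac")
  expect_error(synthetic_spec(sim_noise = -0.1), "nonnegative")
})
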