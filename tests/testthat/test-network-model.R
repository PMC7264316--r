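# Loaders, validators, alignment and harmonization of the six-matrix model.

test_that("similarity edge lists are max-symmetrized with zero diagonal", {
  p <- write_tsv_lines(c("A\tB\t0.5"))
  m <- read_similarity(p, "drug")
  expect_identical(rownames(m), c("A", "B"))
  expect_equal(m["A", "B"], 0.5)
  expect_equal(m["B", "A"], 0.5)
  expect_equal(Matrix::diag(m), c(A = 0, B = 0))

  # self-edge dropped but the id stays in the catalog
  p <- write_tsv_lines(c("A\tA\t0.9"))
  m <- read_similarity(p, "drug")
  expect_identical(dim(m), c(1L, 1L))
  expect_equal(as.numeric(m), 0)

  # conflicting directions resolved by max
  p <- write_tsv_lines(c("A\tB\t0.3", "B\tA\t0.7"))
  m <- read_similarity(p, "drug")
  expect_equal(m["A", "B"], 0.7)
  expect_equal(m["B", "A"], 0.7)
})

test_that("similarity loader accepts an optional header and labelled matrices", {
  p <- write_tsv_lines(c("id1\tid2\tweight", "A\tB\t0.25"))
  m <- read_similarity(p, "target")
  expect_equal(m["A", "B"], 0.25)

  p <- write_tsv_lines(c("\tA\tB\tC",
                         "A\t0\t0.2\t0",
                         "B\t0.2\t0\t0.6",
                         "C\t0\t0.6\t0"))
  m <- read_similarity(p, "disease")
  expect_equal(m["B", "C"], 0.6)
  expect_true(Matrix::isSymmetric(m))
})

test_that("similarity loader reports malformed input with line numbers", {
  p <- write_tsv_lines(c("A\tB\t0.5", "B\tC\tnot_a_number"))
  expect_error(read_similarity(p, "drug"), "line 2")

  p <- write_tsv_lines(c("A\tB\t0.5", "B\tC\t1.5"))
  expect_error(read_similarity(p, "drug"), "outside \\[0, 1\\]")

  p <- write_tsv_lines(c("A\tB\t0.5", "A\tB\t0.6"))
  expect_error(read_similarity(p, "drug"), "[Dd]uplicate")

  p <- write_tsv_lines(c("\tA\tB", "A\t0\t0.3", "B\t0.5\t0"))
  expect_error(read_similarity(p, "drug"), "asymmetric|conflicting")
})

test_that("association loader defaults weights to 1 and tolerates empty files", {
  p <- write_tsv_lines(c("mitotane\tAdrenocortical carcinoma"))
  m <- read_association(p, "drug", "disease")
  expect_identical(dim(m), c(1L, 1L))
  expect_equal(as.numeric(m), 1.0)

  p <- write_tsv_lines(c("d1\tx1\t0.2", "d1\tx2\t0.8"))
  m <- read_association(p, "drug", "disease")
  expect_equal(Matrix::rowSums(m)[["d1"]], 1.0)

  p <- write_tsv_lines(character(0))
  expect_warning(m <- read_association(p, "drug", "disease"), "Empty")
  expect_identical(dim(m), c(0L, 0L))

  p <- write_tsv_lines(c("d1\tx1\t2.0"))
  expect_error(read_association(p, "drug", "disease"), "outside \\[0, 1\\]")
})

test_that("alignment takes catalog unions and zero-fills absent entries", {
  S <- sym_sim(c("A", "B"), edges("A", "B", 0.9))
  A_dd <- assoc(c("B", "C"), c("x1"), edges("B", "x1", 1, "C", "x1", 1))
  net <- align_network(S, empty_sim(), empty_sim(), A_dd, empty_assoc(),
                       empty_assoc())
  expect_identical(net$drugs, c("A", "B", "C"))
  expect_equal(net$S_drug["A", "B"], 0.9)
  expect_equal(Matrix::rowSums(net$S_drug)[["C"]], 0)
  expect_equal(net$A_drug_disease["C", "x1"], 1)
  expect_equal(Matrix::rowSums(net$A_drug_disease)[["A"]], 0)
})

test_that("alignment is idempotent and rejects cross-kind identifier reuse", {
  net <- toy_network()
  net2 <- align_network(net)
  expect_identical(lapply(net, as.matrix), lapply(net2, as.matrix))

  S <- sym_sim(c("A", "B"), edges("A", "B", 0.9))
  A_dd <- assoc("A", "A", edges("A", "A", 1))  # "A" as drug and disease
  expect_error(align_network(S, empty_sim(), empty_sim(), A_dd, empty_assoc(),
                             empty_assoc()),
               "'A'.*two different entity kinds")
})

test_that("harmonization keeps entities active in all three of their layers", {
  # drug activity: sim {A,B,C}, drug-disease {B,C,D}, drug-target {B,C}
  S_drug <- sym_sim(c("A", "B", "C", "D"),
                    edges("A", "B", 0.5, "B", "C", 0.5, "A", "C", 0.4))
  A_dd <- assoc(c("B", "C", "D"), c("x1", "x2"),
                edges("B", "x1", 1, "C", "x2", 1, "D", "x1", 1))
  A_dt <- assoc(c("B", "C"), c("t1", "t2"),
                edges("B", "t1", 1, "C", "t2", 1))
  S_dis <- sym_sim(c("x1", "x2"), edges("x1", "x2", 0.3))
  S_tgt <- sym_sim(c("t1", "t2"))
  A_xt <- assoc(c("x1", "x2"), c("t1", "t2"),
                edges("x1", "t1", 1, "x2", "t2", 1))
  net <- align_network(S_drug, S_dis, S_tgt, A_dd, A_dt, A_xt)
  # targets have an empty similarity layer -> no common targets
  expect_error(harmonize_common_entities(net), "target.*inapplicable")

  S_tgt <- sym_sim(c("t1", "t2"), edges("t1", "t2", 0.2))
  net <- align_network(S_drug, S_dis, S_tgt, A_dd, A_dt, A_xt)
  h <- harmonize_common_entities(net)
  expect_identical(h$drugs, c("B", "C"))
  expect_identical(h$diseases, c("x1", "x2"))
  expect_identical(h$targets, c("t1", "t2"))

  # idempotent; catalogs shrink, never grow; no new nonzeros appear
  h2 <- harmonize_common_entities(h)
  expect_identical(lapply(h, as.matrix), lapply(h2, as.matrix))
  expect_true(all(h$drugs %in% net$drugs))
  expect_true(Matrix::nnzero(h$A_drug_disease) <=
                Matrix::nnzero(net$A_drug_disease))
  expect_equal(sum(as.matrix(h$A_drug_disease) >
                     as.matrix(net$A_drug_disease[h$drugs, h$diseases])), 0)
})

test_that("identity harmonization leaves a fully-consistent network unchanged", {
  net <- generate_network(synthetic_spec(n_drugs = 12, n_diseases = 10,
                                         n_targets = 8, n_blocks = 2,
                                         p_in = 0.9, p_out = 0.2, seed = 4))
  h <- harmonize_common_entities(net)
  expect_identical(h$drugs, net$drugs)
  expect_identical(as.matrix(h$A_drug_disease), as.matrix(net$A_drug_disease))
})

test_that("edge-list TSVs round-trip bit-identically", {
  set.seed(11)
  net <- generate_network(synthetic_spec(n_drugs = 8, n_diseases = 6,
                                         n_targets = 5, n_blocks = 2,
                                         sim_noise = 0.13, seed = 9))
  dir <- tempfile()
  write_network(net, dir)
  net2 <- read_network_dir(dir)
  dir2 <- tempfile()
  write_network(net2, dir2)
  for (f in network_filenames()) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
  expect_identical(as.matrix(net$S_drug), as.matrix(net2$S_drug))
  expect_identical(as.matrix(net$A_disease_target),
                   as.matrix(net2$A_disease_target))
})

test_that("network validators catch broken invariants", {
  net <- toy_network()
  bad <- net
  bad$S_drug[1, 2] <- 0.3  # breaks symmetry
  expect_error(validate_network(bad), "not symmetric")
  bad <- net
  bad$drugs <- c(bad$drugs[-1], bad$drugs[1])  # catalog out of step
  expect_error(validate_network(bad), "not indexed")
})
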