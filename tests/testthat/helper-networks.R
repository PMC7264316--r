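# Fixture builders shared across test files. Everything is generated in code;
# TSVs are written to tempdirs on demand.

sp <- function(i, j, x, dims, rn, cn) {
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = dims,
                       dimnames = list(rn, cn))
}

# symmetric similarity matrix from an upper-triangle edge list
sym_sim <- function(ids, edges = NULL) {
  n <- length(ids)
  m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, n), dimnames = list(ids, ids))
  if (!is.null(edges) && nrow(edges) > 0) {
    i <- match(edges[[1]], ids)
    j <- match(edges[[2]], ids)
    m <- sp(c(i, j), c(j, i), rep(edges[[3]], 2), c(n, n), ids, ids)
  }
  methods::as(m, "CsparseMatrix")
}

assoc <- function(rows, cols, edges = NULL) {
  m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(length(rows), length(cols)),
                            dimnames = list(rows, cols))
  if (!is.null(edges) && nrow(edges) > 0) {
    m <- sp(match(edges[[1]], rows), match(edges[[2]], cols), edges[[3]],
            c(length(rows), length(cols)), rows, cols)
  }
  methods::as(m, "CsparseMatrix")
}

edges <- function(...) {
  df <- as.data.frame(matrix(c(...), ncol = 3, byrow = TRUE),
                      stringsAsFactors = FALSE)
  df[[3]] <- as.numeric(df[[3]])
  df
}

# a small fully-specified network: 3 drugs, 2 diseases, 2 targets
toy_network <- function() {
  align_network(
    S_drug = sym_sim(c("d1", "d2", "d3"), edges("d1", "d2", 0.9)),
    S_disease = sym_sim(c("x1", "x2"), edges("x1", "x2", 0.4)),
    S_target = sym_sim(c("t1", "t2"), edges("t1", "t2", 0.5)),
    A_drug_disease = assoc(c("d1", "d2", "d3"), c("x1", "x2"),
                           edges("d1", "x1", 1)),
    A_drug_target = assoc(c("d1", "d2", "d3"), c("t1", "t2"),
                          edges("d1", "t1", 1, "d3", "t2", 1)),
    A_disease_target = assoc(c("x1", "x2"), c("t1", "t2"),
                             edges("x1", "t1", 1))
  )
}

# random symmetric normalized operator + labels, for oracle/property tests
random_instance <- function(n, n_labels = 2, density = 0.3) {
  m <- matrix(0, n, n)
  up <- upper.tri(m)
  vals <- stats::runif(sum(up))
  vals[stats::runif(sum(up)) > density] <- 0
  m[up] <- vals
  m <- m + t(m)
  ids <- sprintf("n%02d", seq_len(n))
  dimnames(m) <- list(ids, ids)
  Y <- matrix(stats::runif(n * n_labels), n, n_labels)
  Y[stats::runif(n * n_labels) > 0.3] <- 0
  list(S_norm = normalize_symmetric(methods::as(m, "CsparseMatrix")), Y = Y)
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
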