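# TSV readers/writers for the six-matrix network model.
#
# Two on-disk forms are accepted: a 2/3-column edge list (id1, id2, weight;
# header optional) and, for similarities, a labelled square matrix whose first
# row/column carry the ids. Everything is UTF-8, tab-separated.

# Read non-empty lines, keeping original line numbers for error messages.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path))
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  raw <- sub("\r$", "", raw)
  keep <- nzchar(trimws(raw))
  list(fields = strsplit(raw[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

is_numeric_str <- function(x) {
  suppressWarnings(!is.na(as.numeric(x)))
}

# Parse an edge list with `ncols` id columns + optional weight column.
# Returns a tibble (id1, id2, weight, lineno) with header row removed.
parse_edge_list <- function(lines, default_weight = NA_real_, what = "edge") {
  fields <- lines$fields
  lineno <- lines$lineno
  n <- vapply(fields, length, integer(1))
  bad <- which(!(n %in% c(2L, 3L)))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Malformed %s row at line %d: expected 2 or 3 tab-separated columns, got %d.",
      what, lineno[bad[1]], n[bad[1]]))
  }
  id1 <- vapply(fields, `[`, character(1), 1L)
  id2 <- vapply(fields, `[`, character(1), 2L)
  w_str <- vapply(fields, function(f) if (length(f) >= 3L) f[3L] else NA_character_,
                  character(1))
  # Optional header: first row whose weight column does not parse as a number,
  # or a weightless first row made of column names.
  if (length(id1) > 0) {
    first_w <- w_str[1]
    header <- (!is.na(first_w) && !is_numeric_str(first_w)) ||
      (is.na(first_w) && tolower(id1[1]) %in% c("id1", "id", "source", "row_id"))
    if (header) {
      id1 <- id1[-1]; id2 <- id2[-1]; w_str <- w_str[-1]; lineno <- lineno[-1]
    }
  }
  w <- ifelse(is.na(w_str), default_weight, suppressWarnings(as.numeric(w_str)))
  bad <- which(!is.na(w_str) & !is_numeric_str(w_str))
  if (length(bad) > 0) {
    rlang::abort(sprintf("Malformed %s row at line %d: weight '%s' is not numeric.",
                         what, lineno[bad[1]], w_str[bad[1]]))
  }
  bad <- which(is.na(w))
  if (length(bad) > 0) {
    rlang::abort(sprintf("Malformed %s row at line %d: missing weight.",
                         what, lineno[bad[1]]))
  }
  bad <- which(w < 0 | w > 1)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Weight %g at line %d is outside [0, 1].",
                         w[bad[1]], lineno[bad[1]]))
  }
  if (any(!nzchar(id1)) || any(!nzchar(id2))) {
    bad <- which(!nzchar(id1) | !nzchar(id2))[1]
    rlang::abort(sprintf("Empty identifier at line %d.", lineno[bad]))
  }
  tibble::tibble(id1 = id1, id2 = id2, weight = w, lineno = lineno)
}

# Error on the same ordered cell appearing twice with different weights;
# silently dedupe exact repeats.
dedupe_cells <- function(df) {
  key <- paste(df$id1, df$id2, sep = "\r")
  split_w <- split(df$weight, key)
  conflict <- vapply(split_w, function(v) max(v) - min(v) > 0, logical(1))
  if (any(conflict)) {
    k <- strsplit(names(split_w)[which(conflict)[1]], "\r", fixed = TRUE)[[1]]
    rlang::abort(sprintf(
      "Duplicate conflicting cells for pair ('%s', '%s'): weights differ.",
      k[1], k[2]))
  }
  df[!duplicated(key), , drop = FALSE]
}

#' Load a similarity matrix from TSV
#'
#' Accepts either a 3-column edge list (`id1 id2 weight`, header optional) or
#' a labelled square matrix (first row/column are identifiers); the form is
#' auto-detected from the column count. Edge lists are symmetrised by taking
#' the maximum of the two directed weights, self-edges are dropped, and the
#' catalog follows first appearance in the file. The diagonal is always zero
#' after loading: propagation ignores self-similarity.
#'
#' @param path Path to a TSV file.
#' @param kind Entity kind the matrix describes: `"drug"`, `"disease"` or
#'   `"target"`. Stored as an attribute for later validation.
#' @return A sparse symmetric `dgCMatrix` with identical row/column names,
#'   entries in \[0, 1\] and zero diagonal.
#' @seealso [read_association()], [align_network()]
#' @export
read_similarity <- function(path, kind = c("drug", "disease", "target")) {
  kind <- match.arg(kind)
  lines <- read_tsv_lines(path)
  if (length(lines$fields) == 0) {
    rlang::warn(paste0("Empty similarity file: ", path))
    m <- empty_sparse(character(0), character(0))
    attr(m, "kind") <- kind
    return(m)
  }
  nf <- vapply(lines$fields, length, integer(1))
  # labelled-matrix form: more than three columns, or a corner cell left
  # empty in the header row (required to disambiguate 2 x 2 matrices)
  labelled <- max(nf) > 3L || !nzchar(lines$fields[[1]][1])
  if (labelled) {
    m <- parse_labelled_matrix(lines, path)
  } else {
    df <- parse_edge_list(lines, what = "similarity")
    ids <- unique(as.vector(rbind(df$id1, df$id2)))
    df <- dedupe_cells(df)
    i <- match(df$id1, ids)
    j <- match(df$id2, ids)
    # max-symmetrise the two directions, drop the diagonal
    all_i <- c(i, j); all_j <- c(j, i); all_w <- c(df$weight, df$weight)
    off <- all_i != all_j
    m <- empty_sparse(ids, ids)
    if (any(off)) {
      key <- paste(all_i[off], all_j[off])
      w <- vapply(split(all_w[off], key), max, numeric(1))
      ij <- do.call(rbind, lapply(strsplit(names(w), " ", fixed = TRUE),
                                  as.integer))
      m <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = unname(w),
                                dims = c(length(ids), length(ids)),
                                dimnames = list(ids, ids))
    }
  }
  m <- as_dgc(Matrix::drop0(m))
  validate_similarity(m, where = path)
  attr(m, "kind") <- kind
  m
}

parse_labelled_matrix <- function(lines, path) {
  fields <- lines$fields
  header <- fields[[1]]
  body <- fields[-1]
  ncols <- length(body[[1]])
  col_ids <- if (length(header) == ncols) header[-1] else header
  if (length(col_ids) != ncols - 1L) {
    rlang::abort(sprintf("Malformed matrix header in %s: %d column ids for %d value columns.",
                         path, length(col_ids), ncols - 1L))
  }
  bad <- which(vapply(body, length, integer(1)) != ncols)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Malformed matrix row at line %d: ragged column count.",
                         lines$lineno[-1][bad[1]]))
  }
  row_ids <- vapply(body, `[`, character(1), 1L)
  vals <- t(vapply(body, function(f) suppressWarnings(as.numeric(f[-1])),
                   numeric(ncols - 1L)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    rlang::abort(sprintf("Malformed matrix row at line %d: non-numeric cell.",
                         lines$lineno[-1][bad]))
  }
  if (any(vals < 0 | vals > 1)) {
    rlang::abort(sprintf("Matrix in %s has entries outside [0, 1].", path))
  }
  if (!setequal(row_ids, col_ids) || length(row_ids) != length(col_ids)) {
    rlang::abort(sprintf("Labelled matrix in %s is not square over one id set.", path))
  }
  vals <- vals[, match(row_ids, col_ids), drop = FALSE]
  dimnames(vals) <- list(row_ids, row_ids)
  asym <- abs(vals - t(vals))
  if (max(asym) > 1e-9) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "Duplicate conflicting cells: matrix is asymmetric at ('%s', '%s').",
      row_ids[ij[1]], row_ids[ij[2]]))
  }
  diag(vals) <- 0
  methods::as(vals, "CsparseMatrix")
}

#' Load an association matrix from TSV
#'
#' Expects an edge list `row_id col_id [weight]`; a missing third column means
#' weight 1.0 (a plain known association). Pairs absent from the file are 0.
#' An empty file yields a 0 x 0 matrix with a warning.
#'
#' @param path Path to a TSV file.
#' @param row_kind,col_kind Entity kinds of the rows and columns, e.g.
#'   `"drug"` and `"disease"`.
#' @return A sparse `dgCMatrix` with row/column names in order of first
#'   appearance and entries in \[0, 1\].
#' @export
read_association <- function(path,
                             row_kind = c("drug", "disease", "target"),
                             col_kind = c("drug", "disease", "target")) {
  row_kind <- match.arg(row_kind)
  col_kind <- match.arg(col_kind)
  lines <- read_tsv_lines(path)
  if (length(lines$fields) == 0) {
    rlang::warn(paste0("Empty association file: ", path))
    m <- empty_sparse(character(0), character(0))
  } else {
    df <- parse_edge_list(lines, default_weight = 1.0, what = "association")
    df <- dedupe_cells(df)
    rows <- unique(df$id1)
    cols <- unique(df$id2)
    m <- Matrix::sparseMatrix(i = match(df$id1, rows), j = match(df$id2, cols),
                              x = df$weight,
                              dims = c(length(rows), length(cols)),
                              dimnames = list(rows, cols))
    m <- methods::as(Matrix::drop0(m), "CsparseMatrix")
  }
  attr(m, "row_kind") <- row_kind
  attr(m, "col_kind") <- col_kind
  m
}

#' Write a matrix as a TSV edge list
#'
#' Nonzero entries only; symmetric matrices are written as their upper
#' triangle. Weights are printed with 17 significant digits so a
#' load -> write -> load round trip reproduces the matrix bit-identically.
#'
#' @param m A sparse or dense matrix with dimnames.
#' @param path Output path.
#' @param symmetric Write only the upper triangle (for similarity matrices).
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(m, path, symmetric = FALSE) {
  m <- methods::as(Matrix::drop0(as_dgc(m)), "TsparseMatrix")
  i <- m@i + 1L
  j <- m@j + 1L
  x <- m@x
  if (symmetric) {
    keep <- i < j
    i <- i[keep]; j <- j[keep]; x <- x[keep]
  }
  ord <- order(i, j)
  lines <- c("id1\tid2\tweight",
             sprintf("%s\t%s\t%s", rownames(m)[i[ord]], colnames(m)[j[ord]],
                     sprintf("%.17g", x[ord])))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Canonical file names of a network directory
#'
#' The six TSV names that [write_network()], [read_network_dir()] and the CLI
#' agree on.
#' @return A named character vector.
#' @export
network_filenames <- function() {
  c(S_drug = "drug_similarity.tsv",
    S_disease = "disease_similarity.tsv",
    S_target = "target_similarity.tsv",
    A_drug_disease = "drug_disease.tsv",
    A_drug_target = "drug_target.tsv",
    A_disease_target = "disease_target.tsv")
}

#' Write a heterogeneous network as six TSV edge lists
#'
#' @param network A `hetero_network`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  stopifnot(inherits(network, "hetero_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fn <- network_filenames()
  write_edgelist(network$S_drug, file.path(dir, fn[["S_drug"]]), symmetric = TRUE)
  write_edgelist(network$S_disease, file.path(dir, fn[["S_disease"]]), symmetric = TRUE)
  write_edgelist(network$S_target, file.path(dir, fn[["S_target"]]), symmetric = TRUE)
  write_edgelist(network$A_drug_disease, file.path(dir, fn[["A_drug_disease"]]))
  write_edgelist(network$A_drug_target, file.path(dir, fn[["A_drug_target"]]))
  write_edgelist(network$A_disease_target, file.path(dir, fn[["A_disease_target"]]))
  invisible(dir)
}

#' Read the six network TSVs from a directory and align them
#'
#' Looks for the canonical file names (`drug_similarity.tsv`,
#' `disease_similarity.tsv`, `target_similarity.tsv`, `drug_disease.tsv`,
#' `drug_target.tsv`, `disease_target.tsv`) and returns the aligned network.
#'
#' @param dir Directory containing the six TSV files.
#' @return A `hetero_network`.
#' @export
read_network_dir <- function(dir) {
  fn <- network_filenames()
  paths <- file.path(dir, fn)
  missing <- !file.exists(paths)
  if (any(missing)) {
    rlang::abort(paste0("Missing network file(s): ",
                        paste(fn[missing], collapse = ", "), " in ", dir))
  }
  align_network(
    S_drug = read_similarity(paths[[1]], "drug"),
    S_disease = read_similarity(paths[[2]], "disease"),
    S_target = read_similarity(paths[[3]], "target"),
    A_drug_disease = read_association(paths[[4]], "drug", "disease"),
    A_drug_target = read_association(paths[[5]], "drug", "target"),
    A_disease_target = read_association(paths[[6]], "disease", "target")
  )
}
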