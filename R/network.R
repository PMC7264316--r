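# The heterogeneous network container: three entity catalogs, three
# homogeneous similarity layers, three bipartite association layers.
# Catalogs are character vectors; matrices are sparse dgCMatrix whose
# dimnames ARE the coordinate system.

# general (non-symmetric-storage) column-sparse form; triplet helpers rely on
# both triangles being materialized
as_dgc <- function(m) {
  methods::as(methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix"),
              "dMatrix")
}

empty_sparse <- function(rows, cols) {
  Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                       dims = c(length(rows), length(cols)),
                       dimnames = list(rows, cols))
}

validate_catalog <- function(ids, kind = "entity") {
  if (any(!nzchar(ids))) {
    rlang::abort(sprintf("%s catalog contains empty identifiers.", kind))
  }
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("%s catalog contains duplicate identifier '%s'.",
                         kind, ids[duplicated(ids)][1]))
  }
  invisible(ids)
}

validate_similarity <- function(m, where = "similarity matrix") {
  if (nrow(m) != ncol(m)) {
    rlang::abort(sprintf("%s: matrix is not square.", where))
  }
  if (!identical(rownames(m), colnames(m))) {
    rlang::abort(sprintf("%s: row and column ids differ.", where))
  }
  validate_catalog(rownames(m), where)
  if (length(m@x) > 0 && (min(m@x) < 0 || max(m@x) > 1)) {
    rlang::abort(sprintf("%s: entries outside [0, 1].", where))
  }
  if (nrow(m) > 0) {
    if (max(abs(m - Matrix::t(m))) > 1e-9) {
      rlang::abort(sprintf("%s: matrix is not symmetric.", where))
    }
    if (any(Matrix::diag(m) != 0)) {
      rlang::abort(sprintf("%s: nonzero diagonal (self-similarity must be dropped).",
                           where))
    }
  }
  invisible(m)
}

validate_association <- function(m, where = "association matrix") {
  validate_catalog(rownames(m), where)
  validate_catalog(colnames(m), where)
  if (length(m@x) > 0 && (min(m@x) < 0 || max(m@x) > 1)) {
    rlang::abort(sprintf("%s: entries outside [0, 1].", where))
  }
  invisible(m)
}

# Zero-filled re-indexing of a matrix onto target row/col catalogs.
expand_matrix <- function(m, rows, cols) {
  out <- empty_sparse(rows, cols)
  if (!is.null(m) && nrow(m) > 0 && ncol(m) > 0) {
    t <- methods::as(as_dgc(m), "TsparseMatrix")
    ri <- match(rownames(m)[t@i + 1L], rows)
    ci <- match(colnames(m)[t@j + 1L], cols)
    keep <- !is.na(ri) & !is.na(ci)
    if (any(keep)) {
      out <- Matrix::sparseMatrix(i = ri[keep], j = ci[keep], x = t@x[keep],
                                  dims = c(length(rows), length(cols)),
                                  dimnames = list(rows, cols))
    }
  }
  methods::as(out, "CsparseMatrix")
}

new_hetero_network <- function(drugs, diseases, targets,
                               S_drug, S_disease, S_target,
                               A_drug_disease, A_drug_target, A_disease_target) {
  structure(
    list(drugs = drugs, diseases = diseases, targets = targets,
         S_drug = S_drug, S_disease = S_disease, S_target = S_target,
         A_drug_disease = A_drug_disease, A_drug_target = A_drug_target,
         A_disease_target = A_disease_target),
    class = "hetero_network"
  )
}

#' Validate a heterogeneous network
#'
#' Checks the invariants of the data model: catalogs free of duplicates and
#' empty strings; similarity layers square, symmetric (to 1e-9), zero-diagonal
#' and in \[0, 1\]; association layers in \[0, 1\]; every matrix indexed
#' exactly by the network's catalogs.
#'
#' @param network A `hetero_network`.
#' @return The network, invisibly; errors describe the first violation found.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "hetero_network"))
  validate_catalog(network$drugs, "drug")
  validate_catalog(network$diseases, "disease")
  validate_catalog(network$targets, "target")
  validate_similarity(network$S_drug, "drug similarity")
  validate_similarity(network$S_disease, "disease similarity")
  validate_similarity(network$S_target, "target similarity")
  validate_association(network$A_drug_disease, "drug-disease associations")
  validate_association(network$A_drug_target, "drug-target associations")
  validate_association(network$A_disease_target, "disease-target associations")
  expect_names <- list(
    S_drug = list(network$drugs, network$drugs),
    S_disease = list(network$diseases, network$diseases),
    S_target = list(network$targets, network$targets),
    A_drug_disease = list(network$drugs, network$diseases),
    A_drug_target = list(network$drugs, network$targets),
    A_disease_target = list(network$diseases, network$targets)
  )
  for (nm in names(expect_names)) {
    want <- expect_names[[nm]]
    m <- network[[nm]]
    if (!identical(rownames(m), want[[1]]) || !identical(colnames(m), want[[2]])) {
      rlang::abort(sprintf("Layer %s is not indexed by the network catalogs.", nm))
    }
  }
  invisible(network)
}

#' Integrate six matrices into one heterogeneous network
#'
#' Each entity catalog becomes the union of the identifiers seen in any of the
#' three matrices mentioning that type (in order of first appearance:
#' similarity layer first, then the association layers); matrices are
#' re-indexed onto the union catalogs with absent rows/columns zero-filled.
#' Unlike the DT-Hybrid baseline, label propagation accepts layers whose id
#' lists only partially overlap.
#'
#' @param S_drug,S_disease,S_target Similarity matrices from
#'   [read_similarity()] (or any named sparse symmetric matrix). Alternatively
#'   pass an existing `hetero_network` as the single first argument to
#'   re-align it.
#' @param A_drug_disease,A_drug_target,A_disease_target Association matrices
#'   from [read_association()].
#' @return A validated `hetero_network`.
#' @examples
#' S <- Matrix::sparseMatrix(i = 1, j = 2, x = 0.9, dims = c(2, 2),
#'                           dimnames = list(c("d1", "d2"), c("d1", "d2")))
#' S <- S + Matrix::t(S)
#' A <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1),
#'                           dimnames = list("d3", "x1"))
#' net <- align_network(S, empty_sim(), empty_sim(), A, empty_assoc(),
#'                      empty_assoc())
#' net$drugs  # union: d1 d2 d3
#' @export
align_network <- function(S_drug, S_disease = NULL, S_target = NULL,
                          A_drug_disease = NULL, A_drug_target = NULL,
                          A_disease_target = NULL) {
  if (inherits(S_drug, "hetero_network")) {
    net <- S_drug
    return(align_network(net$S_drug, net$S_disease, net$S_target,
                         net$A_drug_disease, net$A_drug_target,
                         net$A_disease_target))
  }
  nm <- function(m, which) if (is.null(m)) character(0) else dimnames(m)[[which]]
  drugs <- unique(c(nm(S_drug, 1), nm(A_drug_disease, 1), nm(A_drug_target, 1)))
  diseases <- unique(c(nm(S_disease, 1), nm(A_drug_disease, 2),
                       nm(A_disease_target, 1)))
  targets <- unique(c(nm(S_target, 1), nm(A_drug_target, 2),
                      nm(A_disease_target, 2)))
  clash <- c(intersect(drugs, diseases), intersect(drugs, targets),
             intersect(diseases, targets))
  if (length(clash) > 0) {
    rlang::abort(sprintf(
      "Identifier '%s' appears under two different entity kinds; kinds must be disjoint.",
      clash[1]))
  }
  net <- new_hetero_network(
    drugs, diseases, targets,
    S_drug = expand_matrix(S_drug, drugs, drugs),
    S_disease = expand_matrix(S_disease, diseases, diseases),
    S_target = expand_matrix(S_target, targets, targets),
    A_drug_disease = expand_matrix(A_drug_disease, drugs, diseases),
    A_drug_target = expand_matrix(A_drug_target, drugs, targets),
    A_disease_target = expand_matrix(A_disease_target, diseases, targets)
  )
  validate_network(net)
}

#' Empty similarity / association placeholders
#'
#' Convenience constructors for building toy networks where some layer is
#' absent; [align_network()] zero-fills them onto the union catalogs.
#' @return A 0 x 0 sparse matrix.
#' @export
empty_sim <- function() empty_sparse(character(0), character(0))

#' @rdname empty_sim
#' @export
empty_assoc <- function() empty_sparse(character(0), character(0))

# ids with >= 1 nonzero entry in a layer, along the given margin;
# the similarity diagonal is already zero so off-diagonal activity is implied.
active_ids <- function(m, margin) {
  deg <- if (margin == 1) Matrix::rowSums(m != 0) else Matrix::colSums(m != 0)
  dimnames(m)[[margin]][deg > 0]
}

#' Restrict a network to entities present in every layer of their type
#'
#' Degree-tuned bipartite projection (the DT-Hybrid baseline) is undefined for
#' nodes that are missing from any sub-network touching their type, so it
#' requires a "justified" dataset: each drug must be active (have at least one
#' nonzero entry) in the drug similarity layer and in both drug association
#' layers, and likewise for diseases and targets. This function intersects the
#' active id sets and restricts all six matrices accordingly, preserving
#' catalog order. Because restricting one catalog can deactivate entities of
#' another type, the step is iterated until the catalogs are stable, so the
#' operation is idempotent.
#'
#' @param network An aligned `hetero_network`.
#' @return The restricted `hetero_network`. Errors if any intersection is
#'   empty, in which case DT-Hybrid is inapplicable to the dataset.
#' @export
harmonize_common_entities <- function(network) {
  validate_network(network)
  net <- network
  # Restricting one catalog can deactivate entities of another, so iterate
  # the intersect-and-restrict step to its fixed point; this is what makes
  # harmonization idempotent.
  repeat {
    common <- list(
      drug = Reduce(intersect, list(active_ids(net$S_drug, 1),
                                    active_ids(net$A_drug_disease, 1),
                                    active_ids(net$A_drug_target, 1))),
      disease = Reduce(intersect, list(active_ids(net$S_disease, 1),
                                       active_ids(net$A_drug_disease, 2),
                                       active_ids(net$A_disease_target, 1))),
      target = Reduce(intersect, list(active_ids(net$S_target, 1),
                                      active_ids(net$A_drug_target, 2),
                                      active_ids(net$A_disease_target, 2)))
    )
    for (k in names(common)) {
      if (length(common[[k]]) == 0) {
        rlang::abort(sprintf(
          "No %s is active in all three of its layers: DT-Hybrid is inapplicable to this dataset.",
          k))
      }
    }
    drugs <- net$drugs[net$drugs %in% common$drug]
    diseases <- net$diseases[net$diseases %in% common$disease]
    targets <- net$targets[net$targets %in% common$target]
    stable <- identical(drugs, net$drugs) && identical(diseases, net$diseases) &&
      identical(targets, net$targets)
    net <- new_hetero_network(
      drugs, diseases, targets,
      S_drug = expand_matrix(net$S_drug, drugs, drugs),
      S_disease = expand_matrix(net$S_disease, diseases, diseases),
      S_target = expand_matrix(net$S_target, targets, targets),
      A_drug_disease = expand_matrix(net$A_drug_disease, drugs, diseases),
      A_drug_target = expand_matrix(net$A_drug_target, drugs, targets),
      A_disease_target = expand_matrix(net$A_disease_target, diseases, targets)
    )
    if (stable) break
  }
  validate_network(net)
}

#' @method print hetero_network
#' @export
print.hetero_network <- function(x, ...) {
  dens <- function(m) {
    if (length(m) == 0) return(0)
    Matrix::nnzero(m) / length(m)
  }
  cat("<hetero_network>\n")
  cat(sprintf("  drugs: %d, diseases: %d, targets: %d\n",
              length(x$drugs), length(x$diseases), length(x$targets)))
  cat(sprintf("  similarity density  drug %.3g | disease %.3g | target %.3g\n",
              dens(x$S_drug), dens(x$S_disease), dens(x$S_target)))
  cat(sprintf("  association density drug-dis %.3g | drug-tgt %.3g | dis-tgt %.3g\n",
              dens(x$A_drug_disease), dens(x$A_drug_target),
              dens(x$A_disease_target)))
  invisible(x)
}
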