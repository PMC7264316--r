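# Projection: topological similarity of same-type nodes from a bipartite
# layer, and fusion with the intrinsic similarity layer.

#' Topological similarity from a bipartite association layer
#'
#' Scores how alike two same-type nodes are from the way they connect to the
#' opposite side of a bipartite layer, using the weighted Jaccard index of
#' their neighbour profiles:
#' \deqn{T_{ij} = \frac{\sum_k \min(a_{ik}, a_{jk})}{\sum_k \max(a_{ik}, a_{jk})}}
#' which reduces to the set Jaccard index on binary data and is bounded in
#' \[0, 1\]. Pairs where both profiles are all-zero score 0, and the diagonal
#' is set to 0.
#'
#' @param A An association matrix (nonnegative).
#' @param side Which side's profiles to compare: `"rows"` or `"cols"` of `A`.
#' @return A sparse symmetric similarity matrix over the chosen side's
#'   catalog, zero diagonal, entries in \[0, 1\].
#' @examples
#' A <- Matrix::sparseMatrix(i = c(1, 1, 1, 2, 2, 2), j = c(1, 2, 3, 1, 2, 4),
#'                           x = 1, dims = c(2, 4),
#'                           dimnames = list(c("u", "v"), c("a", "b", "c", "d")))
#' topological_similarity(A, "rows")["u", "v"]  # 2 shared / 4 in union = 0.5
#' @export
topological_similarity <- function(A, side = c("rows", "cols")) {
  side <- match.arg(side)
  M <- as.matrix(A)
  if (side == "cols") M <- t(M)
  ids <- rownames(M)
  n <- nrow(M)
  if (n == 0) return(empty_sparse(ids, ids))
  rs <- rowSums(M)
  smin <- matrix(0, n, n)
  tM <- t(M)
  for (i in seq_len(n)) {
    # column k of tM is node k's profile; recycle node i's profile down it
    smin[i, ] <- colSums(pmin(tM, M[i, ]))
  }
  smax <- outer(rs, rs, "+") - smin
  T_ <- ifelse(smax > 0, smin / smax, 0)
  diag(T_) <- 0
  dimnames(T_) <- list(ids, ids)
  methods::as(methods::as(T_, "CsparseMatrix"), "generalMatrix")
}

# element-wise max of two sparse nonnegative matrices (triplet union)
sparse_pmax <- function(a, b) {
  ta <- methods::as(as_dgc(a), "TsparseMatrix")
  tb <- methods::as(as_dgc(b), "TsparseMatrix")
  df <- rbind(data.frame(i = ta@i, j = ta@j, x = ta@x),
              data.frame(i = tb@i, j = tb@j, x = tb@x))
  if (nrow(df) == 0) return(empty_sparse(rownames(a), colnames(a)))
  key <- paste(df$i, df$j)
  x <- vapply(split(df$x, key), max, numeric(1))
  ij <- do.call(rbind, lapply(strsplit(names(x), " ", fixed = TRUE), as.integer))
  Matrix::sparseMatrix(i = ij[, 1] + 1L, j = ij[, 2] + 1L, x = unname(x),
                       dims = dim(a), dimnames = dimnames(a))
}

#' Fuse intrinsic and topological similarities
#'
#' Integrates the intrinsic (input) similarity of an entity type with the two
#' topological similarities projected from its bipartite layers. The default
#' is the element-wise maximum, which stays in \[0, 1\] without extra
#' parameters and keeps the strongest evidence from any layer; `"mean"`
#' averages the three layers instead.
#'
#' @param intrinsic,topo1,topo2 Square symmetric matrices over the same
#'   catalog (identical dimnames).
#' @param method `"max"` (default) or `"mean"`.
#' @return A sparse symmetric fused similarity matrix, zero diagonal, entries
#'   in \[0, 1\], with a `provenance` attribute naming the contributing layers.
#' @export
fuse_similarities <- function(intrinsic, topo1, topo2,
                              method = c("max", "mean")) {
  method <- match.arg(method)
  mats <- list(intrinsic = intrinsic, topo1 = topo1, topo2 = topo2)
  ref <- dimnames(intrinsic)
  for (nm in names(mats)) {
    if (!identical(dim(mats[[nm]]), dim(intrinsic)) ||
        !identical(dimnames(mats[[nm]]), ref)) {
      rlang::abort(sprintf(
        "Catalog mismatch: '%s' is not indexed like the intrinsic matrix.", nm))
    }
  }
  out <- if (method == "max") {
    sparse_pmax(sparse_pmax(intrinsic, topo1), topo2)
  } else {
    (intrinsic + topo1 + topo2) / 3
  }
  out <- as_dgc(Matrix::drop0(out))
  if (nrow(out) > 0) Matrix::diag(out) <- 0
  out <- as_dgc(Matrix::drop0(out))
  attr(out, "provenance") <- c("intrinsic", "topo1", "topo2")
  out
}
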