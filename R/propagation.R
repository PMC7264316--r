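# Core inference: symmetric normalization and iterative label spreading,
# plus the closed-form fixed point used as an independent oracle in tests.

#' Symmetric degree normalization
#'
#' Returns \eqn{\bar S = D^{-1/2} S D^{-1/2}} where `D` is the diagonal of row
#' sums. Zero-degree rows (isolated nodes) map to zero rows rather than
#' raising a division error. The result is symmetric with spectral radius at
#' most 1, which guarantees convergence of the propagation iteration for any
#' mixing parameter below 1.
#'
#' @param S A symmetric nonnegative matrix (e.g. from [fuse_similarities()]).
#' @return A sparse symmetric matrix of the same shape.
#' @export
normalize_symmetric <- function(S) {
  S <- methods::as(methods::as(S, "CsparseMatrix"), "generalMatrix")
  d <- Matrix::rowSums(S)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  out <- Matrix::Diagonal(x = dinv) %*% S %*% Matrix::Diagonal(x = dinv)
  out <- methods::as(out, "CsparseMatrix")
  dimnames(out) <- dimnames(S)
  out
}

#' Propagate labels over a normalized similarity graph
#'
#' Iterates the label-spreading update
#' \deqn{F^{(t+1)} = \alpha \bar S F^{(t)} + (1 - \alpha) Y}
#' from \eqn{F^{(0)} = Y} until the maximum absolute change drops to `tol` or
#' `max_iter` is reached. Because \eqn{\bar S} has spectral radius at most 1
#' and \eqn{\alpha < 1}, the iteration contracts to the unique fixed point
#' \eqn{(1-\alpha)(I - \alpha \bar S)^{-1} Y}. Scores are clipped to \[0, 1\]
#' at the end (clipping, not rescaling, so an absolute weight threshold keeps
#' its meaning).
#'
#' @param S_norm Normalized similarity matrix from [normalize_symmetric()].
#' @param Y Label matrix (columns are propagated independently), entries in
#'   \[0, 1\]. A vector is treated as a one-column matrix.
#' @param alpha Mixing parameter in \[0, 1): weight of the neighbourhood term.
#'   `alpha = 0` is the restart-only limit and returns `Y`.
#' @param tol Convergence tolerance on the max absolute change.
#' @param max_iter Iteration cap.
#' @return A `propagation_result`: list with `scores` (clipped), `iterations`,
#'   `converged`, `residual` (final max-absolute change) and `residuals` (the
#'   full trace).
#' @seealso [solve_closed_form()] for the direct solution of the fixed point.
#' @export
propagate <- function(S_norm, Y, alpha = 0.5, tol = 1e-6, max_iter = 1000L) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha >= 1) {
    rlang::abort("`alpha` must lie in [0, 1) for the iteration to contract.")
  }
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(S_norm)) {
    rlang::abort(sprintf("Shape mismatch: S_norm is %d x %d but Y has %d rows.",
                         nrow(S_norm), ncol(S_norm), nrow(Y)))
  }
  if (length(Y) > 0 && (min(Y) < 0 || max(Y) > 1)) {
    rlang::abort("Label matrix Y must have entries in [0, 1].")
  }
  F_cur <- Y
  residuals <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    F_new <- alpha * as.matrix(S_norm %*% F_cur) + (1 - alpha) * Y
    res <- if (length(F_new) == 0) 0 else max(abs(F_new - F_cur))
    residuals <- c(residuals, res)
    F_cur <- F_new
    if (res <= tol) {
      converged <- TRUE
      break
    }
  }
  scores <- pmin(pmax(F_cur, 0), 1)
  dimnames(scores) <- dimnames(Y)
  structure(
    list(scores = scores, iterations = iter, converged = converged,
         residual = if (iter > 0) residuals[iter] else 0,
         residuals = residuals, alpha = alpha, tol = tol),
    class = "propagation_result"
  )
}

#' @method print propagation_result
#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf("<propagation_result> %d x %d scores | alpha %.3g | %s in %d iterations (residual %.3g)\n",
              nrow(x$scores), ncol(x$scores), x$alpha,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  invisible(x)
}

#' Closed-form fixed point of the propagation iteration
#'
#' Solves \eqn{(I - \alpha \bar S) F = (1-\alpha) Y} directly. The system is
#' nonsingular whenever `alpha < 1` and the spectral radius of `S_norm` is at
#' most 1; a singular factorization is surfaced as an error anyway. Intended
#' as an exact oracle for [propagate()] on problems small enough to factorize.
#'
#' @inheritParams propagate
#' @return A dense score matrix (not clipped).
#' @export
solve_closed_form <- function(S_norm, Y, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha >= 1) {
    rlang::abort("`alpha` must lie in [0, 1).")
  }
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  Y <- as.matrix(Y)
  n <- nrow(S_norm)
  if (nrow(Y) != n) rlang::abort("Shape mismatch between S_norm and Y.")
  A <- diag(n) - alpha * as.matrix(S_norm)
  out <- tryCatch(solve(A, (1 - alpha) * Y),
                  error = function(e) rlang::abort(paste0(
                    "Singular propagation system: ", conditionMessage(e))))
  dimnames(out) <- dimnames(Y)
  out
}

#' Score one relation by two-sided label propagation
#'
#' Runs the propagation once over the row-type fused network using the
#' association columns as labels, and once over the column-type fused network
#' using the transposed associations, then averages the two views:
#' \eqn{F = (F_\mathrm{row} + F_\mathrm{col}^\top)/2}, clipped to \[0, 1\].
#'
#' @param S_row,S_col Fused similarity matrices of the relation's row and
#'   column entity types (not yet normalized).
#' @param A Association matrix of the relation (rows x cols).
#' @param config A [heterolp_config()].
#' @return A list with `scores` (sparse-compatible dense matrix with the
#'   association's dimnames), and `row_result` / `col_result` propagation
#'   diagnostics. Non-convergence produces a warning, not an error; the
#'   partial result is returned with `converged = FALSE`.
#' @export
predict_relation <- function(S_row, S_col, A, config = heterolp_config()) {
  if (nrow(S_row) != nrow(A) || nrow(S_col) != ncol(A)) {
    rlang::abort("Shape mismatch between fused similarities and the association layer.")
  }
  fr <- propagate(normalize_symmetric(S_row), as.matrix(A),
                  alpha = config$alpha, tol = config$tol,
                  max_iter = config$max_iter)
  fc <- propagate(normalize_symmetric(S_col), t(as.matrix(A)),
                  alpha = config$alpha, tol = config$tol,
                  max_iter = config$max_iter)
  if (!fr$converged || !fc$converged) {
    rlang::warn("Label propagation did not converge within max_iter; returning partial scores.")
  }
  scores <- pmin(pmax((fr$scores + t(fc$scores)) / 2, 0), 1)
  dimnames(scores) <- dimnames(A)
  list(scores = scores, row_result = fr, col_result = fc,
       converged = fr$converged && fc$converged)
}
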