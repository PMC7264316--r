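# DT-Hybrid-style baseline: degree-tuned two-phase resource allocation on a
# bipartite layer, blended multiplicatively with intrinsic similarity.

#' Degree-tuned resource-allocation transfer weights
#'
#' Computes the row-side transfer matrix of the hybrid bipartite projection:
#' \deqn{w_{ij} = \frac{1}{\Gamma(i)^{1-\lambda}\,\Gamma(j)^{\lambda}}
#'   \sum_l \frac{a_{il} a_{jl}}{\Gamma'(l)}}
#' where \eqn{\Gamma} and \eqn{\Gamma'} are row and column degrees (weight
#' sums), then blends each weight with the intrinsic similarity of the pair:
#' \eqn{w'_{ij} = w_{ij}\,(\alpha_{dt}\, s_{ij} + 1 - \alpha_{dt})}. Self
#' similarity is taken as 1, so diagonal transfer is never shrunk by the
#' blend. `lambda = 0.5` gives the symmetric hybrid form; `alpha_dt = 0`
#' ignores the similarity entirely (pure network-based inference).
#'
#' @param A Association matrix (binary or \[0, 1\] weights). Every row must
#'   have nonzero degree; run [harmonize_common_entities()] first.
#' @param S_row Intrinsic similarity of the row entities (same row catalog).
#' @param lambda Degree-balance exponent in \[0, 1\].
#' @param alpha_dt Similarity blending weight in \[0, 1\].
#' @return A dense nonnegative square matrix over the row catalog.
#' @export
dthybrid_weights <- function(A, S_row, lambda = 0.5, alpha_dt = 0.5) {
  A <- as.matrix(A)
  gamma_r <- rowSums(A)
  gamma_c <- colSums(A)
  if (any(gamma_r == 0)) {
    rlang::abort(sprintf(
      "Row '%s' has zero degree; the projection is undefined. Harmonize the network first.",
      rownames(A)[which(gamma_r == 0)[1]]))
  }
  # columns with zero degree contribute nothing to the resource allocation
  cinv <- ifelse(gamma_c > 0, 1 / gamma_c, 0)
  raw <- A %*% (t(A) * cinv)
  W <- raw * outer(gamma_r^-(1 - lambda), gamma_r^-lambda)
  S <- as.matrix(S_row)
  if (!all(dim(S) == dim(W)) ||
      (!is.null(rownames(S)) && !identical(rownames(S), rownames(A)))) {
    rlang::abort("`S_row` must be square over the association's row catalog.")
  }
  diag(S) <- 1
  W <- W * (alpha_dt * S + (1 - alpha_dt))
  dimnames(W) <- list(rownames(A), rownames(A))
  W
}

#' Recommendation scores from transfer weights
#'
#' `R = W A`, optionally min-max rescaled to \[0, 1\] per matrix so the same
#' absolute weight threshold used for the propagation scores applies.
#'
#' @param W Transfer matrix from [dthybrid_weights()].
#' @param A The association matrix it was built from.
#' @param rescale Min-max rescale to \[0, 1\] (default `TRUE`).
#' @return A nonnegative recommendation matrix with `A`'s dimnames.
#' @export
dthybrid_recommend <- function(W, A, rescale = TRUE) {
  A <- as.matrix(A)
  if (ncol(W) != nrow(A)) {
    rlang::abort(sprintf("Shape mismatch: W is %d x %d but A has %d rows.",
                         nrow(W), ncol(W), nrow(A)))
  }
  R <- W %*% A
  if (rescale && length(R) > 0) {
    lo <- min(R); hi <- max(R)
    R <- if (hi > lo) (R - lo) / (hi - lo) else R * 0
  }
  dimnames(R) <- dimnames(A)
  R
}

#' DT-Hybrid baseline over a heterogeneous network
#'
#' Harmonizes the network to the entities present in every layer of their
#' type (the "justified" dataset the projection requires), then scores each
#' relation by degree-tuned resource allocation: drug-disease and drug-target
#' from the drug side, disease-target from the disease side.
#'
#' @param network An aligned `hetero_network`.
#' @param config A [heterolp_config()]; uses `dthybrid_lambda`,
#'   `dthybrid_alpha` and `rescale`.
#' @return A `dthybrid_fit`: list with `scores` (three matrices), the
#'   harmonized `network` and the `config`. Supports [tidy()], [glance()] and
#'   [novel_predictions()] via the same score-matrix contract as
#'   [heterolp()].
#' @export
dthybrid <- function(network, config = heterolp_config()) {
  net <- harmonize_common_entities(network)
  lam <- config$dthybrid_lambda
  adt <- config$dthybrid_alpha
  score_layer <- function(A, S_row) {
    W <- dthybrid_weights(A, S_row, lambda = lam, alpha_dt = adt)
    dthybrid_recommend(W, A, rescale = config$rescale)
  }
  structure(
    list(scores = list(
           drug_disease = score_layer(net$A_drug_disease, net$S_drug),
           drug_target = score_layer(net$A_drug_target, net$S_drug),
           disease_target = score_layer(net$A_disease_target, net$S_disease)),
         network = net,
         config = config),
    class = "dthybrid_fit"
  )
}

#' @method print dthybrid_fit
#' @export
print.dthybrid_fit <- function(x, ...) {
  cat("<dthybrid_fit>\n")
  cat(sprintf("  harmonized network: %d drugs, %d diseases, %d targets\n",
              length(x$network$drugs), length(x$network$diseases),
              length(x$network$targets)))
  cat(sprintf("  lambda = %.3g, alpha_dt = %.3g, rescaled = %s\n",
              x$config$dthybrid_lambda, x$config$dthybrid_alpha,
              x$config$rescale))
  invisible(x)
}

#' @export
tidy.dthybrid_fit <- function(x, ...) {
  known <- list(drug_disease = x$network$A_drug_disease,
                drug_target = x$network$A_drug_target,
                disease_target = x$network$A_disease_target)
  purrr::map_dfr(names(x$scores), function(r) {
    df <- scores_to_triples(x$scores[[r]], r)
    if (nrow(df) == 0) {
      df$novel <- logical(0)
      return(df)
    }
    k <- known[[r]]
    df$novel <- k[cbind(match(df$row_id, rownames(k)),
                        match(df$col_id, colnames(k)))] == 0
    df
  }) |>
    dplyr::arrange(.data$relation, dplyr::desc(.data$weight), .data$row_id,
                   .data$col_id)
}

#' @export
glance.dthybrid_fit <- function(x, ...) {
  preds <- purrr::map_dfr(names(x$scores), function(r) {
    known <- switch(r,
                    drug_disease = x$network$A_drug_disease,
                    drug_target = x$network$A_drug_target,
                    disease_target = x$network$A_disease_target)
    novel_predictions(x$scores[[r]], known, tau = x$config$tau, relation = r)
  })
  tibble::tibble(
    n_drugs = length(x$network$drugs),
    n_diseases = length(x$network$diseases),
    n_targets = length(x$network$targets),
    lambda = x$config$dthybrid_lambda,
    alpha_dt = x$config$dthybrid_alpha,
    tau = x$config$tau,
    n_novel = nrow(preds)
  )
}
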