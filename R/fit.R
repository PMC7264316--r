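# The full pipeline: projection of each bipartite layer, fusion with the
# intrinsic similarities, and two-sided propagation of all three relations.

#' Compute the fused similarity layers of a network
#'
#' Each entity type receives topological similarities projected from the two
#' bipartite layers it participates in (drugs: drug-disease and drug-target;
#' diseases: drug-disease and disease-target; targets: drug-target and
#' disease-target), fused with its intrinsic similarity layer.
#'
#' @param network A validated `hetero_network`.
#' @param config A [heterolp_config()] (only `fusion` is used here).
#' @return Named list of fused similarity matrices: `drug`, `disease`,
#'   `target`.
#' @export
fused_similarities <- function(network, config = heterolp_config()) {
  m <- config$fusion
  list(
    drug = fuse_similarities(
      network$S_drug,
      topological_similarity(network$A_drug_disease, "rows"),
      topological_similarity(network$A_drug_target, "rows"),
      method = m),
    disease = fuse_similarities(
      network$S_disease,
      topological_similarity(network$A_drug_disease, "cols"),
      topological_similarity(network$A_disease_target, "rows"),
      method = m),
    target = fuse_similarities(
      network$S_target,
      topological_similarity(network$A_drug_target, "cols"),
      topological_similarity(network$A_disease_target, "cols"),
      method = m)
  )
}

#' Heterogeneous-network label propagation
#'
#' Runs the three-stage pipeline on an aligned network: (1) project each
#' bipartite association layer into topological similarities of both its
#' entity types, (2) fuse these with the intrinsic similarity layers, and
#' (3) propagate the known association labels over the fused graphs to score
#' every entity pair of each relation (drug-disease, drug-target,
#' disease-target). Inference is fully deterministic.
#'
#' @param network A `hetero_network`, e.g. from [align_network()],
#'   [read_network_dir()] or [generate_network()].
#' @param config A [heterolp_config()].
#' @return A `heterolp_fit`: list with `scores` (named list of three score
#'   matrices in \[0, 1\]), `fused` similarities, `convergence` diagnostics
#'   (a tibble), the `network` and the `config`. Use [tidy()] for the scored
#'   triples, [novel_predictions()] for thresholded novel links and
#'   [autoplot()] for the weight distributions.
#' @examples
#' net <- generate_network(synthetic_spec(n_drugs = 12, n_diseases = 10,
#'                                        n_targets = 8, n_blocks = 2))
#' fit <- heterolp(net)
#' glance(fit)
#' @export
heterolp <- function(network, config = heterolp_config()) {
  validate_network(network)
  fused <- fused_similarities(network, config)
  rel <- list(
    drug_disease = predict_relation(fused$drug, fused$disease,
                                    network$A_drug_disease, config),
    drug_target = predict_relation(fused$drug, fused$target,
                                   network$A_drug_target, config),
    disease_target = predict_relation(fused$disease, fused$target,
                                      network$A_disease_target, config)
  )
  convergence <- purrr::map_dfr(names(rel), function(r) {
    tibble::tibble(
      relation = r,
      side = c("row", "col"),
      iterations = c(rel[[r]]$row_result$iterations,
                     rel[[r]]$col_result$iterations),
      converged = c(rel[[r]]$row_result$converged,
                    rel[[r]]$col_result$converged),
      residual = c(rel[[r]]$row_result$residual,
                   rel[[r]]$col_result$residual)
    )
  })
  structure(
    list(scores = purrr::map(rel, "scores"),
         fused = fused,
         convergence = convergence,
         network = network,
         config = config),
    class = "heterolp_fit"
  )
}

#' @method print heterolp_fit
#' @export
print.heterolp_fit <- function(x, ...) {
  cat("<heterolp_fit>\n")
  cat(sprintf("  network: %d drugs, %d diseases, %d targets\n",
              length(x$network$drugs), length(x$network$diseases),
              length(x$network$targets)))
  cat(sprintf("  alpha = %.3g, tau = %.3g, fusion = %s\n",
              x$config$alpha, x$config$tau, x$config$fusion))
  conv <- x$convergence
  cat(sprintf("  propagation: %s (max %d iterations, max residual %.3g)\n",
              if (all(conv$converged)) "all converged" else "NOT all converged",
              max(conv$iterations), max(conv$residual)))
  for (r in names(x$scores)) {
    cat(sprintf("  %-15s %d x %d scores\n", r, nrow(x$scores[[r]]),
                ncol(x$scores[[r]])))
  }
  invisible(x)
}

# matrix -> (row_id, col_id, weight) tibble of nonzero cells
scores_to_triples <- function(m, relation) {
  t <- methods::as(Matrix::drop0(as_dgc(m)), "TsparseMatrix")
  tibble::tibble(
    relation = relation,
    row_id = rownames(m)[t@i + 1L],
    col_id = colnames(m)[t@j + 1L],
    weight = t@x
  )
}

#' @describeIn heterolp Tidy the scored pairs into a tibble. One row per
#'   nonzero scored pair, with a `novel` flag marking pairs absent from the
#'   input associations.
#' @param x A `heterolp_fit`.
#' @param ... Unused.
#' @export
tidy.heterolp_fit <- function(x, ...) {
  known <- list(drug_disease = x$network$A_drug_disease,
                drug_target = x$network$A_drug_target,
                disease_target = x$network$A_disease_target)
  purrr::map_dfr(names(x$scores), function(r) {
    df <- scores_to_triples(x$scores[[r]], r)
    if (nrow(df) == 0) return(df[, c("relation", "row_id", "col_id", "weight")] |>
                                dplyr::mutate(novel = logical(0)))
    k <- known[[r]]
    df$novel <- k[cbind(match(df$row_id, rownames(k)),
                        match(df$col_id, colnames(k)))] == 0
    df
  }) |>
    dplyr::arrange(.data$relation, dplyr::desc(.data$weight), .data$row_id,
                   .data$col_id)
}

#' @describeIn heterolp One-row model summary: catalog sizes, convergence and
#'   novel-prediction count at the configured threshold.
#' @export
glance.heterolp_fit <- function(x, ...) {
  preds <- novel_predictions_all(x)
  tibble::tibble(
    n_drugs = length(x$network$drugs),
    n_diseases = length(x$network$diseases),
    n_targets = length(x$network$targets),
    alpha = x$config$alpha,
    tau = x$config$tau,
    converged = all(x$convergence$converged),
    max_iterations = max(x$convergence$iterations),
    max_residual = max(x$convergence$residual),
    n_novel = nrow(preds)
  )
}
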