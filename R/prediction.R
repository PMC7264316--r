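# Threshold-and-novelty extraction of predictions, and per-entity queries.

#' Extract novel predictions above a weight threshold
#'
#' Keeps scored pairs with weight at or above `tau` that are absent from the
#' input association layer ("novel"). Any nonzero input weight counts as
#' known, including partial confidences in (0, 1). The result is sorted by
#' weight descending with deterministic lexicographic tie-breaking on
#' (row_id, col_id).
#'
#' @param scores Score matrix for one relation (e.g. `fit$scores$drug_disease`).
#' @param known The input association matrix of the same shape.
#' @param tau Nonnegative weight threshold; pairs scoring `>= tau` are kept.
#'   The default 0.005 separates the effective weights from the long tail of
#'   near-zero diffusion mass.
#' @param relation Relation label stored in the output.
#' @return A `heterolp_predictions` tibble with columns `relation`, `row_id`,
#'   `col_id`, `weight`, `novel` (all `TRUE` here), and attributes `tau` and
#'   `catalogs`.
#' @export
novel_predictions <- function(scores, known, tau = 0.005,
                              relation = "relation") {
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0) {
    rlang::abort("`tau` must be a single nonnegative number.")
  }
  if (!all(dim(scores) == dim(known))) {
    rlang::abort("`scores` and `known` must have the same shape.")
  }
  df <- scores_to_triples(scores, relation)
  if (nrow(df) > 0) {
    kw <- known[cbind(match(df$row_id, rownames(known)),
                      match(df$col_id, colnames(known)))]
    df <- df[df$weight >= tau & kw == 0, , drop = FALSE]
  }
  df$novel <- rep(TRUE, nrow(df))
  df <- dplyr::arrange(df, dplyr::desc(.data$weight), .data$row_id, .data$col_id)
  structure(df,
            tau = tau,
            catalogs = list(rows = rownames(scores), cols = colnames(scores)),
            class = c("heterolp_predictions", class(df)))
}

# Novel predictions for all three relations of a fit, bound into one tibble.
novel_predictions_all <- function(fit, tau = fit$config$tau) {
  known <- list(drug_disease = fit$network$A_drug_disease,
                drug_target = fit$network$A_drug_target,
                disease_target = fit$network$A_disease_target)
  out <- purrr::map_dfr(names(fit$scores), function(r) {
    novel_predictions(fit$scores[[r]], known[[r]], tau = tau, relation = r)
  })
  structure(out,
            tau = tau,
            catalogs = list(drug = fit$network$drugs,
                            disease = fit$network$diseases,
                            target = fit$network$targets),
            class = c("heterolp_predictions",
                      class(tibble::as_tibble(out))))
}

#' Query the predictions involving one entity
#'
#' Collects all novel predictions that mention `entity_id`, grouped by
#' relation and ranked by weight. Querying a disease, for instance, returns
#' its candidate drugs (drug-disease relation) and candidate targets
#' (disease-target relation).
#'
#' @param x A `heterolp_fit` or a `heterolp_predictions` tibble.
#' @param entity_id Identifier to look up. An unknown id raises an error that
#'   lists the nearest-matching known identifiers.
#' @param ... Passed on between methods; for the fit method, `tau` overrides
#'   the configured threshold.
#' @return A `heterolp_predictions` tibble restricted to `entity_id` (possibly
#'   empty).
#' @export
query_entity <- function(x, entity_id, ...) {
  UseMethod("query_entity")
}

#' @export
query_entity.heterolp_fit <- function(x, entity_id, tau = x$config$tau, ...) {
  query_entity(novel_predictions_all(x, tau = tau), entity_id)
}

#' @export
query_entity.heterolp_predictions <- function(x, entity_id, ...) {
  known_ids <- unique(unlist(attr(x, "catalogs"), use.names = FALSE))
  if (is.null(known_ids)) known_ids <- unique(c(x$row_id, x$col_id))
  if (!entity_id %in% known_ids) {
    d <- utils::adist(entity_id, known_ids, ignore.case = TRUE)
    near <- known_ids[order(d)][seq_len(min(5L, length(known_ids)))]
    rlang::abort(sprintf("Unknown entity '%s'. Nearest matches: %s",
                         entity_id, paste(near, collapse = ", ")))
  }
  out <- dplyr::filter(x, .data$row_id == entity_id | .data$col_id == entity_id)
  out <- dplyr::arrange(out, .data$relation, dplyr::desc(.data$weight),
                        .data$row_id, .data$col_id)
  structure(out, tau = attr(x, "tau"), catalogs = attr(x, "catalogs"),
            entity = entity_id, class = class(x))
}

#' Write predictions as TSV
#'
#' Columns: `relation  id1  id2  weight  novel`.
#'
#' @param predictions A `heterolp_predictions` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  df <- tibble::as_tibble(predictions)
  lines <- c("relation\tid1\tid2\tweight\tnovel",
             sprintf("%s\t%s\t%s\t%s\t%s", df$relation, df$row_id, df$col_id,
                     sprintf("%.17g", df$weight),
                     ifelse(df$novel, "true", "false")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
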