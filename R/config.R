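#' Analysis configuration
#'
#' Bundles every tunable of the pipeline in one validated list. All values
#' have working defaults; the label-propagation literature gives no canonical
#' setting for `alpha`, so it is exposed rather than hard-coded.
#'
#' @param alpha Label-propagation mixing parameter in (0, 1): the fraction of
#'   each update taken from the neighbourhood average, with `1 - alpha`
#'   restarting from the observed labels. Default 0.5.
#' @param tol Convergence tolerance on the maximum absolute change between
#'   successive score matrices. Default `1e-6`.
#' @param max_iter Iteration cap for the propagation loop. Default 1000.
#' @param tau Weight threshold for reporting predictions; pairs scoring
#'   `>= tau` are kept. Default 0.005.
#' @param dthybrid_lambda Degree-balance exponent of the DT-Hybrid projection,
#'   in \[0, 1\]. 0.5 gives the symmetric hybrid form. Default 0.5.
#' @param dthybrid_alpha Similarity blending weight of DT-Hybrid, in \[0, 1\];
#'   0 ignores intrinsic similarity (pure network-based inference). Default 0.5.
#' @param fusion How intrinsic and topological similarities are combined:
#'   `"max"` (element-wise maximum, default) or `"mean"`.
#' @param rescale Logical; min-max rescale DT-Hybrid recommendation scores to
#'   \[0, 1\] so the `tau` threshold is applicable. Default `TRUE`.
#' @param seed Integer seed for synthetic generation and hold-out sampling.
#'
#' @return A list of class `heterolp_config`.
#' @examples
#' heterolp_config(alpha = 0.7, tau = 0.01)
#' @export
heterolp_config <- function(alpha = 0.5, tol = 1e-6, max_iter = 1000L,
                            tau = 0.005, dthybrid_lambda = 0.5,
                            dthybrid_alpha = 0.5, fusion = c("max", "mean"),
                            rescale = TRUE, seed = 1L) {
  fusion <- match.arg(fusion)
  stopifnot(is.numeric(alpha), length(alpha) == 1)
  if (!(alpha > 0 && alpha < 1)) {
    rlang::abort("`alpha` must lie strictly inside (0, 1).")
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0) {
    rlang::abort("`tau` must be a single nonnegative number.")
  }
  stopifnot(tol > 0, max_iter >= 1)
  if (dthybrid_lambda < 0 || dthybrid_lambda > 1) {
    rlang::abort("`dthybrid_lambda` must lie in [0, 1].")
  }
  if (dthybrid_alpha < 0 || dthybrid_alpha > 1) {
    rlang::abort("`dthybrid_alpha` must lie in [0, 1].")
  }
  structure(
    list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter), tau = tau,
         dthybrid_lambda = dthybrid_lambda, dthybrid_alpha = dthybrid_alpha,
         fusion = fusion, rescale = isTRUE(rescale), seed = as.integer(seed)),
    class = "heterolp_config"
  )
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file whose keys are arguments of
#'   [heterolp_config()].
#' @param ... Overrides applied on top of the file (e.g. CLI flags).
#' @return A `heterolp_config`.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(heterolp_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown configuration keys: ",
                        paste(bad, collapse = ", ")))
  }
  do.call(heterolp_config, vals)
}

#' @method print heterolp_config
#' @export
print.heterolp_config <- function(x, ...) {
  cat("<heterolp_config>\n")
  for (k in names(x)) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}
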