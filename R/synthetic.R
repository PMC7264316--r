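# Synthetic block-structured heterogeneous networks. The generator emulates
# the deposited-data regime in miniature: three sparse similarity layers and
# three very sparse bipartite layers with correlated (modular) structure, and
# id lists that may only partially overlap across layers.

#' Specification of a synthetic heterogeneous network
#'
#' Entities of all three types are assigned to `n_blocks` aligned modules.
#' Associations are drawn Bernoulli(`p_in`) within aligned blocks and
#' Bernoulli(`p_out`) between blocks, so the three bipartite layers share the
#' same latent structure — the regime in which similarity and association
#' evidence reinforce each other across layers. Intrinsic similarity is 0.8
#' for same-block pairs plus Uniform(0, `sim_noise`) everywhere, symmetrized
#' and clipped to \[0, 1\]. Setting `overlap_frac < 1` subsamples each layer's
#' id list to exercise alignment and harmonization.
#'
#' @param n_drugs,n_diseases,n_targets Catalog sizes.
#' @param n_blocks Number of planted modules.
#' @param p_in,p_out Within/between-block association probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param sim_noise Scale of the additive uniform similarity noise.
#' @param overlap_frac Fraction of each catalog present in every layer,
#'   in (0, 1\].
#' @param seed Integer seed; the network is fully reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_drugs = 50, n_diseases = 40, n_targets = 30,
                           n_blocks = 5, p_in = 0.6, p_out = 0.02,
                           sim_noise = 0.1, overlap_frac = 1.0, seed = 1L) {
  stopifnot(n_drugs >= 1, n_diseases >= 1, n_targets >= 1, n_blocks >= 1)
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    rlang::abort("Require 0 <= p_out < p_in <= 1.")
  }
  if (!(overlap_frac > 0 && overlap_frac <= 1)) {
    rlang::abort("Require 0 < overlap_frac <= 1.")
  }
  if (sim_noise < 0) rlang::abort("`sim_noise` must be nonnegative.")
  structure(
    list(n_drugs = as.integer(n_drugs), n_diseases = as.integer(n_diseases),
         n_targets = as.integer(n_targets), n_blocks = as.integer(n_blocks),
         p_in = p_in, p_out = p_out, sim_noise = sim_noise,
         overlap_frac = overlap_frac, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# deterministic per-layer sub-seed from the global seed (kept below 2^31)
layer_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 99991 * k) %% 2147483647)
}

block_assign <- function(n, n_blocks) {
  rep(seq_len(n_blocks), each = ceiling(n / n_blocks))[seq_len(n)]
}

sim_block_matrix <- function(ids, blocks, sim_noise, seed) {
  set.seed(seed)
  n <- length(ids)
  base <- 0.8 * outer(blocks, blocks, "==")
  if (sim_noise > 0) {
    noise <- matrix(stats::runif(n * n, 0, sim_noise), n, n)
    noise <- (noise + t(noise)) / 2
    base <- base + noise
  }
  base <- pmin(pmax(base, 0), 1)
  diag(base) <- 0
  dimnames(base) <- list(ids, ids)
  methods::as(methods::as(base, "CsparseMatrix"), "generalMatrix")
}

assoc_block_matrix <- function(row_ids, col_ids, row_blocks, col_blocks,
                               p_in, p_out, seed) {
  set.seed(seed)
  same <- outer(row_blocks, col_blocks, "==")
  p <- ifelse(same, p_in, p_out)
  draws <- matrix(stats::runif(length(p)) < p, nrow(p), ncol(p)) * 1
  dimnames(draws) <- list(row_ids, col_ids)
  methods::as(methods::as(draws, "CsparseMatrix"), "generalMatrix")
}

subsample_ids <- function(ids, frac, seed) {
  if (frac >= 1) return(ids)
  set.seed(seed)
  keep <- sort(sample.int(length(ids), max(1L, ceiling(frac * length(ids)))))
  ids[keep]
}

#' Generate a synthetic heterogeneous network
#'
#' Draws the six matrices described by a [synthetic_spec()] and aligns them
#' into a `hetero_network`. The planted block memberships are attached as the
#' `blocks` attribute (named integer vectors per entity type) for use as
#' ground truth in benchmarks.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated `hetero_network` with a `blocks` attribute.
#' @examples
#' net <- generate_network(synthetic_spec(n_drugs = 10, n_diseases = 8,
#'                                        n_targets = 6, n_blocks = 2))
#' net
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  drugs <- sprintf("drug%03d", seq_len(spec$n_drugs))
  diseases <- sprintf("disease%03d", seq_len(spec$n_diseases))
  targets <- sprintf("target%03d", seq_len(spec$n_targets))
  b_drug <- block_assign(spec$n_drugs, spec$n_blocks)
  b_dis <- block_assign(spec$n_diseases, spec$n_blocks)
  b_tgt <- block_assign(spec$n_targets, spec$n_blocks)

  S_drug <- sim_block_matrix(drugs, b_drug, spec$sim_noise,
                             layer_seed(spec$seed, 1))
  S_disease <- sim_block_matrix(diseases, b_dis, spec$sim_noise,
                                layer_seed(spec$seed, 2))
  S_target <- sim_block_matrix(targets, b_tgt, spec$sim_noise,
                               layer_seed(spec$seed, 3))
  A_dd <- assoc_block_matrix(drugs, diseases, b_drug, b_dis,
                             spec$p_in, spec$p_out, layer_seed(spec$seed, 4))
  A_dt <- assoc_block_matrix(drugs, targets, b_drug, b_tgt,
                             spec$p_in, spec$p_out, layer_seed(spec$seed, 5))
  A_xt <- assoc_block_matrix(diseases, targets, b_dis, b_tgt,
                             spec$p_in, spec$p_out, layer_seed(spec$seed, 6))

  if (spec$overlap_frac < 1) {
    keep <- function(ids, k) subsample_ids(ids, spec$overlap_frac,
                                           layer_seed(spec$seed, 100 + k))
    S_drug <- S_drug[keep(drugs, 1), keep(drugs, 1), drop = FALSE]
    S_disease <- S_disease[keep(diseases, 2), keep(diseases, 2), drop = FALSE]
    S_target <- S_target[keep(targets, 3), keep(targets, 3), drop = FALSE]
    A_dd <- A_dd[keep(drugs, 4), keep(diseases, 5), drop = FALSE]
    A_dt <- A_dt[keep(drugs, 6), keep(targets, 7), drop = FALSE]
    A_xt <- A_xt[keep(diseases, 8), keep(targets, 9), drop = FALSE]
  }

  net <- align_network(S_drug, S_disease, S_target, A_dd, A_dt, A_xt)
  attr(net, "blocks") <- list(
    drug = stats::setNames(b_drug, drugs)[net$drugs],
    disease = stats::setNames(b_dis, diseases)[net$diseases],
    target = stats::setNames(b_tgt, targets)[net$targets]
  )
  attr(net, "spec") <- spec
  net
}

#' Hold out a fraction of one association layer
#'
#' Removes `round(fraction * nnz)` associations uniformly at random from the
#' chosen relation layer and samples an equal number of true-zero pairs as
#' negatives, for rank-based evaluation of link recovery.
#'
#' @param network A `hetero_network`.
#' @param relation One of `"drug_disease"`, `"drug_target"`,
#'   `"disease_target"`.
#' @param fraction Fraction of nonzero associations to remove, in (0, 1).
#' @param seed Integer seed for the split.
#' @return A `holdout_split`: list with `train` (the network with held-out
#'   links zeroed), `held_out` and `negatives` tibbles of pairs, plus the
#'   relation, fraction and seed.
#' @export
make_holdout <- function(network, relation = c("drug_disease", "drug_target",
                                               "disease_target"),
                         fraction = 0.1, seed = 1L) {
  relation <- match.arg(relation)
  if (!(fraction > 0 && fraction < 1)) {
    rlang::abort("`fraction` must lie in (0, 1).")
  }
  layer_name <- paste0("A_", relation)
  A <- network[[layer_name]]
  t <- methods::as(Matrix::drop0(as_dgc(A)), "TsparseMatrix")
  nnz <- length(t@x)
  if (nnz < 2) {
    rlang::abort(sprintf("Layer %s has fewer than 2 links; cannot hold out.",
                         relation))
  }
  n_out <- max(1L, round(fraction * nnz))
  set.seed(layer_seed(seed, 7))
  pick <- sample.int(nnz, n_out)
  held <- tibble::tibble(row_id = rownames(A)[t@i[pick] + 1L],
                         col_id = colnames(A)[t@j[pick] + 1L],
                         weight = t@x[pick])
  train_A <- A
  train_A[cbind(t@i[pick] + 1L, t@j[pick] + 1L)] <- 0
  train_A <- Matrix::drop0(train_A)
  # negatives: uniformly sampled pairs that are zero in the source layer
  zero_cells <- which(as.matrix(A) == 0)
  if (length(zero_cells) < n_out) {
    rlang::abort("Not enough zero pairs to sample negatives.")
  }
  set.seed(layer_seed(seed, 8))
  neg <- sample(zero_cells, n_out)
  neg_i <- ((neg - 1L) %% nrow(A)) + 1L
  neg_j <- ((neg - 1L) %/% nrow(A)) + 1L
  negatives <- tibble::tibble(row_id = rownames(A)[neg_i],
                              col_id = colnames(A)[neg_j])
  train <- network
  train[[layer_name]] <- methods::as(train_A, "CsparseMatrix")
  structure(
    list(train = train, held_out = held, negatives = negatives,
         relation = relation, fraction = fraction, seed = as.integer(seed)),
    class = "holdout_split"
  )
}

#' Rank-based AUC of held-out links
#'
#' Area under the ROC curve computed from ranks (the Wilcoxon statistic):
#' the probability that a held-out true link outscores a sampled negative
#' pair, with ties contributing 0.5.
#'
#' @param scores Score matrix covering all split pairs (e.g.
#'   `fit$scores[[split$relation]]`).
#' @param split A `holdout_split`.
#' @return AUC in \[0, 1\].
#' @export
holdout_auc <- function(scores, split) {
  stopifnot(inherits(split, "holdout_split"))
  lookup <- function(df) {
    i <- match(df$row_id, rownames(scores))
    j <- match(df$col_id, colnames(scores))
    if (anyNA(i) || anyNA(j)) {
      rlang::abort("`scores` does not cover every pair in the split.")
    }
    as.numeric(scores[cbind(i, j)])
  }
  pos <- lookup(split$held_out)
  neg <- lookup(split$negatives)
  if (length(pos) == 0 || length(neg) == 0) {
    rlang::abort("Both positives and negatives are required for AUC.")
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Degree-product baseline scores
#'
#' Scores every pair by the product of its endpoints' degrees in the training
#' layer — the classic popularity baseline any structural method must beat.
#'
#' @param A Training association matrix.
#' @return A dense nonnegative score matrix with `A`'s dimnames.
#' @export
degree_baseline <- function(A) {
  out <- outer(Matrix::rowSums(A), Matrix::colSums(A))
  dimnames(out) <- dimnames(A)
  out
}
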