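#' Candidate gene pairs eligible for clustering
#'
#' Clustering is restricted to genes whose protein products interact
#' directly (`"adjacent"`) or lie within shortest-path distance 2
#' (`"within2"`) on the induced network. Both directions of every unordered
#' pair are emitted, since the fused similarity is directed.
#'
#' @param net A [ppi_network()].
#' @param policy `"adjacent"` or `"within2"`.
#' @return Tibble with character columns `i`, `k` (directed pairs).
#' @export
candidate_pairs <- function(net, policy = c("adjacent", "within2")) {
  policy <- match.arg(policy)
  g <- net$graph
  nm <- igraph::V(g)$name
  if (igraph::ecount(g) == 0L) {
    return(tibble::tibble(i = character(0), k = character(0)))
  }
  if (policy == "adjacent") {
    e <- igraph::as_edgelist(g, names = TRUE)
    i <- c(e[, 1L], e[, 2L]); k <- c(e[, 2L], e[, 1L])
  } else {
    nb2 <- igraph::ego(g, order = 2L, mindist = 1L)
    i <- rep(nm, lengths(nb2))
    k <- nm[unlist(lapply(nb2, as.integer), use.names = FALSE)]
  }
  tibble::tibble(i = i, k = k)
}

#' Fuse topological and discriminative similarity as a product
#'
#' \eqn{s(i,k) = s_T(i,k) \cdot s_{DP}(i,k)}. The topological factor in
#' `[0, 1]` damps the discriminative similarity of pairs with little
#' neighborhood overlap; the sign of `s_dp` is preserved.
#'
#' @param s_t Topological similarity in `[0, 1]` (vectorised).
#' @param s_dp Discriminative-power similarity (any real).
#' @return Fused similarity.
#' @export
product_similarity <- function(s_t, s_dp) {
  if (any(s_t < 0 | s_t > 1)) stop_subnetap("`s_t` must lie in [0, 1].", "bad_input")
  s_t * s_dp
}

#' Min-max rescale discriminative similarities to `[0, 1]`
#'
#' \eqn{\hat s_{DP} = (s_{DP} - \min) / (\max - \min)}, with min and max
#' taken over the full collection of candidate-pair similarities. A constant
#' collection maps to 0.5 (degenerate convention).
#'
#' @param s_dp Numeric vector over all candidate pairs.
#' @return Rescaled vector in `[0, 1]`.
#' @export
rescale_dp <- function(s_dp) {
  if (length(s_dp) == 0L) stop_subnetap("cannot rescale an empty collection.", "empty")
  lo <- min(s_dp); hi <- max(s_dp)
  if (hi == lo) return(rep(0.5, length(s_dp)))
  (s_dp - lo) / (hi - lo)
}

#' Fuse topological and rescaled discriminative similarity linearly
#'
#' \eqn{s(i,k) = \beta\, s_T(i,k) + (1-\beta)\, \hat s_{DP}(i,k)}; larger
#' \eqn{\beta} weights network topology more heavily.
#'
#' @param s_t Topological similarity in `[0, 1]`.
#' @param s_dp_hat Rescaled discriminative similarity in `[0, 1]`
#'   (see [rescale_dp()]).
#' @param beta Mixing weight in `[0, 1]`.
#' @return Fused similarity in `[0, 1]`.
#' @export
linear_combination <- function(s_t, s_dp_hat, beta = 0.5) {
  if (!is_scalar_number(beta) || beta < 0 || beta > 1) {
    stop_subnetap("`beta` must be a single value in [0, 1].", "bad_beta")
  }
  beta * s_t + (1 - beta) * s_dp_hat
}

#' Shared preference from the similarity distribution
#'
#' The affinity-propagation self-similarity (preference) is set uniformly to
#' `c` such that only a fraction `quantile` (default 1%) of all directed
#' candidate-pair similarities fall at or below `c` -- a low preference that
#' gives every gene an equal, modest chance of becoming an exemplar.
#' Computed as the linear-interpolation (type 7) percentile.
#'
#' @param sims Numeric vector of directed pair similarities.
#' @param quantile Lower-tail fraction, default `0.01`.
#' @return The preference value `c`.
#' @export
set_preference <- function(sims, quantile = 0.01) {
  if (length(sims) == 0L) stop_subnetap("no similarities to take a preference from.", "empty")
  if (!is_scalar_number(quantile) || quantile < 0 || quantile > 1) {
    stop_subnetap("`quantile` must lie in [0, 1].", "bad_input")
  }
  stats::quantile(sims, probs = quantile, type = 7, names = FALSE)
}

#' Build the fused similarity graph of an induced dataset
#'
#' Composes the full similarity used by affinity propagation: candidate
#' pairs from the network, per-gene LLR t scores and pairwise joint t scores
#' for the discriminative similarity, the chosen neighborhood association
#' index for the topological similarity, and either the product or the
#' rescaled linear-combination fusion. Isolated nodes can form no candidate
#' pair and are excluded (and recorded). Similarity for non-candidate pairs
#' is absent, which the clustering treats as \eqn{-\infty}.
#'
#' @param induced An [overlay()] result (or any object with `network` and
#'   `expression` fields in that shape).
#' @param mode `"product"` or `"linear"`.
#' @param index Topological index: `"tversky"` (default), `"jaccard"`, or
#'   `"kulczynski"`.
#' @param alpha Discriminative penalty weight in `[0, 1]`, default `0.5`.
#' @param beta Linear-combination weight (only with `mode = "linear"`),
#'   default `0.5`.
#' @param pair_policy `"adjacent"` (default) or `"within2"`.
#' @param tversky_a,tversky_b Tversky weights, defaults `(1, 0)`.
#' @param include_self Self-inclusive neighborhoods (default `TRUE`).
#' @param use_abs_t Use magnitudes of t scores inside the discriminative
#'   similarity (default `TRUE`); signed mode available for sensitivity
#'   analysis.
#' @param t_variant `"welch"` or `"pooled"`.
#' @param preference_quantile Lower-tail fraction for [set_preference()].
#' @param clamp_negative_dp Clamp negative discriminative similarities to 0
#'   before the product fusion (sensitivity flag, default `FALSE`).
#' @return An object of class `similarity_graph`: list with `pairs` (tibble
#'   `i`, `k`, `sim`), `preference`, `nodes` (clusterable genes),
#'   `excluded` (isolated genes), and `meta` (full configuration).
#' @export
build_similarity_graph <- function(induced,
                                   mode = c("product", "linear"),
                                   index = c("tversky", "jaccard", "kulczynski"),
                                   alpha = 0.5,
                                   beta = 0.5,
                                   pair_policy = c("adjacent", "within2"),
                                   tversky_a = 1, tversky_b = 0,
                                   include_self = TRUE,
                                   use_abs_t = TRUE,
                                   t_variant = c("welch", "pooled"),
                                   preference_quantile = 0.01,
                                   clamp_negative_dp = FALSE) {
  mode <- match.arg(mode)
  index <- match.arg(index)
  pair_policy <- match.arg(pair_policy)
  t_variant <- match.arg(t_variant)
  if (!is_scalar_number(alpha) || alpha < 0 || alpha > 1) {
    stop_subnetap("`alpha` must lie in [0, 1].", "bad_alpha")
  }
  net <- induced$network
  expr <- induced$expression
  labels <- expr$labels
  nm <- proteins(net)

  pairs <- candidate_pairs(net, policy = pair_policy)
  if (nrow(pairs) == 0L) stop_subnetap("no candidate pairs: the network has no edges.", "empty")
  deg <- igraph::degree(net$graph)
  nodes <- nm[deg > 0L]
  excluded <- nm[deg == 0L]

  # discriminative side: per-gene and per-pair (summed-LLR) t scores
  L <- llr_matrix(expr$values, labels)
  t_gene <- row_t_scores(L, labels, variant = t_variant)
  names(t_gene) <- rownames(L)
  i_idx <- match(pairs$i, nm)
  k_idx <- match(pairs$k, nm)
  # t_ik is symmetric: compute once per unordered pair
  lo <- pmin(i_idx, k_idx); hi <- pmax(i_idx, k_idx)
  key <- paste(lo, hi)
  first <- !duplicated(key)
  Lsum <- L[lo[first], , drop = FALSE] + L[hi[first], , drop = FALSE]
  t_pair_u <- row_t_scores(Lsum, labels, variant = t_variant)
  t_ik <- t_pair_u[match(key, key[first])]

  t_i <- t_gene[i_idx]; t_k <- t_gene[k_idx]
  if (use_abs_t) {
    t_i <- abs(t_i); t_k <- abs(t_k); t_ik <- abs(t_ik)
  }
  s_dp <- dp_similarity(t_i, t_k, t_ik, alpha = alpha)

  s_t <- pair_topo_similarity(net, i_idx, k_idx, index = index,
                              a = tversky_a, b = tversky_b,
                              include_self = include_self)

  if (mode == "product") {
    if (clamp_negative_dp) s_dp <- pmax(s_dp, 0)
    sim <- product_similarity(s_t, s_dp)
  } else {
    sim <- linear_combination(s_t, rescale_dp(s_dp), beta = beta)
  }

  pref <- set_preference(sim, quantile = preference_quantile)
  meta <- list(mode = mode, index = index, alpha = alpha,
               beta = if (mode == "linear") beta else NULL,
               pair_policy = pair_policy,
               tversky_a = tversky_a, tversky_b = tversky_b,
               include_self = include_self, use_abs_t = use_abs_t,
               t_variant = t_variant,
               preference_quantile = preference_quantile,
               clamp_negative_dp = clamp_negative_dp)
  structure(
    list(pairs = tibble::tibble(i = pairs$i, k = pairs$k, sim = as.numeric(sim)),
         preference = pref, nodes = nodes, excluded = excluded, meta = meta),
    class = "similarity_graph"
  )
}

#' Construct a similarity graph from a raw directed pair table
#'
#' Low-level constructor used by tests and by callers with externally
#' computed similarities.
#'
#' @param pairs Data frame with columns `i`, `k`, `sim` (both directions of
#'   every candidate pair).
#' @param preference Shared self-similarity `c`.
#' @param nodes Clusterable gene ids; defaults to the ids seen in `pairs`.
#' @param meta Optional provenance list.
#' @return A `similarity_graph`.
#' @export
similarity_graph <- function(pairs, preference, nodes = NULL, meta = list()) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("i", "k", "sim") %in% names(pairs)))
  pairs$i <- as.character(pairs$i); pairs$k <- as.character(pairs$k)
  if (!is_scalar_number(preference)) stop_subnetap("`preference` must be a finite number.", "bad_input")
  nodes <- nodes %||% unique(c(pairs$i, pairs$k))
  structure(list(pairs = pairs, preference = preference,
                 nodes = as.character(nodes), excluded = character(0), meta = meta),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("<similarity_graph> ", length(x$nodes), " genes, ", nrow(x$pairs),
      " directed pairs, preference c = ", format(x$preference, digits = 4),
      "\n", sep = "")
  if (!is.null(x$meta$mode)) {
    cat("  mode=", x$meta$mode, " index=", x$meta$index,
        " alpha=", x$meta$alpha,
        if (!is.null(x$meta$beta)) paste0(" beta=", x$meta$beta) else "",
        "\n", sep = "")
  }
  invisible(x)
}
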