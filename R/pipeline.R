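#' Run configuration for marker discovery
#'
#' Validates and bundles every knob of the discovery pipeline. `beta` is
#' only meaningful for the linear-combination fusion; supplying it together
#' with `mode = "product"` is a configuration error.
#'
#' @param mode Fusion mode, `"product"` or `"linear"`.
#' @param index Topological index, `"tversky"`, `"jaccard"`, or
#'   `"kulczynski"`.
#' @param alpha Discriminative penalty weight, default 0.5.
#' @param beta Linear-combination weight (linear mode only); defaults to
#'   0.5 there.
#' @param pair_policy `"adjacent"` or `"within2"`.
#' @param tversky_a,tversky_b Tversky weights.
#' @param include_self Self-inclusive neighborhoods.
#' @param use_abs_t Magnitude t scores inside the discriminative similarity.
#' @param t_variant `"welch"` or `"pooled"`.
#' @param preference_quantile Lower-tail fraction defining the preference.
#' @param top_k Number of markers to keep, default 50.
#' @param damping,max_iter,conv_window Affinity-propagation settings (see
#'   [ap_config()]).
#' @param seed Seed for clustering tie-breaks and any downstream CV.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("product", "linear"),
                       index = c("tversky", "jaccard", "kulczynski"),
                       alpha = 0.5, beta = NULL,
                       pair_policy = c("adjacent", "within2"),
                       tversky_a = 1, tversky_b = 0,
                       include_self = TRUE, use_abs_t = TRUE,
                       t_variant = c("welch", "pooled"),
                       preference_quantile = 0.01,
                       top_k = 50L,
                       damping = 0.7, max_iter = 2000L, conv_window = 200L,
                       seed = 1L) {
  mode <- match.arg(mode)
  index <- match.arg(index)
  pair_policy <- match.arg(pair_policy)
  t_variant <- match.arg(t_variant)
  if (mode == "product" && !is.null(beta)) {
    stop_subnetap("`beta` is only used by the linear-combination mode; remove it or set mode = \"linear\".",
                  "config_incoherent")
  }
  if (mode == "linear") {
    beta <- beta %||% 0.5
    if (!is_scalar_number(beta) || beta < 0 || beta > 1) {
      stop_subnetap("`beta` must lie in [0, 1].", "bad_beta")
    }
  }
  if (!is_scalar_number(alpha) || alpha < 0 || alpha > 1) {
    stop_subnetap("`alpha` must lie in [0, 1].", "bad_alpha")
  }
  structure(
    list(mode = mode, index = index, alpha = alpha, beta = beta,
         pair_policy = pair_policy, tversky_a = tversky_a,
         tversky_b = tversky_b, include_self = include_self,
         use_abs_t = use_abs_t, t_variant = t_variant,
         preference_quantile = preference_quantile,
         top_k = as.integer(top_k), damping = damping,
         max_iter = as.integer(max_iter), conv_window = as.integer(conv_window),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Named method-variant presets
#'
#' The six standard variants: `jac_p`, `kul_p`, `tve_p` (product fusion with
#' the Jaccard, Kulczynski, Tversky index) and `jac_lc`, `kul_lc`, `tve_lc`
#' (linear combination, `beta` settable, default 0.5).
#'
#' @param name Preset name.
#' @param beta Mixing weight for the `_lc` presets.
#' @param ... Further [run_config()] overrides (e.g. `top_k`, `seed`).
#' @return A [run_config()].
#' @export
preset_config <- function(name = c("tve_p", "jac_p", "kul_p",
                                   "tve_lc", "jac_lc", "kul_lc"),
                          beta = 0.5, ...) {
  name <- match.arg(name)
  parts <- strsplit(name, "_", fixed = TRUE)[[1L]]
  index <- switch(parts[1L], jac = "jaccard", kul = "kulczynski", tve = "tversky")
  if (parts[2L] == "p") {
    run_config(mode = "product", index = index, ...)
  } else {
    run_config(mode = "linear", index = index, beta = beta, ...)
  }
}

#' Discover subnetwork markers on an induced dataset
#'
#' End-to-end discovery: fused similarity graph, affinity-propagation
#' clustering, LLR activity scoring, ranking by absolute activity t score,
#' and top-K selection. Every stage's gene/edge counts are collected into a
#' log, and the returned marker set carries full provenance (configuration,
#' content hashes of the inputs, package version).
#'
#' @param induced An [overlay()] result, or a [generate_synthetic()] result
#'   (its `induced` element is used).
#' @param config A [run_config()].
#' @return An object of class `discovery_result`: list with `markers`
#'   (a `marker_set`), `clustering` (an `ap_result`), `similarity`
#'   (summary of the similarity graph), and `log` (tibble of per-stage
#'   counts).
#' @export
discover_markers <- function(induced, config = run_config()) {
  if (!inherits(induced, "induced_dataset") && !is.null(induced$induced)) {
    induced <- induced$induced
  }
  stopifnot(inherits(induced, "induced_dataset"), inherits(config, "run_config"))

  sims <- build_similarity_graph(
    induced,
    mode = config$mode, index = config$index, alpha = config$alpha,
    beta = config$beta %||% 0.5, pair_policy = config$pair_policy,
    tversky_a = config$tversky_a, tversky_b = config$tversky_b,
    include_self = config$include_self, use_abs_t = config$use_abs_t,
    t_variant = config$t_variant,
    preference_quantile = config$preference_quantile
  )
  clustering <- ap_cluster(
    sims,
    ap_config(damping = config$damping, max_iter = config$max_iter,
              conv_window = config$conv_window, seed = config$seed)
  )
  L <- llr_matrix(induced$expression)
  provenance <- list(
    config = unclass(config),
    input_hash = rlang::hash(list(induced$expression$values,
                                  induced$expression$labels,
                                  igraph::as_edgelist(induced$network$graph))),
    package_version = as.character(utils::packageVersion("subnetap"))
  )
  ranked <- rank_markers(clustering, L, induced$expression$labels,
                         t_variant = config$t_variant, meta = provenance)
  markers <- suppressWarnings(select_top_k(ranked, config$top_k))

  log <- tibble::tibble(
    stage = c("induced_nodes", "induced_edges", "isolated_excluded",
              "candidate_directed_pairs", "clusters", "markers_selected",
              "unique_marker_genes"),
    count = c(induced$n_proteins, induced$n_interactions,
              length(sims$excluded), nrow(sims$pairs),
              length(clustering$clusters), nrow(markers),
              length(unique(unlist(markers$genes))))
  )
  structure(
    list(markers = markers, clustering = clustering,
         similarity = list(n_pairs = nrow(sims$pairs),
                           preference = sims$preference,
                           meta = sims$meta),
         log = log, config = config),
    class = "discovery_result"
  )
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("<discovery_result> ", nrow(x$markers), " markers from ",
      length(x$clustering$clusters), " clusters (",
      x$config$index, "/", x$config$mode,
      ", alpha=", x$config$alpha,
      if (!is.null(x$config$beta)) paste0(", beta=", x$config$beta) else "",
      ")\n", sep = "")
  invisible(x)
}

#' Evaluate a marker set on a dataset
#'
#' Convenience wrapper around [cross_dataset_eval()] for the common cases:
#' within-dataset evaluation (`evaluation` = the discovery data) and
#' cross-dataset transfer.
#'
#' @param markers A `marker_set` (e.g. from [discover_markers()]).
#' @param evaluation An [overlay()] result or [expression_dataset()].
#' @param protocol A [cv_protocol()].
#' @return An `eval_report` (see [cross_dataset_eval()]).
#' @export
evaluate_markers <- function(markers, evaluation, protocol = cv_protocol()) {
  stopifnot(inherits(markers, "marker_set"))
  cross_dataset_eval(markers, evaluation, protocol = protocol)
}
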