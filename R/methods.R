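#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a marker set into a plain tibble
#'
#' @param x A `marker_set`.
#' @param ... Unused.
#' @return Tibble with `rank`, `marker_id`, `size`, `t_score`, `genes`
#'   (list column).
#' @method tidy marker_set
#' @export
tidy.marker_set <- function(x, ...) {
  tibble::tibble(rank = seq_len(nrow(x)),
                 marker_id = x$marker_id,
                 size = x$size,
                 t_score = x$t_score,
                 genes = x$genes)
}

#' One-row summary of a marker set
#' @param x A `marker_set`.
#' @param ... Unused.
#' @return Tibble with marker count, mean size, unique gene count, and the
#'   top absolute activity t score.
#' @method glance marker_set
#' @export
glance.marker_set <- function(x, ...) {
  dplyr::mutate(marker_size_stats(x), top_abs_t = max(abs(x$t_score)))
}

#' Tidy a clustering result
#' @param x An `ap_result`.
#' @param ... Unused.
#' @return Tibble with `gene`, `exemplar`, `cluster_size`.
#' @method tidy ap_result
#' @export
tidy.ap_result <- function(x, ...) {
  sizes <- lengths(x$clusters)
  tibble::tibble(gene = names(x$exemplar),
                 exemplar = unname(x$exemplar),
                 cluster_size = unname(sizes[x$exemplar]))
}

#' One-row summary of a clustering result
#' @param x An `ap_result`.
#' @param ... Unused.
#' @return Tibble with cluster count, mean cluster size, iterations,
#'   convergence flag.
#' @method glance ap_result
#' @export
glance.ap_result <- function(x, ...) {
  tibble::tibble(n_clusters = length(x$clusters),
                 mean_cluster_size = mean(lengths(x$clusters)),
                 iterations = x$iterations,
                 converged = x$converged)
}

#' Tidy an evaluation report (per-K discriminative-power curve)
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with `k`, `mean_abs_t`.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$dp_curve

#' One-row summary of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with mean/sd AUC and marker statistics.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(mean_auc = x$cv$mean_auc, sd_auc = x$cv$sd_auc),
    x$size_stats
  )
}

#' Tidy a discovery result
#' @param x A `discovery_result`.
#' @param ... Unused.
#' @return The tidied marker set.
#' @method tidy discovery_result
#' @export
tidy.discovery_result <- function(x, ...) tidy(x$markers)

#' One-row summary of a discovery result
#' @param x A `discovery_result`.
#' @param ... Unused.
#' @return Marker summary plus cluster count and convergence flag.
#' @method glance discovery_result
#' @export
glance.discovery_result <- function(x, ...) {
  dplyr::bind_cols(glance(x$markers),
                   tibble::tibble(n_clusters = length(x$clustering$clusters),
                                  converged = x$clustering$converged))
}

#' Plot the ranked discriminative power of a marker set
#'
#' Bar chart of absolute activity t scores by marker rank.
#'
#' @param object A `marker_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot marker_set
#' @export
autoplot.marker_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = abs(.data$t_score))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "marker rank", y = "|t| of subnetwork activity",
                  title = "Discriminative power of ranked subnetwork markers") +
    ggplot2::theme_minimal()
}

#' Plot cluster sizes of an affinity-propagation result
#' @param object An `ap_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ap_result
#' @export
autoplot.ap_result <- function(object, ...) {
  df <- tibble::tibble(size = lengths(object$clusters))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey40") +
    ggplot2::labs(x = "cluster size (genes)", y = "clusters",
                  title = "Subnetwork size distribution") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Discriminative-power curve (mean top-K |t|) with the per-repeat AUC
#' distribution in the subtitle.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$dp_curve, ggplot2::aes(x = .data$k, y = .data$mean_abs_t)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "top K markers", y = "mean |t|",
                  title = "Discriminative power of top-K markers",
                  subtitle = sprintf("mean CV AUC %.3f (sd %.3f)",
                                     object$cv$mean_auc, object$cv$sd_auc)) +
    ggplot2::theme_minimal()
}

#' Plot the fused similarity distribution
#'
#' Histogram of directed candidate-pair similarities with the preference
#' `c` marked; useful for judging how selective the exemplar preference is.
#'
#' @param object A `similarity_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot similarity_graph
#' @export
autoplot.similarity_graph <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$sim)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$preference, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "fused similarity s(i,k)", y = "directed pairs",
                  title = "Candidate-pair similarity distribution",
                  subtitle = sprintf("preference c = %.4g (dashed)",
                                     object$preference)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
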