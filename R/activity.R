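#' Subnetwork activity: summed member LLR profiles
#'
#' The activity of a subnetwork \eqn{\mathcal G = \{g_1, \ldots, g_n\}} in a
#' sample is the sum of the member genes' log-likelihood ratios,
#' \eqn{A(\mathcal G) = \sum_i \lambda(x_i)} -- the aggregated probabilistic
#' evidence for phenotype 1.
#'
#' @param genes Character vector of member gene ids.
#' @param llrs LLR matrix (genes x samples) from [llr_matrix()].
#' @return Numeric activity vector over samples.
#' @export
subnetwork_activity <- function(genes, llrs) {
  if (length(genes) == 0L) stop_subnetap("empty gene set.", "empty")
  miss <- setdiff(genes, rownames(llrs))
  if (length(miss)) {
    stop_subnetap(paste0("gene(s) without LLR profile: ",
                         paste(head(miss, 5L), collapse = ", ")), "unknown_gene")
  }
  colSums(llrs[genes, , drop = FALSE])
}

#' Activity matrix of a set of clusters
#'
#' @param clusters Named list of member-gene vectors (names are exemplars).
#' @param llrs LLR matrix from [llr_matrix()].
#' @return Numeric matrix, one row per cluster (rownames = cluster names).
#' @export
activity_matrix <- function(clusters, llrs) {
  if (length(clusters) == 0L) stop_subnetap("no clusters to score.", "empty")
  out <- t(vapply(clusters, subnetwork_activity, numeric(ncol(llrs)), llrs = llrs))
  rownames(out) <- names(clusters)
  colnames(out) <- colnames(llrs)
  out
}

new_marker_set <- function(df, meta = list()) {
  df <- tibble::as_tibble(df)
  structure(df, meta = meta, class = c("marker_set", class(df)))
}

marker_meta <- function(markers) attr(markers, "meta") %||% list()

#' Rank clusters into a marker set by activity discriminative power
#'
#' Scores every cluster's activity vector with the two-sample t statistic
#' between phenotypes and orders markers by descending magnitude
#' (markers may be risk- or protective-directional, so ranking uses
#' \eqn{|t|}). Ties are broken by the smaller exemplar identifier so the
#' ordering is deterministic.
#'
#' @param clusters Named list of member-gene vectors (names = exemplar ids),
#'   or an [ap_cluster()] result.
#' @param llrs LLR matrix from [llr_matrix()].
#' @param labels Phenotype vector in `{1, 2}`.
#' @param t_variant `"welch"` or `"pooled"`.
#' @param meta Optional provenance list stored on the result.
#' @return A `marker_set`: tibble with columns `marker_id` (exemplar),
#'   `genes` (list column), `size`, `t_score`, ordered by descending
#'   `|t_score|`.
#' @export
rank_markers <- function(clusters, llrs, labels, t_variant = c("welch", "pooled"),
                         meta = list()) {
  t_variant <- match.arg(t_variant)
  if (inherits(clusters, "ap_result")) clusters <- clusters$clusters
  if (length(clusters) == 0L) stop_subnetap("no clusters to rank.", "empty")
  act <- activity_matrix(clusters, llrs)
  tt <- row_t_scores(act, labels, variant = t_variant)
  df <- tibble::tibble(
    marker_id = names(clusters),
    genes = lapply(clusters, function(g) sort(unname(g))),
    size = lengths(clusters),
    t_score = as.numeric(tt)
  )
  df <- df[order(-abs(df$t_score), df$marker_id), ]
  new_marker_set(df, meta = meta)
}

#' Keep the top-K markers
#'
#' @param markers A `marker_set` (already ranked).
#' @param k Number of markers to keep; default 50. When fewer are available
#'   all are returned with a warning.
#' @return A `marker_set` of `min(k, nrow(markers))` rows.
#' @export
select_top_k <- function(markers, k = 50L) {
  stopifnot(inherits(markers, "marker_set"))
  k <- as.integer(k)
  if (k < 1L) stop_subnetap("`k` must be >= 1.", "bad_input")
  if (nrow(markers) < k) {
    warn_subnetap(paste0("only ", nrow(markers), " markers available (k = ", k, ")"),
                  "short_marker_set")
    return(markers)
  }
  out <- markers[seq_len(k), ]
  new_marker_set(out, meta = marker_meta(markers))
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set> ", nrow(x), " markers, ",
      length(unique(unlist(x$genes))), " unique genes\n", sep = "")
  NextMethod()
}
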