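#' Neighborhood association indices
#'
#' Set-overlap similarity indices between two proteins' neighbor sets
#' \eqn{N_i} and \eqn{N_k}:
#'
#' * Jaccard: \eqn{|N_i \cap N_k| / |N_i \cup N_k|}
#' * Kulczynski: \eqn{\frac12(|N_i \cap N_k|/|N_i| + |N_i \cap N_k|/|N_k|)},
#'   the average proportion of common neighbors.
#' * Tversky: \eqn{|N_i \cap N_k| / (|N_i \cap N_k| + a|N_i \setminus N_k| +
#'   b|N_k \setminus N_i|)}; `(a=1, b=1)` recovers Jaccard, `(0.5, 0.5)`
#'   Dice, and the default `(1, 0)` the asymmetric fraction
#'   \eqn{|N_i \cap N_k| / |N_i|} of the first set's neighbors that are
#'   shared.
#' * Dice: \eqn{2|N_i \cap N_k| / (|N_i| + |N_k|)}.
#' * Ochiai (cosine): \eqn{|N_i \cap N_k| / \sqrt{|N_i| |N_k|}}.
#'
#' All indices lie in `[0, 1]` and return 0 whenever a denominator would be
#' zero (empty-neighborhood convention). Dice and Ochiai are provided for
#' rank-equivalence comparisons; the clustering pipeline uses Jaccard,
#' Kulczynski, or Tversky.
#'
#' @param Ni,Nk Neighbor sets (vectors of identifiers; duplicates ignored).
#' @param a,b Nonnegative Tversky weights.
#' @return A similarity in `[0, 1]`.
#' @name association_indices
NULL

set_counts <- function(Ni, Nk) {
  Ni <- unique(Ni); Nk <- unique(Nk)
  c(common = length(intersect(Ni, Nk)), ni = length(Ni), nk = length(Nk))
}

#' @rdname association_indices
#' @export
jaccard_index <- function(Ni, Nk) {
  s <- set_counts(Ni, Nk)
  denom <- s[["ni"]] + s[["nk"]] - s[["common"]]
  if (denom == 0) return(0)
  s[["common"]] / denom
}

#' @rdname association_indices
#' @export
kulczynski_index <- function(Ni, Nk) {
  s <- set_counts(Ni, Nk)
  if (s[["ni"]] == 0 || s[["nk"]] == 0) return(0)
  0.5 * (s[["common"]] / s[["ni"]] + s[["common"]] / s[["nk"]])
}

#' @rdname association_indices
#' @export
tversky_index <- function(Ni, Nk, a = 1, b = 0) {
  if (a < 0 || b < 0) stop_subnetap("Tversky weights must be nonnegative.", "bad_input")
  s <- set_counts(Ni, Nk)
  denom <- s[["common"]] + a * (s[["ni"]] - s[["common"]]) + b * (s[["nk"]] - s[["common"]])
  if (denom == 0) return(0)
  s[["common"]] / denom
}

#' @rdname association_indices
#' @export
dice_index <- function(Ni, Nk) {
  s <- set_counts(Ni, Nk)
  if (s[["ni"]] + s[["nk"]] == 0) return(0)
  2 * s[["common"]] / (s[["ni"]] + s[["nk"]])
}

#' @rdname association_indices
#' @export
ochiai_index <- function(Ni, Nk) {
  s <- set_counts(Ni, Nk)
  if (s[["ni"]] == 0 || s[["nk"]] == 0) return(0)
  s[["common"]] / sqrt(s[["ni"]] * s[["nk"]])
}

#' Neighbor sets of every protein in a network
#'
#' By default each protein is included in its own neighborhood
#' (`include_self = TRUE`): without self-inclusion two directly interacting
#' proteins sharing no third partner would score 0 on every index, which
#' contradicts the premise that interacting proteins are candidates for the
#' same module. The flag is recorded in downstream provenance.
#'
#' @param net A [ppi_network()] (the induced network, post-overlay).
#' @param include_self Include each protein in its own neighbor set?
#' @return Named list of character vectors (one neighbor set per protein).
#' @export
neighborhoods <- function(net, include_self = TRUE) {
  stopifnot(inherits(net, "ppi_network"))
  g <- net$graph
  adj <- igraph::as_adj_list(g, mode = "all")
  nm <- igraph::V(g)$name
  out <- lapply(seq_along(adj), function(i) {
    nb <- nm[as.integer(adj[[i]])]
    if (include_self) unique(c(nm[i], nb)) else unique(nb)
  })
  names(out) <- nm
  out
}

#' Topological similarity between two proteins
#'
#' Dispatches to the chosen association index over the proteins' neighbor
#' sets. For the (asymmetric) Tversky index the first argument's
#' neighborhood plays the role of \eqn{N_i}, matching the direction of the
#' fused similarity \eqn{s(i, k)}.
#'
#' @param net A [ppi_network()].
#' @param i,k Protein identifiers present in `net`.
#' @param index `"jaccard"`, `"kulczynski"`, or `"tversky"`.
#' @param a,b Tversky weights (ignored by the symmetric indices).
#' @param include_self Passed to [neighborhoods()].
#' @return A similarity in `[0, 1]`.
#' @export
topo_similarity <- function(net, i, k, index = c("jaccard", "kulczynski", "tversky"),
                            a = 1, b = 0, include_self = TRUE) {
  index <- match.arg(index)
  nb <- neighborhoods(net, include_self = include_self)
  if (!i %in% names(nb) || !k %in% names(nb)) {
    stop_subnetap("protein not present in the network.", "unknown_protein")
  }
  switch(index,
         jaccard = jaccard_index(nb[[i]], nb[[k]]),
         kulczynski = kulczynski_index(nb[[i]], nb[[k]]),
         tversky = tversky_index(nb[[i]], nb[[k]], a = a, b = b))
}

# vectorised index evaluation for a directed pair table via the sparse
# adjacency; pairs: integer node indices (i, k) into V(net)
pair_topo_similarity <- function(net, i_idx, k_idx,
                                 index = c("jaccard", "kulczynski", "tversky"),
                                 a = 1, b = 0, include_self = TRUE) {
  index <- match.arg(index)
  g <- net$graph
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- (A > 0) * 1  # binarise; guards against multi-edge weights
  if (include_self) A <- A + Matrix::Diagonal(nrow(A))
  sizes <- Matrix::rowSums(A)
  common_mat <- Matrix::tcrossprod(A)
  common <- common_mat[cbind(i_idx, k_idx)]
  ni <- sizes[i_idx]; nk <- sizes[k_idx]
  out <- switch(index,
    jaccard = {
      denom <- ni + nk - common
      ifelse(denom == 0, 0, common / denom)
    },
    kulczynski = {
      ifelse(ni == 0 | nk == 0, 0, 0.5 * (common / ni + common / nk))
    },
    tversky = {
      denom <- common + a * (ni - common) + b * (nk - common)
      ifelse(denom == 0, 0, common / denom)
    })
  as.numeric(out)
}
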