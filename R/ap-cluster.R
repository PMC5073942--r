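#' Affinity propagation configuration
#'
#' @param damping Message damping factor \eqn{\lambda_d \in [0.5, 1)};
#'   default 0.7.
#' @param max_iter Maximum message-passing sweeps; default 2000.
#' @param conv_window Consecutive sweeps with an unchanged exemplar set
#'   required to declare convergence; default 200.
#' @param noise_scale Scale of the tiny deterministic jitter added to
#'   similarities to break exact ties; default `1e-12`.
#' @param seed Seed driving the jitter; default 1.
#' @return A list of class `ap_config`.
#' @export
ap_config <- function(damping = 0.7, max_iter = 2000L, conv_window = 200L,
                      noise_scale = 1e-12, seed = 1L) {
  if (!is_scalar_number(damping) || damping < 0.5 || damping >= 1) {
    stop_subnetap("`damping` must lie in [0.5, 1).", "bad_config")
  }
  max_iter <- as.integer(max_iter); conv_window <- as.integer(conv_window)
  if (conv_window < 1L || max_iter < conv_window) {
    stop_subnetap("need max_iter >= conv_window >= 1.", "bad_config")
  }
  structure(list(damping = damping, max_iter = max_iter,
                 conv_window = conv_window, noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "ap_config")
}

#' Cluster genes by affinity propagation on a sparse similarity graph
#'
#' Runs the responsibility/availability message-passing scheme on the
#' directed candidate-pair support of a [similarity_graph()]. Messages are
#' stored only on candidate pairs plus the self-pairs, so memory is
#' O(number of candidate pairs); a pair with no defined similarity behaves
#' as \eqn{s = -\infty}. Updates:
#' \deqn{r(i,k) \leftarrow s(i,k) - \max_{k' \neq k} [a(i,k') + s(i,k')]}
#' \deqn{a(i,k) \leftarrow \min\{0,\; r(k,k) + \sum_{i' \notin \{i,k\}} \max(0, r(i',k))\}, \quad i \neq k}
#' \deqn{a(k,k) \leftarrow \sum_{i' \neq k} \max(0, r(i',k))}
#' both damped by `damping`. Self-similarities are the shared preference
#' `c` of the graph. After convergence (exemplar set unchanged for
#' `conv_window` sweeps) each gene is assigned to
#' \eqn{\arg\max_k [a(i,k) + r(i,k)]}; a gene whose chosen exemplar did not
#' declare itself an exemplar is reassigned to its best self-declared
#' exemplar, and becomes a singleton if it has none (standard finalization).
#'
#' @param sims A [similarity_graph()].
#' @param config An [ap_config()].
#' @return An object of class `ap_result`: list with `exemplar` (named
#'   character vector gene -> exemplar), `clusters` (named list exemplar ->
#'   member genes), `iterations`, `converged`, and `excluded` (isolated
#'   genes carried over from the graph).
#' @export
ap_cluster <- function(sims, config = ap_config()) {
  stopifnot(inherits(sims, "similarity_graph"), inherits(config, "ap_config"))
  nodes <- sims$nodes
  n <- length(nodes)
  if (n == 0L) stop_subnetap("similarity graph has no clusterable genes.", "empty")

  ii <- match(sims$pairs$i, nodes)
  kk <- match(sims$pairs$k, nodes)
  keep <- !is.na(ii) & !is.na(kk)
  ii <- ii[keep]; kk <- kk[keep]
  s <- as.numeric(sims$pairs$sim[keep])
  # drop duplicate directed pairs defensively (keep first occurrence)
  dup <- duplicated(paste(ii, kk)) | ii == kk
  ii <- ii[!dup]; kk <- kk[!dup]; s <- s[!dup]

  # append self-pairs carrying the preference
  ii <- c(ii, seq_len(n)); kk <- c(kk, seq_len(n))
  s <- c(s, rep(sims$preference, n))
  E <- length(s)
  self_idx <- (E - n + 1L):E

  # tiny seeded jitter to break exact ties, as in reference AP practice
  if (config$noise_scale > 0) {
    jit <- with_seed(config$seed, runif(E, 0, 1))
    s <- s + config$noise_scale * (abs(s) + 1) * jit
  }

  gi <- split(seq_len(E), ii)   # out-edges per sender i (includes self)
  fi <- ii                       # group index per edge
  r <- numeric(E); a <- numeric(E)
  lam <- config$damping
  rp <- numeric(E)

  exemplars_prev <- integer(0)
  stable <- 0L
  it <- 0L
  converged <- FALSE

  while (it < config$max_iter) {
    it <- it + 1L

    # responsibilities: subtract the best competing (a + s) per sender
    v <- a + s
    m <- vapply(gi, function(e) {
      vv <- v[e]
      j <- which.max(vv)
      m1 <- vv[j]
      vv[j] <- -Inf
      m2 <- if (length(vv) > 1L) max(vv) else -Inf
      c(m1, m2, e[j])
    }, numeric(3))
    m1 <- m[1L, fi]
    rnew <- s - m1
    arg <- as.integer(m[3L, ])
    rnew[arg] <- s[arg] - m[2L, ]
    r <- lam * r + (1 - lam) * rnew

    # availabilities: evidence flowing back from candidate exemplars
    rp <- pmax(r, 0)
    rp[self_idx] <- 0
    tot <- numeric(n)
    rs <- rowsum(rp, kk)
    tot[as.integer(rownames(rs))] <- rs[, 1L]
    rkk <- r[self_idx]
    anew <- pmin(0, rkk[kk] + tot[kk] - rp)
    anew[self_idx] <- tot
    a <- lam * a + (1 - lam) * anew

    exemplars <- which(r[self_idx] + a[self_idx] > 0)
    if (identical(exemplars, exemplars_prev)) {
      stable <- stable + 1L
      if (stable >= config$conv_window && length(exemplars) > 0L) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
      exemplars_prev <- exemplars
    }
  }
  if (!converged) {
    warn_subnetap(paste0("affinity propagation did not converge within ",
                         config$max_iter, " iterations; returning best-effort result"),
                  "no_convergence")
  }

  # final assignment on a + r
  crit <- a + r
  choice <- vapply(gi, function(e) e[which.max(crit[e])], integer(1))
  chosen_k <- kk[choice]
  self_declared <- which(chosen_k == seq_len(n))

  exemplar_of <- integer(n)
  for (g in seq_len(n)) {
    ck <- chosen_k[g]
    if (ck == g || ck %in% self_declared) {
      exemplar_of[g] <- ck
    } else {
      # reassign to the best self-declared exemplar reachable from g
      e <- gi[[g]]
      cand <- e[kk[e] %in% self_declared & kk[e] != g]
      if (length(cand) > 0L) {
        exemplar_of[g] <- kk[cand[which.max(s[cand])]]
      } else {
        exemplar_of[g] <- g  # unreachable: becomes its own singleton
        self_declared <- c(self_declared, g)
      }
    }
  }
  # exemplars must point to themselves
  exemplar_of[unique(exemplar_of)] <- unique(exemplar_of)

  exemplar <- setNames(nodes[exemplar_of], nodes)
  clusters <- split(nodes, exemplar_of)
  names(clusters) <- nodes[as.integer(names(clusters))]

  structure(
    list(exemplar = exemplar, clusters = clusters,
         iterations = it, converged = converged,
         excluded = sims$excluded),
    class = "ap_result"
  )
}

#' @export
print.ap_result <- function(x, ...) {
  cat("<ap_result> ", length(x$clusters), " clusters over ", length(x$exemplar),
      " genes (", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}

#' Net similarity of a clustering (the affinity-propagation objective)
#'
#' \eqn{\sum_i s(i, e(i))}, counting the preference `c` for each exemplar's
#' self-assignment. Returns \eqn{-\infty} if any non-exemplar gene is
#' assigned across a pair with no defined similarity.
#'
#' @param sims A [similarity_graph()].
#' @param result An [ap_cluster()] result (or a named exemplar vector).
#' @return The scalar objective value.
#' @export
net_similarity <- function(sims, result) {
  ex <- if (inherits(result, "ap_result")) result$exemplar else result
  genes <- names(ex)
  lut <- sims$pairs
  key <- paste(lut$i, lut$k, sep = "\r")
  smap <- setNames(lut$sim, key)
  total <- 0
  for (g in genes) {
    e <- ex[[g]]
    if (identical(e, g)) {
      total <- total + sims$preference
    } else {
      sv <- smap[paste(g, e, sep = "\r")]
      if (is.na(sv)) return(-Inf)
      total <- total + sv
    }
  }
  unname(total)
}
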