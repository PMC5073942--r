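# Independent oracles and small fixture builders shared across tests.

# brute-force association index over explicit 0/1 membership vectors on a
# fixed universe -- deliberately independent of the package's set-based and
# sparse-matrix implementations
bitvec_index <- function(Ni, Nk, universe, index, a = 1, b = 0) {
  vi <- universe %in% Ni
  vk <- universe %in% Nk
  common <- sum(vi & vk)
  ni <- sum(vi)
  nk <- sum(vk)
  switch(index,
    jaccard = if (ni + nk - common == 0) 0 else common / (ni + nk - common),
    kulczynski = if (ni == 0 || nk == 0) 0 else 0.5 * (common / ni + common / nk),
    tversky = {
      den <- common + a * (ni - common) + b * (nk - common)
      if (den == 0) 0 else common / den
    },
    dice = if (ni + nk == 0) 0 else 2 * common / (ni + nk),
    ochiai = if (ni == 0 || nk == 0) 0 else common / sqrt(ni * nk)
  )
}

# exhaustive search over all exemplar subsets, maximising the net-similarity
# objective sum_i s(i, e(i)) + c * |E|; returns the optimum value
oracle_optimum <- function(sims) {
  nodes <- sims$nodes
  n <- length(nodes)
  stopifnot(n <= 16)
  S <- matrix(-Inf, n, n, dimnames = list(nodes, nodes))
  S[cbind(match(sims$pairs$i, nodes), match(sims$pairs$k, nodes))] <- sims$pairs$sim
  best <- -Inf
  for (mask in seq_len(2^n - 1)) {
    E <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    tot <- length(E) * sims$preference
    ok <- TRUE
    for (i in seq_len(n)) {
      if (i %in% E) next
      v <- max(S[i, E])
      if (!is.finite(v)) {
        ok <- FALSE
        break
      }
      tot <- tot + v
    }
    if (ok && tot > best) best <- tot
  }
  best
}

# random two-block similarity instance: dense within-block directed
# similarities drawn in [5, 6], no cross-block pairs
make_block_sims <- function(n, seed, preference = -1) {
  set.seed(seed)
  block <- sample(rep(1:2, length.out = n))
  ids <- sprintf("n%02d", seq_len(n))
  pr <- expand.grid(i = seq_len(n), k = seq_len(n))
  pr <- pr[pr$i != pr$k & block[pr$i] == block[pr$k], ]
  similarity_graph(
    data.frame(i = ids[pr$i], k = ids[pr$k],
               sim = runif(nrow(pr), 5, 6)),
    preference = preference, nodes = ids
  )
}

# deterministic toy expression dataset: 4 genes x 6 samples, two genes shifted
make_toy_expr <- function() {
  vals <- rbind(
    gA = c(2.0, 2.2, 1.8, 0.1, -0.1, 0.0),
    gB = c(1.5, 1.7, 1.6, 0.2, 0.1, -0.2),
    gC = c(0.3, -0.2, 0.1, 0.2, -0.1, 0.1),
    gD = c(-0.1, 0.2, 0.0, 0.1, 0.0, -0.3)
  )
  colnames(vals) <- paste0("s", 1:6)
  expression_dataset(vals, labels = c(1, 1, 1, 2, 2, 2))
}

# random neighbor-set pair over a lettered universe
random_set_pair <- function(universe_size = 20) {
  u <- paste0("p", seq_len(universe_size))
  list(
    Ni = sample(u, sample.int(universe_size, 1)),
    Nk = sample(u, sample.int(universe_size, 1)),
    universe = u
  )
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
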