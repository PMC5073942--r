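path_net <- function() ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))

test_that("candidate pairs follow the proximity policy, both directions", {
  net <- path_net()
  adj <- candidate_pairs(net, "adjacent")
  expect_setequal(paste(adj$i, adj$k), c("A B", "B A", "B C", "C B"))
  w2 <- candidate_pairs(net, "within2")
  expect_setequal(paste(w2$i, w2$k),
                  c("A B", "B A", "B C", "C B", "A C", "C A"))
  lonely <- ppi_network(igraph::make_empty_graph(3, directed = FALSE) |>
                          igraph::set_vertex_attr("name", value = c("X", "Y", "Z")))
  expect_equal(nrow(candidate_pairs(lonely, "adjacent")), 0L)
})

test_that("product fusion damps by topology and preserves sign", {
  expect_equal(product_similarity(0, 123.4), 0)
  expect_equal(product_similarity(1, -3.2), -3.2)
  expect_equal(product_similarity(0.5, 3.5), 1.75)
  expect_error(product_similarity(1.2, 1), class = "subnetap_bad_input")
})

test_that("min-max rescaling maps extremes to 0/1 with a degenerate midpoint", {
  expect_equal(rescale_dp(c(0, 5, 10)), c(0, 0.5, 1))
  x <- rnorm(50)
  r <- rescale_dp(x)
  expect_equal(r[which.min(x)], 0)
  expect_equal(r[which.max(x)], 1)
  expect_equal(rescale_dp(rep(3.3, 7)), rep(0.5, 7))
  expect_error(rescale_dp(numeric(0)), class = "subnetap_empty")
})

test_that("linear combination interpolates between the two similarities", {
  expect_equal(linear_combination(0.4, 0.8, beta = 0), 0.8)
  expect_equal(linear_combination(0.4, 0.8, beta = 1), 0.4)
  expect_equal(linear_combination(0.4, 0.8, beta = 0.5), 0.6)
  expect_error(linear_combination(0.4, 0.8, beta = 1.2), class = "subnetap_bad_beta")
  # monotone path toward s_T as beta grows
  betas <- seq(0, 1, by = 0.25)
  vals <- vapply(betas, function(b) linear_combination(0.9, 0.1, b), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("the preference sits at the lower tail of the similarity spectrum", {
  expect_equal(set_preference(rep(2.5, 40)), 2.5)
  set.seed(8)
  sims <- rnorm(1000)
  c0 <- set_preference(sims, 0.01)
  # at most 1% of pairs (plus a tie block) fall at or below c
  expect_lte(mean(sims <= c0), 0.011)
  expect_gte(mean(sims <= c0), 0.009)
  # 100 distinct values: c lies between the 1st and 2nd smallest
  v <- sort(rnorm(100))
  c1 <- set_preference(v, 0.01)
  expect_gte(c1, v[1])
  expect_lt(c1, v[2])
  expect_equal(mean(v <= c1), 0.01)
  expect_error(set_preference(numeric(0)), class = "subnetap_empty")
})

test_that("the fused similarity graph matches a hand-composed two-node case", {
  net <- ppi_network(data.frame(a = "A", b = "B"))
  vals <- rbind(A = c(1.8, 2.2, 2.0, 0.2, -0.2, 0.0),
                B = c(0.9, 1.1, 1.0, 0.1, 0.0, -0.1))
  colnames(vals) <- paste0("s", 1:6)
  lab <- c(1, 1, 1, 2, 2, 2)
  expr <- expression_dataset(vals, lab)
  ind <- overlay(expr, net)
  sg <- build_similarity_graph(ind, mode = "product", index = "jaccard",
                               alpha = 0.5, pair_policy = "adjacent")

  # independent scalar-path composition of the same quantities
  pA <- fit_class_gaussians(vals["A", ], lab)
  pB <- fit_class_gaussians(vals["B", ], lab)
  lA <- llr(vals["A", ], pA)
  lB <- llr(vals["B", ], pB)
  tA <- abs(t_score(lA, lab)); tB <- abs(t_score(lB, lab))
  tAB <- abs(t_score(lA + lB, lab))
  sT <- jaccard_index(c("A", "B"), c("A", "B"))  # self-inclusive: identical sets
  s_ab <- sT * dp_similarity(tA, tB, tAB, 0.5)
  s_ba <- sT * dp_similarity(tB, tA, tAB, 0.5)
  got <- sg$pairs
  expect_equal(got$sim[got$i == "A" & got$k == "B"], s_ab, tolerance = 1e-10)
  expect_equal(got$sim[got$i == "B" & got$k == "A"], s_ba, tolerance = 1e-10)
})

test_that("beta = 0 linear fusion equals the rescaled pure-DP graph", {
  set.seed(3)
  g <- igraph::sample_gnp(12, 0.3)
  igraph::V(g)$name <- paste0("p", 1:12)
  vals <- matrix(rnorm(12 * 10), 12, 10,
                 dimnames = list(paste0("p", 1:12), paste0("s", 1:10)))
  expr <- expression_dataset(vals, rep(c(1, 2), each = 5))
  ind <- suppressMessages(overlay(expr, ppi_network(g)))
  lin0 <- build_similarity_graph(ind, mode = "linear", beta = 0)
  prod <- build_similarity_graph(ind, mode = "product", index = "jaccard")
  # recover raw DP from the product graph via s_T
  i_idx <- match(prod$pairs$i, proteins(ind$network))
  k_idx <- match(prod$pairs$k, proteins(ind$network))
  sT <- subnetap:::pair_topo_similarity(ind$network, i_idx, k_idx, "jaccard")
  s_dp <- prod$pairs$sim / sT
  expect_equal(lin0$pairs$sim, rescale_dp(s_dp), tolerance = 1e-10)
  expect_true(all(lin0$pairs$sim >= 0 & lin0$pairs$sim <= 1))
})

test_that("similarity graphs are deterministic and validated", {
  set.seed(4)
  g <- igraph::sample_gnp(10, 0.35)
  igraph::V(g)$name <- paste0("p", 1:10)
  vals <- matrix(rnorm(100), 10, 10,
                 dimnames = list(paste0("p", 1:10), paste0("s", 1:10)))
  expr <- expression_dataset(vals, rep(c(1, 2), each = 5))
  ind <- suppressMessages(overlay(expr, ppi_network(g)))
  a <- build_similarity_graph(ind)
  b <- build_similarity_graph(ind)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$preference, b$preference)
  # directed pairs come in both orientations
  expect_setequal(paste(a$pairs$i, a$pairs$k), paste(a$pairs$k, a$pairs$i))
  edgeless <- suppressMessages(overlay(
    expr, ppi_network(igraph::make_empty_graph(10, directed = FALSE) |>
                        igraph::set_vertex_attr("name", value = paste0("p", 1:10)))
  ))
  expect_error(build_similarity_graph(edgeless), class = "subnetap_empty")
})
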