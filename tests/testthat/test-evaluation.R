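mk_markers <- function(genes, t = NULL) {
  if (is.null(t)) t <- rev(seq_along(genes))
  df <- tibble::tibble(marker_id = paste0("m", seq_along(genes)),
                       genes = genes, size = lengths(genes),
                       t_score = t)
  subnetap:::new_marker_set(df)
}

test_that("marker size statistics match hand counts", {
  ms <- mk_markers(list(c("A", "B"), c("B", "C"), "D"))
  st <- marker_size_stats(ms)
  expect_equal(st$mean_size, 5 / 3)
  expect_equal(st$unique_genes, 4L)
  one <- mk_markers(list(paste0("g", 1:7)))
  expect_equal(marker_size_stats(one)$mean_size, 7)
  expect_equal(marker_size_stats(one)$unique_genes, 7L)
  singles <- mk_markers(as.list(paste0("g", 1:50)))
  expect_equal(marker_size_stats(singles)$mean_size, 1)
  expect_equal(marker_size_stats(singles)$unique_genes, 50L)
})

test_that("gene-level marker overlap behaves like Jaccard on unions", {
  a <- mk_markers(list(c("a", "b"), "c"))
  b <- mk_markers(list(c("b", "c"), "d"))
  expect_equal(marker_overlap(a, a), 1)
  expect_equal(marker_overlap(a, b), 0.5)  # {a,b,c} vs {b,c,d}
  expect_equal(marker_overlap(a, b), marker_overlap(b, a))
  disj <- mk_markers(list("x", "y"))
  expect_equal(marker_overlap(a, disj), 0)
  expect_equal(marker_overlap(a, b, method = "containment"), 2 / 3)
})

test_that("discriminative-power curves average the top-K |t| values", {
  ms <- mk_markers(as.list(paste0("g", 1:5)), t = c(5, -4, 3, 2, 1))
  cv <- dp_curve(ms, ks = c(1, 2, 5))
  expect_equal(cv$mean_abs_t, c(5, 4.5, 3))
  expect_true(all(diff(cv$mean_abs_t) <= 0))  # non-increasing in K
  flat <- mk_markers(as.list(paste0("g", 1:4)), t = rep(2.2, 4))
  expect_equal(dp_curve(flat, ks = c(2, 4))$mean_abs_t, c(2.2, 2.2))
  expect_warning(tr <- dp_curve(ms, ks = 10), class = "subnetap_k_truncated")
  expect_equal(tr$mean_abs_t, mean(c(5, 4, 3, 2, 1)))
})

test_that("cross-dataset rescoring on the same data reproduces the ranking t", {
  ds <- make_toy_expr()
  L <- llr_matrix(ds)
  clusters <- list(gA = c("gA", "gB"), gC = "gC")
  ms <- rank_markers(clusters, L, ds$labels)
  out <- cross_dataset_dp(ms, ds, ks = c(1, 2))
  expect_equal(out$per_marker$t_score_b, ms$t_score, tolerance = 1e-10)
  expect_equal(out$curve$mean_abs_t,
               dp_curve(ms, ks = c(1, 2))$mean_abs_t, tolerance = 1e-10)
})

test_that("markers losing genes are rescored on the remainder or dropped", {
  ds <- make_toy_expr()
  sub_vals <- ds$values[c("gA", "gC"), ]  # gB and gD unmeasured here
  sub <- expression_dataset(sub_vals, ds$labels)
  ms <- mk_markers(list(c("gA", "gB"), c("gD")), t = c(3, 1))
  expect_message(out <- cross_dataset_dp(ms, sub, ks = 1), "dropped")
  expect_equal(nrow(out$per_marker), 1L)   # the gD-only marker is gone
  L <- llr_matrix(sub)
  expect_equal(out$per_marker$t_score_b,
               t_score(subnetwork_activity("gA", L), ds$labels),
               tolerance = 1e-10)  # hand recomputation on the surviving gene
})

test_that("rank AUC matches hand-computed probabilities", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 2, 2)), 1)
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 2, 2)), 0)
  expect_equal(auc_score(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 2, 2)), 0.75)
  expect_equal(auc_score(rep(1, 10), rep(c(1, 2), 5)), 0.5)  # all tied
  # invariance under strictly monotone transforms
  set.seed(2)
  sc <- rnorm(40); lb <- rep(c(1, 2), 20)
  expect_equal(auc_score(sc, lb), auc_score(exp(sc), lb))
  expect_equal(auc_score(sc, lb), auc_score(rank(sc), lb))
})

test_that("cross-validated LDA separates a separable activity matrix", {
  set.seed(10)
  lab <- rep(c(1, 2), each = 30)
  act <- rbind(sig = ifelse(lab == 1, 1, -1) + rnorm(60, 0, 0.05),
               noise = rnorm(60))
  cv <- lda_auc_cv(act, lab, cv_protocol(repeats = 10, seed = 1))
  expect_gt(cv$mean_auc, 0.99)
  expect_equal(nrow(cv$per_repeat), 10L)
})

test_that("a single separating feature among many noise features is found", {
  set.seed(20)
  lab <- rep(c(1, 2), each = 40)
  act <- rbind(matrix(rnorm(49 * 80), 49, 80),
               sig = ifelse(lab == 1, 1.5, -1.5) + rnorm(80, 0, 0.3))
  cv <- lda_auc_cv(act, lab, cv_protocol(repeats = 5, seed = 2))
  expect_gt(cv$mean_auc, 0.9)
})

test_that("the shrunken diagonal fallback handles singular training folds", {
  set.seed(30)
  lab <- rep(c(1L, 2L), each = 10)
  base <- ifelse(lab == 1, 1, -1) + rnorm(20, 0, 0.2)
  # a within-group-constant feature makes plain LDA fail -> fallback engages
  x <- cbind(f1 = base, f2 = base, f3 = 1)
  sc <- subnetap:::lda_scores(x, lab, x)
  expect_true(all(is.finite(sc)))
  expect_equal(auc_score(sc, lab), 1)
  sc2 <- subnetap:::diag_lda_scores(x, lab, x)
  expect_equal(auc_score(sc2, lab), 1)
  # and the CV wrapper stays usable on such degenerate activity matrices
  cv <- lda_auc_cv(t(x), lab, cv_protocol(repeats = 5, seed = 3))
  expect_gt(cv$mean_auc, 0.9)
})

test_that("stratified folds preserve class balance", {
  lab <- rep(c(1, 2), c(40, 20))
  f <- subnetap:::with_seed(9, subnetap:::make_folds(lab, 5, TRUE))
  for (fold in 1:5) {
    expect_equal(sum(lab == 1 & f == fold), 8)
    expect_equal(sum(lab == 2 & f == fold), 4)
  }
})

test_that("cross-dataset evaluation wires discovery markers to held-out AUC", {
  spec <- synthetic_spec(n_genes = 80, n_modules = 8, n_disease_modules = 2,
                         delta = 1.5, n_per_class = 25, seed = 55)
  synth <- generate_synthetic(spec)
  cfg <- preset_config("tve_p", top_k = 2, seed = 55)
  rep1 <- suppressWarnings(
    cross_dataset_eval(synth$induced, synth$induced, cfg,
                       cv_protocol(repeats = 5, seed = 55))
  )
  expect_s3_class(rep1, "eval_report")
  expect_gt(rep1$cv$mean_auc, 0.8)
  expect_equal(nrow(rep1$markers), 2L)
  g <- glance(rep1)
  expect_named(g, c("mean_auc", "sd_auc", "n_markers", "mean_size", "unique_genes"))
})
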