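test_that("expression round-trips through the tab-delimited reader", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = rownames(vals), vals), f,
              sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = paste0("s", 1:4), phenotype = c(1, 1, 2, 2)),
              lab, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_expression(f, lab)
  expect_s3_class(ds, "expression_dataset")
  expect_equal(dim(ds), c(3L, 4L))
  expect_equal(unname(ds$values), unname(vals))
  expect_equal(ds$labels, c(1L, 1L, 2L, 2L))
})

test_that("duplicated gene rows are collapsed by their arithmetic mean", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "gA\t1\t2\t3\t4",
               "gA\t3\t4\t5\t6",
               "gB\t0\t0\t1\t1"), f)
  expect_warning(
    ds <- read_expression(f, c(1, 1, 2, 2)),
    class = "subnetap_collapsed_duplicates"
  )
  expect_equal(unname(ds$values["gA", ]), c(2, 3, 4, 5))  # hand-averaged
  expect_equal(nrow(ds$values), 2L)
})

test_that("label problems are hard errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4", "gA\t1\t2\t3\t4"), f)
  expect_error(read_expression(f, c(1, 1, 1, 1)), class = "subnetap_few_samples")
  expect_error(
    read_expression(f, data.frame(sample_id = c("s1", "s2"), phenotype = c(1, 2))),
    class = "subnetap_missing_label"
  )
})

test_that("non-finite rows are imputed (<10% missing) or dropped (>=10%)", {
  vals <- matrix(rnorm(2 * 20), 2, 20,
                 dimnames = list(c("gA", "gB"), paste0("s", 1:20)))
  vals["gA", 1] <- NA      # 5% missing -> impute with row mean
  vals["gB", 1:5] <- NA    # 25% missing -> drop
  expect_message(
    ds <- expression_dataset(vals, rep(c(1, 2), each = 10)),
    "imputed"
  )
  expect_equal(rownames(ds$values), "gA")
  expect_equal(ds$values["gA", 1], mean(vals["gA", -1]))
})

test_that("edge lists are deduplicated and self-loops dropped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "A\tA"), f)
  net <- read_network(f, "edge_tsv")
  expect_equal(n_interactions(net), 1L)
  expect_setequal(proteins(net), c("A", "B"))
  expect_equal(net$n_self_loops_dropped, 1L)
})

test_that("SIF lines expand source-relation-targets into pairwise edges", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines("A pp B C", f)
  net <- read_network(f, "sif")
  el <- igraph::as_edgelist(net$graph)
  got <- apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(got, c("A-B", "A-C"))  # manual SIF parse
})

test_that("malformed and empty network files raise informative errors", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_network(empty, "edge_tsv"), class = "subnetap_empty")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "C"), bad)
  expect_error(read_network(bad, "edge_tsv"), regexp = "line 2")
  badsif <- withr::local_tempfile(fileext = ".sif")
  writeLines("A pp", badsif)
  expect_error(read_network(badsif, "sif"), class = "subnetap_parse")
})

test_that("overlay intersects network and expression and is idempotent", {
  net <- ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  vals <- matrix(rnorm(8), 2, 4, dimnames = list(c("A", "B"), paste0("s", 1:4)))
  expr <- expression_dataset(vals, c(1, 1, 2, 2))
  ind <- suppressMessages(overlay(expr, net))
  expect_equal(ind$n_proteins, 2L)       # manual intersection: {A, B}
  expect_equal(ind$n_interactions, 1L)
  # idempotence and monotonicity of counts
  ind2 <- suppressMessages(overlay(ind$expression, ind$network))
  expect_equal(ind2$n_proteins, ind$n_proteins)
  expect_equal(ind2$n_interactions, ind$n_interactions)
  expect_equal(sort(proteins(ind2$network)), sort(proteins(ind$network)))
  expect_lte(ind$n_proteins, length(proteins(net)))
  expect_lte(ind$n_interactions, n_interactions(net))
})

test_that("identity overlay keeps everything; disjoint universes error", {
  net <- ppi_network(data.frame(a = "A", b = "B"))
  vals <- matrix(rnorm(8), 2, 4, dimnames = list(c("A", "B"), paste0("s", 1:4)))
  expr <- expression_dataset(vals, c(1, 1, 2, 2))
  ind <- overlay(expr, net)
  expect_equal(ind$n_proteins, 2L)
  expect_equal(ind$n_interactions, 1L)
  rownames(vals) <- c("X", "Y")
  expr2 <- expression_dataset(vals, c(1, 1, 2, 2))
  expect_error(overlay(expr2, net), class = "subnetap_empty_overlay")
})

test_that("many-to-many mapping keeps the highest-variance gene per protein", {
  net <- ppi_network(data.frame(a = "P1", b = "P2"))
  vals <- rbind(g_low = c(0, 0, 0.1, 0.1),
                g_high = c(5, -5, 5, -5),
                g_other = c(1, 2, 1, 2))
  colnames(vals) <- paste0("s", 1:4)
  expr <- expression_dataset(vals, c(1, 1, 2, 2))
  map <- gene_protein_map(data.frame(
    gene = c("g_low", "g_high", "g_other"),
    protein = c("P1", "P1", "P2")
  ))
  ind <- overlay(expr, net, map)
  expect_equal(ind$node_gene$gene_id[ind$node_gene$node == "P1"], "g_high")
})

test_that("marker sets round-trip through JSON and format as GMT", {
  df <- tibble::tibble(
    marker_id = c("gX", "gY"),
    genes = list(c("gA", "gX"), "gY"),
    size = c(2L, 1L),
    t_score = c(3.14159265358979, -2.5)
  )
  ms <- subnetap:::new_marker_set(df, meta = list(mode = "product", alpha = 0.5))

  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_markers(ms, gmt, "gmt")
  lines <- readLines(gmt)
  expect_length(lines, 2L)
  expect_equal(strsplit(lines[1], "\t")[[1]][c(1, 3, 4)], c("gX", "gA", "gX"))
  expect_length(strsplit(lines[2], "\t")[[1]], 3L)  # single-member marker is valid

  js <- withr::local_tempfile(fileext = ".json")
  write_markers(ms, js, "json")
  back <- read_markers(js)
  expect_identical(back$marker_id, ms$marker_id)
  expect_identical(back$genes, ms$genes)
  expect_identical(back$t_score, ms$t_score)  # full precision
  expect_equal(attr(back, "meta")$alpha, 0.5)

  empty <- subnetap:::new_marker_set(df[0, ])
  expect_error(write_markers(empty, gmt, "gmt"), class = "subnetap_empty")
})
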