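#' Construct an expression dataset
#'
#' Bundles a genes-by-samples expression matrix (log-scale assumed) with a
#' binary phenotype label per sample. Phenotype `1` is the positive class
#' (e.g. metastatic), phenotype `2` the reference class.
#'
#' Rows containing non-finite values are handled before validation: a row
#' with fewer than 10% missing entries is row-mean imputed, otherwise it is
#' dropped; both actions are reported via a message.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names sample identifiers.
#' @param labels Integer vector of phenotypes in `{1, 2}`, one per sample
#'   (column), optionally named by sample id.
#' @param gene_ids,sample_ids Optional identifier vectors overriding the
#'   dimnames of `values`.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `labels`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_dataset(m, labels = c(1, 1, 2, 2))
expression_dataset <- function(values, labels, gene_ids = rownames(values),
                               sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_subnetap("`values` must be a numeric matrix (genes x samples).", "bad_input")
  }
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids)) {
    stop_subnetap("duplicate gene identifiers; collapse duplicates first (see read_expression()).",
                  "duplicate_genes")
  }
  labels <- as.integer(labels)
  if (length(labels) != ncol(values)) {
    stop_subnetap("`labels` must have one phenotype per sample.", "label_length")
  }
  if (!all(labels %in% c(1L, 2L))) {
    stop_subnetap("phenotype labels must be 1 (positive class) or 2.", "bad_labels")
  }
  if (sum(labels == 1L) < 2L || sum(labels == 2L) < 2L) {
    stop_subnetap("each phenotype needs at least 2 samples.", "few_samples")
  }

  bad <- !is.finite(values)
  if (any(bad)) {
    frac <- rowMeans(bad)
    impute <- frac > 0 & frac < 0.1
    drop <- frac >= 0.1
    if (any(impute)) {
      for (r in which(impute)) {
        row <- values[r, ]
        row[!is.finite(row)] <- mean(row[is.finite(row)])
        values[r, ] <- row
      }
      message(sum(impute), " gene row(s) row-mean imputed (<10% missing)")
    }
    if (any(drop)) {
      message(sum(drop), " gene row(s) dropped (>=10% non-finite)")
      values <- values[!drop, , drop = FALSE]
      gene_ids <- gene_ids[!drop]
    }
    if (nrow(values) == 0L) stop_subnetap("no gene rows left after dropping non-finite rows.", "empty")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids, labels = labels),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$values), " genes x ", ncol(x$values), " samples (",
      sum(x$labels == 1L), " phenotype-1, ", sum(x$labels == 2L), " phenotype-2)\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression matrix with phenotype labels
#'
#' Reads a tab-delimited genes-by-samples matrix (first column gene id,
#' header row sample ids). Labels come either from a two-column TSV
#' (`sample_id`, `phenotype` in `{1,2}`), from a data frame with those
#' columns, or from a named (or unnamed, column-ordered) vector.
#'
#' Duplicated gene rows (multiple probes for one gene) are collapsed by the
#' arithmetic mean of their expression rows, with a warning.
#'
#' @param path Path to the expression matrix file.
#' @param labels Path to a label TSV, a data frame, or a vector of phenotypes.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, labels) {
  if (!file.exists(path)) stop_subnetap(paste0("no such file: ", path), "io")
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_subnetap("expression file needs a gene-id column plus >=1 sample.", "io")
  gene_ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  sample_ids <- colnames(mat)

  if (anyDuplicated(gene_ids)) {
    n_dup <- sum(duplicated(gene_ids))
    warn_subnetap(paste0(n_dup, " duplicated gene row(s) collapsed by mean"), "collapsed_duplicates")
    mat <- rowsum(mat, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
    gene_ids <- rownames(mat)
  }

  lab <- resolve_labels(labels, sample_ids)
  expression_dataset(mat, lab, gene_ids = gene_ids, sample_ids = sample_ids)
}

resolve_labels <- function(labels, sample_ids) {
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    labels <- utils::read.delim(labels, header = TRUE, stringsAsFactors = FALSE)
  }
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L) stop_subnetap("label table needs columns (sample_id, phenotype).", "io")
    lab <- setNames(labels[[2L]], as.character(labels[[1L]]))
    miss <- setdiff(sample_ids, names(lab))
    if (length(miss)) {
      stop_subnetap(paste0("missing phenotype label for sample(s): ",
                           paste(head(miss, 5L), collapse = ", ")), "missing_label")
    }
    return(as.integer(lab[sample_ids]))
  }
  if (is.numeric(labels) || is.integer(labels)) {
    if (!is.null(names(labels))) {
      miss <- setdiff(sample_ids, names(labels))
      if (length(miss)) {
        stop_subnetap(paste0("missing phenotype label for sample(s): ",
                             paste(head(miss, 5L), collapse = ", ")), "missing_label")
      }
      return(as.integer(labels[sample_ids]))
    }
    return(as.integer(labels))
  }
  stop_subnetap("`labels` must be a file path, data frame, or numeric vector.", "bad_input")
}

#' Construct a protein-protein interaction network
#'
#' An undirected, simple graph over protein identifiers. Self-loops are
#' dropped (and counted) and duplicate edges merged.
#'
#' @param edges Two-column data frame or character matrix of interacting
#'   protein pairs, or an igraph object.
#' @return An object of class `ppi_network` wrapping an undirected simple
#'   [igraph::graph] plus bookkeeping counts.
#' @export
#' @examples
#' ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
ppi_network <- function(edges) {
  if (inherits(edges, "igraph")) {
    g <- edges
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    n_loops <- sum(igraph::which_loop(g))
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L) stop_subnetap("edge list needs two columns.", "bad_input")
    a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
    loops <- a == b
    n_loops <- sum(loops)
    a <- a[!loops]; b <- b[!loops]
    g <- igraph::graph_from_data_frame(data.frame(a, b, stringsAsFactors = FALSE),
                                       directed = FALSE)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  }
  if (igraph::vcount(g) == 0L) stop_subnetap("network has no proteins.", "empty")
  structure(
    list(graph = g, n_self_loops_dropped = n_loops),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", igraph::vcount(x$graph), " proteins, ",
      igraph::ecount(x$graph), " interactions\n", sep = "")
  invisible(x)
}

#' Protein identifiers of a network
#' @param net A [ppi_network()].
#' @return Character vector of protein ids.
#' @export
proteins <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  igraph::V(net$graph)$name
}

#' Interaction count of a network
#' @param net A [ppi_network()].
#' @return Integer number of undirected interactions.
#' @export
n_interactions <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  igraph::ecount(net$graph)
}

#' Read a PPI network from an edge list or SIF file
#'
#' `edge_tsv` expects two whitespace/tab-separated protein ids per line.
#' `sif` expects `source relation target1 [target2 ...]`; a single-field
#' line declares an isolated protein (standard SIF), while a two-field line
#' is malformed.
#'
#' @param path File path.
#' @param dialect `"edge_tsv"` or `"sif"`.
#' @return A [ppi_network()].
#' @export
read_network <- function(path, dialect = c("edge_tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_subnetap(paste0("no such file: ", path), "io")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_subnetap("network file is empty.", "empty")
  fields <- strsplit(trimws(lines), "[ \t]+")
  a <- character(0); b <- character(0); isolated <- character(0)
  for (ln in seq_along(fields)) {
    f <- fields[[ln]]
    if (dialect == "edge_tsv") {
      if (length(f) != 2L) {
        stop_subnetap(paste0("malformed edge line ", ln, ": expected 2 fields, got ",
                             length(f)), "parse")
      }
      a <- c(a, f[1L]); b <- c(b, f[2L])
    } else {
      if (length(f) == 1L) {
        isolated <- c(isolated, f[1L])
      } else if (length(f) == 2L) {
        stop_subnetap(paste0("malformed SIF line ", ln,
                             ": source + relation but no target"), "parse")
      } else {
        tgt <- f[-(1:2)]
        a <- c(a, rep(f[1L], length(tgt))); b <- c(b, tgt)
      }
    }
  }
  if (length(a) == 0L && length(isolated) == 0L) stop_subnetap("no interactions found.", "empty")
  loops <- a == b
  g <- igraph::graph_from_data_frame(
    data.frame(a = a[!loops], b = b[!loops], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = unique(c(a, b, isolated)), stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g)
  net <- ppi_network(g)
  net$n_self_loops_dropped <- sum(loops)
  net
}

#' Gene-to-protein identifier map
#'
#' Many-to-many pairs are allowed at construction; multiplicity is resolved
#' during [overlay()].
#'
#' @param pairs Data frame with columns gene id and protein id (first two
#'   columns are used).
#' @return A tibble of class `gene_protein_map` with columns
#'   `gene_id`, `protein_id`.
#' @export
gene_protein_map <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop_subnetap("mapping needs columns (gene_id, protein_id).", "bad_input")
  out <- tibble::tibble(gene_id = as.character(pairs[[1L]]),
                        protein_id = as.character(pairs[[2L]]))
  out <- dplyr::distinct(out)
  class(out) <- c("gene_protein_map", class(out))
  out
}

#' Read a gene-protein mapping table
#' @param path Two-column TSV (gene_id, protein_id) with header.
#' @return A [gene_protein_map()].
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop_subnetap(paste0("no such file: ", path), "io")
  gene_protein_map(utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE))
}

#' Overlay an expression dataset onto a PPI network
#'
#' Restricts both sides to the mapped intersection: proteins without a
#' measured, mapped gene are removed from the network and genes without a
#' network node are removed from the dataset, yielding the induced analysis
#' graph with a one-to-one gene/node correspondence.
#'
#' Multiplicity is resolved deterministically: a protein mapped by several
#' genes keeps the gene with the largest expression variance; a gene mapped
#' to several proteins is replicated onto each node. Isolated nodes are
#' retained (and counted) but can form no candidate pair downstream.
#'
#' @param expr An [expression_dataset()].
#' @param net A [ppi_network()].
#' @param map A [gene_protein_map()], or `NULL` when gene ids are already
#'   protein ids (identity mapping).
#' @return An object of class `induced_dataset` with elements `network`,
#'   `expression` (rows indexed by node id), `node_gene` (tibble node ->
#'   source gene), and retention counts.
#' @export
overlay <- function(expr, net, map = NULL) {
  stopifnot(inherits(expr, "expression_dataset"), inherits(net, "ppi_network"))
  if (is.null(map)) {
    map <- gene_protein_map(tibble::tibble(gene_id = expr$gene_ids,
                                           protein_id = expr$gene_ids))
  }
  stopifnot(inherits(map, "gene_protein_map"))
  prot <- proteins(net)
  m <- dplyr::filter(map, .data$gene_id %in% expr$gene_ids, .data$protein_id %in% prot)
  if (nrow(m) == 0L) {
    stop_subnetap("no protein in the network maps to a measured gene.", "empty_overlay")
  }
  # a protein keeps the mapped gene with the largest expression variance
  gene_var <- apply(expr$values, 1L, stats::var)
  m$var <- gene_var[m$gene_id]
  m <- dplyr::slice_max(dplyr::group_by(m, .data$protein_id), .data$var,
                        n = 1L, with_ties = FALSE)
  m <- dplyr::ungroup(m)

  sub <- igraph::induced_subgraph(net$graph, vids = m$protein_id)
  node_ids <- igraph::V(sub)$name
  m <- m[match(node_ids, m$protein_id), ]
  vals <- expr$values[m$gene_id, , drop = FALSE]
  rownames(vals) <- node_ids
  induced_expr <- expression_dataset(vals, expr$labels,
                                     gene_ids = node_ids,
                                     sample_ids = expr$sample_ids)
  induced_net <- ppi_network(sub)
  iso <- sum(igraph::degree(sub) == 0L)
  if (iso > 0L) message(iso, " isolated node(s) retained; excluded from clustering")
  structure(
    list(network = induced_net,
         expression = induced_expr,
         node_gene = tibble::tibble(node = node_ids, gene_id = m$gene_id),
         n_proteins = length(node_ids),
         n_interactions = igraph::ecount(sub),
         n_isolated = iso),
    class = "induced_dataset"
  )
}

#' @export
print.induced_dataset <- function(x, ...) {
  cat("<induced_dataset> ", x$n_proteins, " mapped nodes, ", x$n_interactions,
      " interactions, ", ncol(x$expression$values), " samples\n", sep = "")
  invisible(x)
}

#' Write a marker set to GMT or JSON
#'
#' GMT is the gene-set standard: one line per marker,
#' `name TAB description TAB gene1 TAB gene2 ...`. JSON additionally carries
#' activity t-scores and provenance and round-trips losslessly through
#' [read_markers()].
#'
#' @param markers A `marker_set` (see [rank_markers()]).
#' @param path Output file path.
#' @param format `"json"` or `"gmt"`.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path, format = c("json", "gmt")) {
  format <- match.arg(format)
  stopifnot(inherits(markers, "marker_set"))
  if (nrow(markers) == 0L) stop_subnetap("marker set is empty.", "empty")
  if (format == "gmt") {
    lines <- vapply(seq_len(nrow(markers)), function(i) {
      paste(c(markers$marker_id[i],
              sprintf("t=%.6g", markers$t_score[i]),
              markers$genes[[i]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
  } else {
    payload <- list(
      markers = lapply(seq_len(nrow(markers)), function(i) {
        list(marker_id = markers$marker_id[i],
             t_score = markers$t_score[i],
             genes = as.list(markers$genes[[i]]))
      }),
      provenance = marker_meta(markers)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a marker set written by [write_markers()] (JSON format)
#' @param path JSON file path.
#' @return A `marker_set`.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop_subnetap(paste0("no such file: ", path), "io")
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- payload$markers
  df <- tibble::tibble(
    marker_id = vapply(rows, function(r) as.character(r$marker_id), character(1)),
    genes = lapply(rows, function(r) vapply(r$genes, as.character, character(1))),
    t_score = vapply(rows, function(r) as.numeric(r$t_score), numeric(1))
  )
  df$size <- lengths(df$genes)
  new_marker_set(df, meta = payload$provenance %||% list())
}
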