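#' Specification of a synthetic benchmark instance
#'
#' Describes a planted-partition PPI network with class-conditional Gaussian
#' expression. Genes are grouped into densely connected modules
#' (within-module edge probability `p_in`, background probability `p_out`,
#' `p_in > p_out`); a subset of modules is flagged "disease": their genes
#' carry a mean shift of `delta` (in units of the within-class standard
#' deviation) in phenotype 1, while all other genes are pure noise in both
#' phenotypes.
#'
#' The defaults are the benchmark conditions used throughout the package's
#' recovery tests: 300 genes in 30 modules of 10, `p_in = 0.6`,
#' `p_out = 0.01`, 3 disease modules, `delta = 1.5`, 50 samples per class,
#' unit noise.
#'
#' @param n_genes Total number of genes.
#' @param n_modules Number of planted modules.
#' @param module_size_range Length-2 integer vector `(min, max)`; sizes are
#'   drawn uniformly. Genes left over after module assignment are
#'   unstructured background.
#' @param p_in,p_out Within-module and background edge probabilities.
#' @param n_disease_modules Number of modules carrying the phenotype signal.
#' @param delta Class-mean shift of disease genes, in units of
#'   `noise_sigma`.
#' @param n_per_class Samples per phenotype.
#' @param noise_sigma Within-class standard deviation.
#' @param degree_exponent Optional power-law exponent for per-gene degree
#'   multipliers (degree heterogeneity); `NULL` (default) keeps the plain
#'   planted-partition model.
#' @param seed Master seed; network, expression and fold randomness are
#'   drawn from named substreams derived from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 300L, n_modules = 30L,
                           module_size_range = c(10L, 10L),
                           p_in = 0.6, p_out = 0.01,
                           n_disease_modules = 3L, delta = 1.5,
                           n_per_class = 50L, noise_sigma = 1,
                           degree_exponent = NULL, seed = 1L) {
  n_genes <- as.integer(n_genes); n_modules <- as.integer(n_modules)
  module_size_range <- as.integer(module_size_range)
  if (length(module_size_range) != 2L || any(module_size_range < 1L) ||
      module_size_range[1L] > module_size_range[2L]) {
    stop_subnetap("`module_size_range` must be (min, max) with 1 <= min <= max.", "bad_spec")
  }
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    stop_subnetap("edge probabilities must lie in [0, 1].", "bad_spec")
  }
  if (n_disease_modules > n_modules) {
    stop_subnetap("`n_disease_modules` cannot exceed `n_modules`.", "bad_spec")
  }
  if (delta < 0) stop_subnetap("`delta` must be >= 0.", "bad_spec")
  if (n_modules * module_size_range[1L] > n_genes) {
    stop_subnetap("module sizes are infeasible for `n_genes`.", "bad_spec")
  }
  structure(
    list(n_genes = n_genes, n_modules = n_modules,
         module_size_range = module_size_range,
         p_in = p_in, p_out = p_out,
         n_disease_modules = as.integer(n_disease_modules), delta = delta,
         n_per_class = as.integer(n_per_class), noise_sigma = noise_sigma,
         degree_exponent = degree_exponent, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

spec_seeds <- function(spec) {
  s <- derive_seeds(spec$seed, 3L)
  list(network = s[1L], expression = s[2L], folds = s[3L])
}

#' Generate a planted-partition PPI network
#'
#' Within-module gene pairs are connected with probability `p_in`, all other
#' pairs with `p_out`; edges are drawn independently and deterministically
#' for a given seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `network` (a [ppi_network()]) and `truth` (class
#'   `ground_truth`: tibble `gene`, `module` (NA = background), `disease`
#'   flag).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seeds <- spec_seeds(spec)
  n <- spec$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  out <- with_seed(seeds$network, {
    lo <- spec$module_size_range[1L]; hi <- spec$module_size_range[2L]
    sizes <- if (lo == hi) rep(lo, spec$n_modules) else {
      s <- sample(lo:hi, spec$n_modules, replace = TRUE)
      # trim uniformly if the draw exceeds the gene budget
      while (sum(s) > n) s[which.max(s)] <- s[which.max(s)] - 1L
      s
    }
    module <- rep(NA_integer_, n)
    module[seq_len(sum(sizes))] <- rep(seq_len(spec$n_modules), sizes)
    disease_modules <- sort(sample(spec$n_modules, spec$n_disease_modules))

    pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
    same <- !is.na(module[pr[, 1L]]) & !is.na(module[pr[, 2L]]) &
      module[pr[, 1L]] == module[pr[, 2L]]
    p <- ifelse(same, spec$p_in, spec$p_out)
    if (!is.null(spec$degree_exponent)) {
      w <- (seq_len(n))^(-spec$degree_exponent)
      w <- sample(w) / mean(w)
      p <- pmin(1, p * sqrt(w[pr[, 1L]] * w[pr[, 2L]]))
    }
    keep <- runif(length(p)) < p
    g <- igraph::graph_from_data_frame(
      data.frame(a = genes[pr[keep, 1L]], b = genes[pr[keep, 2L]],
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = genes, stringsAsFactors = FALSE)
    )
    list(g = g, module = module, disease_modules = disease_modules)
  })
  truth <- tibble::tibble(
    gene = genes,
    module = out$module,
    disease = !is.na(out$module) & out$module %in% out$disease_modules
  )
  class(truth) <- c("ground_truth", class(truth))
  list(network = ppi_network(out$g), truth = truth)
}

#' Generate class-conditional Gaussian expression over a synthetic network
#'
#' Background genes are `N(0, sigma^2)` in both phenotypes; disease-module
#' genes are `N(delta * sigma, sigma^2)` in phenotype 1 and `N(0, sigma^2)`
#' in phenotype 2, with independent per-gene noise.
#'
#' @param truth Ground truth from [generate_network()].
#' @param spec The same [synthetic_spec()].
#' @return An [expression_dataset()] with labels
#'   `(1, ..., 1, 2, ..., 2)`.
#' @export
generate_expression <- function(truth, spec) {
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "synthetic_spec"))
  seeds <- spec_seeds(spec)
  n <- nrow(truth); m <- 2L * spec$n_per_class
  labels <- rep(c(1L, 2L), each = spec$n_per_class)
  vals <- with_seed(seeds$expression, {
    x <- matrix(rnorm(n * m, 0, spec$noise_sigma), n, m)
    shift <- ifelse(truth$disease, spec$delta * spec$noise_sigma, 0)
    x[, labels == 1L] <- x[, labels == 1L] + shift
    x
  })
  dimnames(vals) <- list(truth$gene, sprintf("s%03d", seq_len(m)))
  expression_dataset(vals, labels)
}

#' Generate a complete synthetic benchmark instance
#'
#' Convenience wrapper: network + expression + identity overlay, so the
#' result can be fed straight into [discover_markers()].
#'
#' @param spec A [synthetic_spec()].
#' @return List with `induced` (an overlay-ready `induced_dataset`),
#'   `network`, `expression`, `truth`, and `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  net <- generate_network(spec)
  expr <- generate_expression(net$truth, spec)
  induced <- suppressMessages(overlay(expr, net$network))
  list(induced = induced, network = net$network, expression = expr,
       truth = net$truth, spec = spec)
}

#' Write a synthetic instance to the standard file formats
#'
#' Exercises the public file interfaces: expression TSV + label TSV +
#' edge-list TSV + ground-truth JSON.
#'
#' @param synth A [generate_synthetic()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_synthetic <- function(synth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  lab_path <- file.path(dir, "labels.tsv")
  net_path <- file.path(dir, "network.tsv")
  truth_path <- file.path(dir, "truth.json")
  vals <- synth$expression$values
  utils::write.table(
    data.frame(gene_id = rownames(vals), vals, check.names = FALSE),
    expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(vals), phenotype = synth$expression$labels),
    lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  el <- igraph::as_edgelist(synth$network$graph)
  utils::write.table(el, net_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(synth$truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(expression = expr_path, labels = lab_path,
              network = net_path, truth = truth_path))
}

#' Ground-truth recovery of a marker set
#'
#' Jaccard overlap between the union of marker member genes and the union
#' of planted disease-module genes.
#'
#' @param markers A `marker_set`.
#' @param truth Ground truth from [generate_network()].
#' @return A fraction in `[0, 1]`.
#' @export
recovery_score <- function(markers, truth) {
  stopifnot(inherits(markers, "marker_set"), inherits(truth, "ground_truth"))
  found <- unique(unlist(markers$genes))
  target <- truth$gene[truth$disease]
  if (length(found) == 0L && length(target) == 0L) return(1)
  length(intersect(found, target)) / length(union(found, target))
}
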