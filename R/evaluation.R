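#' Marker set size statistics
#'
#' @param markers A `marker_set`.
#' @return Tibble with `n_markers`, `mean_size` (arithmetic mean of member
#'   counts), and `unique_genes` (cardinality of the union of members).
#' @export
marker_size_stats <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  if (nrow(markers) == 0L) stop_subnetap("marker set is empty.", "empty")
  tibble::tibble(
    n_markers = nrow(markers),
    mean_size = mean(lengths(markers$genes)),
    unique_genes = length(unique(unlist(markers$genes)))
  )
}

#' Gene-level overlap between two marker sets
#'
#' Measures reproducibility of markers discovered on independent datasets
#' as the overlap of the unions of member genes: Jaccard
#' \eqn{|U_A \cap U_B| / |U_A \cup U_B|} by default, or containment
#' \eqn{|U_A \cap U_B| / \min(|U_A|, |U_B|)}.
#'
#' @param markers_a,markers_b `marker_set` objects.
#' @param method `"jaccard"` (default) or `"containment"`.
#' @return A fraction in `[0, 1]`.
#' @export
marker_overlap <- function(markers_a, markers_b, method = c("jaccard", "containment")) {
  method <- match.arg(method)
  stopifnot(inherits(markers_a, "marker_set"), inherits(markers_b, "marker_set"))
  if (nrow(markers_a) == 0L || nrow(markers_b) == 0L) {
    stop_subnetap("both marker sets must be non-empty.", "empty")
  }
  ua <- unique(unlist(markers_a$genes))
  ub <- unique(unlist(markers_b$genes))
  common <- length(intersect(ua, ub))
  if (method == "jaccard") {
    common / length(union(ua, ub))
  } else {
    common / min(length(ua), length(ub))
  }
}

#' Discriminative-power curve of a ranked marker set
#'
#' Mean of the top-K absolute activity t scores, for each K. With rank-
#' sorted markers the curve is non-increasing in K.
#'
#' @param markers A ranked `marker_set`.
#' @param ks Integer vector of K values; default `c(10, 20, 30, 40, 50)`.
#' @return Tibble with columns `k`, `mean_abs_t`.
#' @export
dp_curve <- function(markers, ks = c(10L, 20L, 30L, 40L, 50L)) {
  stopifnot(inherits(markers, "marker_set"))
  tt <- abs(markers$t_score)
  purrr::map_dfr(as.integer(ks), function(k) {
    if (k > length(tt)) {
      warn_subnetap(paste0("K = ", k, " exceeds available markers (",
                           length(tt), "); truncated"), "k_truncated")
      k <- length(tt)
    }
    tibble::tibble(k = k, mean_abs_t = mean(tt[seq_len(k)]))
  })
}

#' Re-score markers on a second dataset, keeping the discovery ranking
#'
#' Recomputes each marker's activity and absolute t score on an independent
#' dataset: LLR parameters are re-fit on the second dataset's samples,
#' member genes absent there are dropped per marker (logged), and markers
#' losing all genes are removed (logged). The discovery ordering is kept,
#' so the per-K means measure how well the original ranking transfers.
#'
#' @param markers A ranked `marker_set` discovered on dataset A.
#' @param expr An [expression_dataset()] (dataset B).
#' @param ks Integer K grid, default `c(10, 20, 30, 40, 50)`.
#' @return List with `per_marker` (tibble `marker_id`, `t_score_b`,
#'   `n_genes_used`) and `curve` (tibble `k`, `mean_abs_t`).
#' @export
cross_dataset_dp <- function(markers, expr, ks = c(10L, 20L, 30L, 40L, 50L)) {
  stopifnot(inherits(markers, "marker_set"), inherits(expr, "expression_dataset"))
  L <- llr_matrix(expr)
  avail <- rownames(L)
  kept_genes <- lapply(markers$genes, intersect, avail)
  dropped <- sum(lengths(markers$genes) - lengths(kept_genes))
  if (dropped > 0L) message(dropped, " member gene(s) absent in the evaluation dataset; dropped")
  keep <- lengths(kept_genes) > 0L
  if (any(!keep)) message(sum(!keep), " marker(s) lost all genes; dropped")
  if (!any(keep)) stop_subnetap("no marker retains any gene in the evaluation dataset.", "empty")
  kept_genes <- kept_genes[keep]
  tb <- vapply(kept_genes, function(g) {
    t_score(subnetwork_activity(g, L), expr$labels)
  }, numeric(1))
  per_marker <- tibble::tibble(
    marker_id = markers$marker_id[keep],
    t_score_b = as.numeric(tb),
    n_genes_used = lengths(kept_genes)
  )
  tt <- abs(per_marker$t_score_b)
  curve <- purrr::map_dfr(as.integer(ks), function(k) {
    kk <- min(k, length(tt))
    tibble::tibble(k = kk, mean_abs_t = mean(tt[seq_len(kk)]))
  })
  list(per_marker = per_marker, curve = curve)
}

#' Cross-validation protocol
#'
#' @param folds Number of folds; default 5.
#' @param repeats Number of random partitions; default 100.
#' @param seed Seed for fold assignment.
#' @param stratified Preserve class proportions per fold (default `TRUE`).
#' @return A list of class `cv_protocol`.
#' @export
cv_protocol <- function(folds = 5L, repeats = 100L, seed = 1L, stratified = TRUE) {
  folds <- as.integer(folds); repeats <- as.integer(repeats)
  if (folds < 2L) stop_subnetap("need >= 2 folds.", "bad_config")
  if (repeats < 1L) stop_subnetap("need >= 1 repeat.", "bad_config")
  structure(list(folds = folds, repeats = repeats, seed = as.integer(seed),
                 stratified = stratified),
            class = "cv_protocol")
}

# fold assignment for one repeat; stratified keeps class balance
make_folds <- function(labels, folds, stratified) {
  n <- length(labels)
  f <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    f[sample(n)] <- rep_len(seq_len(folds), n)
  }
  f
}

#' Area under the ROC curve from decision scores
#'
#' Exact rank (Mann-Whitney) AUC of `scores` for separating phenotype 1
#' (positive) from phenotype 2, with the midrank tie correction. Fixed
#' score direction: larger scores favour phenotype 1.
#'
#' @param scores Numeric decision scores.
#' @param labels Phenotype vector in `{1, 2}`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]; neg <- scores[labels == 2L]
  n1 <- length(pos); n2 <- length(neg)
  if (n1 == 0L || n2 == 0L) stop_subnetap("need both phenotypes to compute AUC.", "bad_input")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# LDA decision scores for held-out samples; falls back to a shrunken
# diagonal discriminant when the pooled covariance is singular
lda_scores <- function(x_train, y_train, x_test) {
  fit <- tryCatch(
    suppressWarnings(MASS::lda(x_train, grouping = factor(y_train, levels = c(1L, 2L)))),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    sc <- tryCatch(
      stats::predict(fit, x_test)$posterior[, "1"],
      error = function(e) NULL
    )
    if (!is.null(sc)) return(as.numeric(sc))
  }
  diag_lda_scores(x_train, y_train, x_test)
}

# diagonal LDA with variances shrunk toward their mean; shrinkage intensity
# p / (p + n_train) (fixed small-sample rule)
diag_lda_scores <- function(x_train, y_train, x_test) {
  p <- ncol(x_train); n <- nrow(x_train)
  i1 <- y_train == 1L; i2 <- y_train == 2L
  m1 <- colMeans(x_train[i1, , drop = FALSE])
  m2 <- colMeans(x_train[i2, , drop = FALSE])
  v1 <- apply(x_train[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(x_train[i2, , drop = FALSE], 2L, stats::var)
  vp <- ((sum(i1) - 1) * v1 + (sum(i2) - 1) * v2) / (n - 2)
  gamma <- p / (p + n)
  vp <- (1 - gamma) * vp + gamma * mean(vp)
  vp <- pmax(vp, 1e-12)
  w <- (m1 - m2) / vp
  as.numeric(x_test %*% w)
}

#' Repeated stratified cross-validated LDA classification AUC
#'
#' For each repeat the samples are split into stratified folds; an LDA
#' classifier is trained on the activity features of the training folds and
#' scores the held-out fold. The repeat's AUC is computed from the pooled
#' out-of-fold scores, and the mean (with dispersion) over repeats is
#' reported.
#'
#' @param activities Activity matrix, features (subnetworks) in rows and
#'   samples in columns (as produced by [activity_matrix()]), or its
#'   transpose with samples in rows.
#' @param labels Phenotype vector in `{1, 2}`.
#' @param protocol A [cv_protocol()].
#' @return List of class `cv_auc` with `mean_auc`, `sd_auc`, and
#'   `per_repeat` (tibble `repeat`, `auc`).
#' @export
lda_auc_cv <- function(activities, labels, protocol = cv_protocol()) {
  stopifnot(inherits(protocol, "cv_protocol"))
  labels <- as.integer(labels)
  x <- if (ncol(activities) == length(labels)) t(activities) else activities
  if (nrow(x) != length(labels)) {
    stop_subnetap("activity matrix does not match the label vector.", "bad_input")
  }
  if (min(table(labels)) < protocol$folds) {
    stop_subnetap("need at least `folds` samples per phenotype.", "few_samples")
  }
  aucs <- with_seed(protocol$seed, {
    vapply(seq_len(protocol$repeats), function(rep_i) {
      f <- make_folds(labels, protocol$folds, protocol$stratified)
      scores <- numeric(length(labels))
      for (fold in seq_len(protocol$folds)) {
        te <- f == fold
        scores[te] <- lda_scores(x[!te, , drop = FALSE], labels[!te],
                                 x[te, , drop = FALSE])
      }
      auc_score(scores, labels)
    }, numeric(1))
  })
  structure(
    list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
         per_repeat = tibble::tibble(rep = seq_along(aucs), auc = aucs)),
    class = "cv_auc"
  )
}

#' @export
print.cv_auc <- function(x, ...) {
  cat("<cv_auc> mean AUC = ", format(x$mean_auc, digits = 4),
      " (sd ", format(x$sd_auc, digits = 3), " over ",
      nrow(x$per_repeat), " repeats)\n", sep = "")
  invisible(x)
}

# cross-validated AUC of a marker set on an expression dataset with LLR
# parameters re-fit on each training fold (no test-sample leakage into the
# activity features)
marker_cv_auc <- function(markers, expr, protocol = cv_protocol()) {
  stopifnot(inherits(markers, "marker_set"), inherits(expr, "expression_dataset"))
  labels <- expr$labels
  vals <- expr$values
  gene_sets <- lapply(markers$genes, intersect, rownames(vals))
  gene_sets <- gene_sets[lengths(gene_sets) > 0L]
  if (length(gene_sets) == 0L) stop_subnetap("no marker gene is measured in this dataset.", "empty")
  aucs <- with_seed(protocol$seed, {
    vapply(seq_len(protocol$repeats), function(rep_i) {
      f <- make_folds(labels, protocol$folds, protocol$stratified)
      scores <- numeric(length(labels))
      for (fold in seq_len(protocol$folds)) {
        te <- f == fold
        p <- row_class_params(vals[, !te, drop = FALSE], labels[!te])
        L <- log(p$sigma2 / p$sigma1) +
          (vals - p$mu2)^2 / (2 * p$sigma2^2) -
          (vals - p$mu1)^2 / (2 * p$sigma1^2)
        act <- t(vapply(gene_sets, function(g) colSums(L[g, , drop = FALSE]),
                        numeric(ncol(L))))
        scores[te] <- lda_scores(t(act[, !te, drop = FALSE]), labels[!te],
                                 t(act[, te, drop = FALSE]))
      }
      auc_score(scores, labels)
    }, numeric(1))
  })
  structure(
    list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
         per_repeat = tibble::tibble(rep = seq_along(aucs), auc = aucs)),
    class = "cv_auc"
  )
}

#' Full cross-dataset evaluation of discovered markers
#'
#' Runs marker discovery on the discovery dataset, then evaluates the
#' resulting top-K markers on an independent evaluation dataset: activities
#' are recomputed there (LLR parameters re-fit on each training fold) and
#' classification performance measured by repeated stratified
#' cross-validated LDA.
#'
#' @param discovery An [overlay()] result (induced dataset) used for marker
#'   discovery, or a pre-computed `marker_set` (skips discovery).
#' @param evaluation An [overlay()] result or [expression_dataset()] used
#'   for training and evaluating the classifier.
#' @param config A [run_config()] controlling discovery.
#' @param protocol A [cv_protocol()] for the evaluation CV.
#' @return An object of class `eval_report`: list with `markers`,
#'   `size_stats`, `dp_curve` (on the evaluation dataset, discovery
#'   ranking), `cv` (a `cv_auc`), and `config`.
#' @export
cross_dataset_eval <- function(discovery, evaluation, config = run_config(),
                               protocol = cv_protocol(seed = config$seed)) {
  eval_expr <- if (inherits(evaluation, "induced_dataset")) evaluation$expression else evaluation
  stopifnot(inherits(eval_expr, "expression_dataset"))
  if (inherits(discovery, "marker_set")) {
    markers <- discovery
  } else {
    markers <- discover_markers(discovery, config = config)$markers
  }
  cdp <- cross_dataset_dp(markers, eval_expr)
  cv <- marker_cv_auc(markers, eval_expr, protocol = protocol)
  structure(
    list(markers = markers,
         size_stats = marker_size_stats(markers),
         dp_curve = cdp$curve,
         per_marker = cdp$per_marker,
         cv = cv,
         config = if (inherits(discovery, "marker_set")) marker_meta(markers) else config),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n  markers: ", nrow(x$markers),
      " (mean size ", format(x$size_stats$mean_size, digits = 4),
      ", ", x$size_stats$unique_genes, " unique genes)\n",
      "  mean AUC: ", format(x$cv$mean_auc, digits = 4),
      " (sd ", format(x$cv$sd_auc, digits = 3), ")\n", sep = "")
  invisible(x)
}
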