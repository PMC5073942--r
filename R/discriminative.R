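#' Fit per-phenotype Gaussian parameters for one gene
#'
#' Estimates the class-conditional Gaussian of a gene's expression under each
#' phenotype: sample mean and standard deviation (denominator n-1) per class.
#' Standard deviations are floored at
#' `max(1e-3 * pooled SD across all samples, 1e-6)` so that degenerate
#' (constant) classes cannot produce infinite log-likelihood ratios.
#'
#' @param values Numeric vector of one gene's expression across samples.
#' @param labels Phenotype vector in `{1, 2}`, same length.
#' @return A list of class `gaussian_class_params` with `mu1`, `sigma1`,
#'   `mu2`, `sigma2`.
#' @export
#' @examples
#' fit_class_gaussians(c(0, 0, 1, 1), c(1, 1, 2, 2))
fit_class_gaussians <- function(values, labels) {
  labels <- as.integer(labels)
  if (length(values) != length(labels)) {
    stop_subnetap("`values` and `labels` lengths differ.", "bad_input")
  }
  n1 <- sum(labels == 1L); n2 <- sum(labels == 2L)
  if (n1 < 2L || n2 < 2L) {
    stop_subnetap("each phenotype needs at least 2 samples.", "few_samples")
  }
  floor_sd <- max(1e-3 * stats::sd(values), 1e-6)
  x1 <- values[labels == 1L]; x2 <- values[labels == 2L]
  structure(
    list(mu1 = mean(x1), sigma1 = max(stats::sd(x1), floor_sd),
         mu2 = mean(x2), sigma2 = max(stats::sd(x2), floor_sd)),
    class = "gaussian_class_params"
  )
}

#' Gaussian log-likelihood ratio of an expression value
#'
#' \eqn{\lambda(x) = \log[f^1(x) / f^2(x)]} where \eqn{f^j} is the fitted
#' class-conditional Gaussian density under phenotype `j`. Positive values
#' favour phenotype 1.
#'
#' @param x Numeric expression value(s).
#' @param p A [fit_class_gaussians()] result.
#' @return Numeric LLR, same length as `x`; identically 0 when the two class
#'   distributions coincide.
#' @export
llr <- function(x, p) {
  stopifnot(inherits(p, "gaussian_class_params"))
  log(p$sigma2 / p$sigma1) +
    (x - p$mu2)^2 / (2 * p$sigma2^2) -
    (x - p$mu1)^2 / (2 * p$sigma1^2)
}

# per-gene class params for a whole matrix, vectorised; returns a list of
# column vectors aligned with rows of `values`
row_class_params <- function(values, labels) {
  labels <- as.integer(labels)
  i1 <- labels == 1L; i2 <- labels == 2L
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop_subnetap("each phenotype needs at least 2 samples.", "few_samples")
  mu1 <- rowMeans(values[, i1, drop = FALSE])
  mu2 <- rowMeans(values[, i2, drop = FALSE])
  v1 <- rowSums((values[, i1, drop = FALSE] - mu1)^2) / (n1 - 1)
  v2 <- rowSums((values[, i2, drop = FALSE] - mu2)^2) / (n2 - 1)
  mu_all <- rowMeans(values)
  v_all <- rowSums((values - mu_all)^2) / (ncol(values) - 1)
  floor_sd <- pmax(1e-3 * sqrt(v_all), 1e-6)
  list(mu1 = mu1, sigma1 = pmax(sqrt(v1), floor_sd),
       mu2 = mu2, sigma2 = pmax(sqrt(v2), floor_sd),
       n1 = n1, n2 = n2)
}

#' Per-gene LLR profiles for a whole expression dataset
#'
#' Fits the two class Gaussians of every gene and evaluates the
#' log-likelihood ratio of every expression value, giving the genes-by-samples
#' LLR matrix that all downstream similarity and activity computations
#' consume.
#'
#' @param values Genes-by-samples numeric matrix (or an
#'   [expression_dataset()]).
#' @param labels Phenotype vector in `{1, 2}`; taken from the dataset when
#'   `values` is an `expression_dataset`.
#' @return Numeric matrix of \eqn{\lambda(x_{i})}, same shape and dimnames
#'   as the input matrix.
#' @export
llr_matrix <- function(values, labels = NULL) {
  if (inherits(values, "expression_dataset")) {
    labels <- labels %||% values$labels
    values <- values$values
  }
  p <- row_class_params(values, labels)
  out <- log(p$sigma2 / p$sigma1) +
    (values - p$mu2)^2 / (2 * p$sigma2^2) -
    (values - p$mu1)^2 / (2 * p$sigma1^2)
  dimnames(out) <- dimnames(values)
  out
}

#' Two-sample t statistic between phenotypes
#'
#' Computes the phenotype-1-minus-phenotype-2 t statistic of a feature
#' (a gene's LLR profile, or a subnetwork activity vector). The Welch form
#' (unequal variances) is the default; `"pooled"` gives the classical
#' equal-variance statistic. Group variances are floored at `1e-6` and the
#' magnitude is capped at `1e3`, so degenerate (zero-variance) inputs yield
#' a large finite score instead of infinity.
#'
#' @param values Numeric feature vector across samples.
#' @param labels Phenotype vector in `{1, 2}`.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A single t score; 0 when both groups are constant with equal
#'   means.
#' @export
#' @examples
#' t_score(c(1, 1, 0, 0), c(1, 1, 2, 2))  # ~1000: variance-floored, capped
t_score <- function(values, labels, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  labels <- as.integer(labels)
  x1 <- values[labels == 1L]; x2 <- values[labels == 2L]
  if (length(x1) < 2L || length(x2) < 2L) {
    stop_subnetap("each phenotype needs at least 2 samples.", "few_samples")
  }
  m1 <- mean(x1); m2 <- mean(x2)
  v1 <- max(stats::var(x1), 1e-6); v2 <- max(stats::var(x2), 1e-6)
  n1 <- length(x1); n2 <- length(x2)
  if (variant == "welch") {
    se <- sqrt(v1 / n1 + v2 / n2)
  } else {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(vp * (1 / n1 + 1 / n2))
  }
  t <- (m1 - m2) / se
  if (!is.finite(t)) t <- 0
  max(min(t, 1e3), -1e3)
}

# vectorised t over matrix rows; same floors/cap as t_score()
row_t_scores <- function(values, labels, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  labels <- as.integer(labels)
  i1 <- labels == 1L; i2 <- labels == 2L
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(values[, i1, drop = FALSE])
  m2 <- rowMeans(values[, i2, drop = FALSE])
  v1 <- pmax(rowSums((values[, i1, drop = FALSE] - m1)^2) / (n1 - 1), 1e-6)
  v2 <- pmax(rowSums((values[, i2, drop = FALSE] - m2)^2) / (n2 - 1), 1e-6)
  if (variant == "welch") {
    se <- sqrt(v1 / n1 + v2 / n2)
  } else {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(vp * (1 / n1 + 1 / n2))
  }
  t <- (m1 - m2) / se
  t[!is.finite(t)] <- 0
  pmax(pmin(t, 1e3), -1e3)
}

#' Discriminative-power similarity between two genes
#'
#' The directed similarity
#' \deqn{s_{DP}(i,k) = t_k + \min\{t_{ik} - t_i,\; t_{ik} - t_k\} - \alpha |t_i - t_k|}
#' where \eqn{t_i, t_k} are the t scores of each gene's LLR profile,
#' \eqn{t_{ik}} is the t score of the per-sample sum of the two LLR profiles,
#' and \eqn{\alpha \in [0,1]} penalises genes of unequal discriminative
#' power. The expression rewards a discriminative candidate exemplar `k`
#' whose pairing with `i` improves joint discrimination; it is asymmetric in
#' `(i, k)` by design (the leading term is \eqn{t_k}), which affinity
#' propagation exploits.
#'
#' By default the t scores entering the formula are magnitudes
#' (absolute values); pass signed scores to explore the signed variant.
#' All arguments are vectorised.
#'
#' @param t_i,t_k t score of gene `i` / gene `k` (LLR profile).
#' @param t_ik t score of the summed LLR profile of the pair.
#' @param alpha Penalty weight in `[0, 1]`.
#' @return Numeric similarity (possibly negative).
#' @export
#' @examples
#' dp_similarity(2, 3, 4, alpha = 0.5)  # 3 + min(2, 1) - 0.5 = 3.5
dp_similarity <- function(t_i, t_k, t_ik, alpha = 0.5) {
  if (any(alpha < 0 | alpha > 1)) stop_subnetap("`alpha` must lie in [0, 1].", "bad_alpha")
  t_k + pmin(t_ik - t_i, t_ik - t_k) - alpha * abs(t_i - t_k)
}
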