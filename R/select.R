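# Attribute ranking: four evaluators paired with a "Ranker"-style ordering.
# All return a `ranked_attributes` table: attribute, score, rank (best
# first); ties break deterministically toward the lower attribute index.

new_ranking <- function(scores, attributes, method) {
  ord <- order(-scores, seq_along(scores))
  out <- data.frame(attribute = attributes[ord], score = scores[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(list(ranking = out, method = method,
                 scores = stats::setNames(scores, attributes)),
            class = "ranked_attributes")
}

#' @export
print.ranked_attributes <- function(x, n = 10, ...) {
  cat(sprintf("<ranked_attributes> method = %s\n", x$method))
  print(utils::head(x$ranking, n), row.names = FALSE)
  invisible(x)
}

rank_input_check <- function(features, labels) {
  features <- as.data.frame(features)
  if (length(labels) != nrow(features))
    stop_input("labels length must match the number of rows")
  y <- factor(labels)
  if (nlevels(y) < 2L) stop_input("need at least two classes")
  if (nrow(features) < 3L) stop_input("need at least three instances")
  list(x = features, y = y)
}

#' Correlation-based attribute ranking
#'
#' Scores each attribute by the class-frequency-weighted mean of the absolute
#' Pearson correlation between the attribute and each one-vs-rest class
#' indicator. Zero-variance attributes score 0.
#'
#' @param features n x p numeric table.
#' @param labels class labels.
#' @return a `ranked_attributes` object.
#' @export
correlation_rank <- function(features, labels) {
  d <- rank_input_check(features, labels)
  freqs <- table(d$y) / length(d$y)
  scores <- vapply(d$x, function(col) {
    if (stats::sd(col) == 0) return(0)
    s <- vapply(levels(d$y), function(cl) {
      ind <- as.numeric(d$y == cl)
      if (stats::sd(ind) == 0) return(0)
      abs(stats::cor(col, ind))
    }, numeric(1))
    sum(freqs * s)
  }, numeric(1))
  new_ranking(scores, colnames(d$x), "correlation")
}

# Equal-frequency discretization; collapses duplicate quantile breaks and
# reduces the bin count (with a warning) when n < n_bins.
discretize_ef <- function(col, n_bins, n) {
  if (stats::sd(col) == 0) return(NULL)
  if (n < n_bins) {
    warning(sprintf("only %d instances; reducing bins from %d", n, n_bins))
    n_bins <- max(2L, n)
  }
  br <- unique(stats::quantile(col, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3L) br <- c(-Inf, mean(range(col)), Inf)
  cut(col, breaks = br, include.lowest = TRUE)
}

chi2_stat <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

#' Chi-squared attribute ranking
#'
#' Discretizes each attribute into equal-frequency bins (default 10) and
#' scores it by the chi-squared statistic of the bin-by-class contingency
#' table. Constant attributes score 0.
#'
#' @inheritParams correlation_rank
#' @param n_bins number of equal-frequency bins.
#' @return a `ranked_attributes` object.
#' @export
chi2_rank <- function(features, labels, n_bins = 10) {
  d <- rank_input_check(features, labels)
  scores <- vapply(d$x, function(col) {
    b <- discretize_ef(col, n_bins, nrow(d$x))
    if (is.null(b)) return(0)
    chi2_stat(table(b, d$y))
  }, numeric(1))
  new_ranking(scores, colnames(d$x), "chi2")
}

#' Probabilistic significance attribute ranking
#'
#' Two-way association on the discretized bin-by-class table: the average of
#' (a) how much the attribute's bin distribution differs between classes
#' (mean total-variation distance between `P(bin | class)` over class pairs)
#' and (b) how much the class distribution differs between bins (mean
#' total-variation distance between `P(class | bin)` over bin pairs). A
#' perfectly class-determining attribute scores 1; a constant attribute 0.
#'
#' @inheritParams chi2_rank
#' @return a `ranked_attributes` object.
#' @export
significance_rank <- function(features, labels, n_bins = 10) {
  d <- rank_input_check(features, labels)
  tv <- function(p, q) 0.5 * sum(abs(p - q))
  pairwise_mean_tv <- function(mat) {   # columns are distributions
    k <- ncol(mat)
    if (k < 2L) return(0)
    pairs <- utils::combn(k, 2)
    mean(apply(pairs, 2, function(ij) tv(mat[, ij[1]], mat[, ij[2]])))
  }
  scores <- vapply(d$x, function(col) {
    b <- discretize_ef(col, n_bins, nrow(d$x))
    if (is.null(b)) return(0)
    tab <- table(b, d$y)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L) return(0)
    p_bin_class <- sweep(tab, 2, pmax(colSums(tab), 1), "/")   # P(bin | class)
    p_class_bin <- t(sweep(tab, 1, pmax(rowSums(tab), 1), "/")) # P(class | bin)
    (pairwise_mean_tv(p_bin_class) + pairwise_mean_tv(p_class_bin)) / 2
  }, numeric(1))
  new_ranking(scores, colnames(d$x), "significance")
}

#' PCA loading-priority attribute ranking
#'
#' The five-step procedure: (1) compute the attribute correlation matrix,
#' (2) eigendecompose it, (3) sort eigenvalues in decreasing order (each is
#' the variance share of its component), (4) keep the leading
#' `n_components`, (5) score each attribute by the eigenvalue-weighted sum of
#' its absolute loadings over those components. Working on the correlation
#' (not covariance) matrix makes the ranking invariant to per-attribute
#' rescaling. Zero-variance attributes are excluded from the decomposition
#' and ranked last with score 0.
#'
#' @param features n x p numeric table.
#' @param n_components number of leading components to use; default is the
#'   Kaiser rule (eigenvalues above 1, at least 1 component).
#' @return a `ranked_attributes` object.
#' @export
pca_rank <- function(features, n_components = NULL) {
  x <- as.data.frame(features)
  if (ncol(x) < 2L) stop_input("need at least two attributes")
  sds <- vapply(x, stats::sd, numeric(1))
  keep <- sds > 0
  scores <- stats::setNames(numeric(ncol(x)), colnames(x))
  lam <- numeric(0)
  if (sum(keep) >= 2L) {
    cm <- stats::cor(as.matrix(x[, keep, drop = FALSE]))
    eg <- eigen(cm, symmetric = TRUE)
    lam <- eg$values
    if (is.null(n_components)) n_components <- max(1L, sum(lam > 1))
    n_components <- min(n_components, length(lam))
    idx <- seq_len(n_components)
    s <- abs(eg$vectors[, idx, drop = FALSE]) %*% lam[idx]
    scores[keep] <- as.numeric(s)
  }
  rk <- new_ranking(scores, colnames(x), "pca")
  rk$eigenvalues <- lam
  rk
}

#' Run all four attribute rankers
#'
#' Convenience wrapper applying [correlation_rank()], [chi2_rank()],
#' [pca_rank()] and [significance_rank()] to the same table.
#'
#' @inheritParams chi2_rank
#' @return named list of `ranked_attributes`.
#' @export
rank_attributes_all <- function(features, labels, n_bins = 10) {
  list(correlation = correlation_rank(features, labels),
       chi2 = chi2_rank(features, labels, n_bins),
       pca = pca_rank(features),
       significance = significance_rank(features, labels, n_bins))
}
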