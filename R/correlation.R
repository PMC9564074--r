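#' Spearman correlation matrix with pairwise significance
#'
#' Computes the full Spearman rank-correlation matrix of a samples-by-features
#' table together with elementwise two-sided p-values. Ties receive average
#' (mid-) ranks; rho is the Pearson correlation of the midranks. The p-value
#' uses the t approximation with `n - 2` degrees of freedom,
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`, the standard choice for the small
#' group sizes of animal studies.
#'
#' Features whose variance is at or below `min_variance` carry no rank
#' information and are excluded; their names are returned in `dropped` and a
#' warning is issued.
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param min_variance Variance threshold below which a feature is dropped
#'   (default 0: only constant features go).
#' @return An object of class `correlation_result`: list with `rho` and
#'   `pvalue` (symmetric matrices over the retained features; `diag(rho) = 1`,
#'   `diag(pvalue) = 0` by convention), `features`, `dropped`, `n_samples`.
#' @export
spearman_matrix <- function(x, min_variance = 0) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples for a correlation network")
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  v <- apply(x, 2, stats::var)
  drop <- v <= min_variance | !is.finite(v)
  if (all(drop)) stop("all features are constant; no correlations are defined")
  if (any(drop)) {
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    sum(drop), paste(colnames(x)[drop], collapse = ", ")))
  }
  kept <- x[, !drop, drop = FALSE]
  ranks <- apply(kept, 2, rank)          # midranks for ties
  rho <- stats::cor(ranks)               # Pearson on midranks = Spearman
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval[abs(rho) >= 1 - 1e-15] <- 0
  diag(rho) <- 1
  diag(pval) <- 0
  structure(list(rho = rho, pvalue = pval,
                 features = colnames(kept),
                 dropped = colnames(x)[drop],
                 n_samples = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: %d features, n = %d samples (%d dropped)\n",
              length(x$features), x$n_samples, length(x$dropped)))
  invisible(x)
}

#' Significance-filtered correlation graph
#'
#' Builds the undirected co-occurrence network: an edge joins features `i`
#' and `j` iff their correlation p-value is below `alpha`; the edge weight is
#' the absolute correlation `|rho|` (only the magnitude of association
#' enters the network). Isolated features remain in the node set.
#'
#' @param corr A `correlation_result` from [spearman_matrix()].
#' @param alpha Retention threshold on the raw p-value (default 0.05). No
#'   multiple-testing correction is applied at this stage.
#' @return An [igraph::igraph] with vertex attribute `name` and edge
#'   attributes `weight` (`|rho|`), `rho` and `p`.
#' @export
build_graph <- function(corr, alpha = 0.05) {
  stopifnot(inherits(corr, "correlation_result"), alpha > 0, alpha <= 1)
  keep <- corr$pvalue < alpha
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    from = corr$features[idx[, 1]],
    to = corr$features[idx[, 2]],
    weight = abs(corr$rho[idx]),
    rho = corr$rho[idx],
    p = corr$pvalue[idx]
  )
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = corr$features))
}

#' Graph edge list as a data frame
#'
#' @param graph A correlation graph from [build_graph()] or
#'   [multiomic_graph()].
#' @return Data frame with `from`, `to` and all edge attributes.
#' @export
edge_table <- function(graph) {
  igraph::as_data_frame(graph, what = "edges")
}

#' Spectral clustering of a weighted correlation graph
#'
#' Clusters network nodes by normalized spectral clustering: the embedding is
#' formed from the `k` smallest eigenvectors of the symmetric normalized
#' Laplacian `L = I - D^{-1/2} A D^{-1/2}` of the weighted adjacency, rows
#' are normalized to unit length, and k-means (with a fixed seed and
#' multiple restarts) assigns the labels. Isolated nodes have no degree and
#' sit at the origin of the embedding; they are assigned deterministically to
#' whichever cluster center is nearest the origin.
#'
#' @param graph Correlation graph ([build_graph()]).
#' @param k Number of clusters (`k >= 2`); use [choose_k_eigengap()] when the
#'   number of communities is unknown.
#' @param seed Integer seed for the k-means step.
#' @return Integer vector of cluster labels in `0:(k-1)`, named by node.
#' @export
spectral_clusters <- function(graph, k, seed = 1L) {
  n <- igraph::vcount(graph)
  if (k > n) stop("k exceeds the number of nodes")
  if (k < 2) stop("k must be at least 2")
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight", sparse = TRUE))
  deg <- rowSums(A)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(n) - (inv_sqrt * A) * rep(inv_sqrt, each = n)
  eig <- eigen(L, symmetric = TRUE)
  U <- eig$vectors[, n - seq_len(k) + 1, drop = FALSE]  # k smallest
  norms <- sqrt(rowSums(U^2))
  U <- U / ifelse(norms > 0, norms, 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = 25, iter.max = 100)
  labels <- km$cluster - 1L
  names(labels) <- igraph::V(graph)$name
  labels
}

#' Eigengap heuristic for the number of spectral clusters
#'
#' Picks `k` as the position of the largest gap in the ascending eigenvalues
#' of the symmetric normalized Laplacian, searched over `2:k_max`. With
#' well-separated communities the first `k` eigenvalues are near 0 and the
#' `(k+1)`-th jumps away.
#'
#' @param graph Correlation graph.
#' @param k_max Largest k considered (default 10, capped at `n - 1`).
#' @return Integer `k >= 2`.
#' @export
choose_k_eigengap <- function(graph, k_max = 10L) {
  n <- igraph::vcount(graph)
  k_max <- min(k_max, n - 1L)
  if (k_max < 2) return(2L)
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight", sparse = TRUE))
  deg <- rowSums(A)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(n) - (inv_sqrt * A) * rep(inv_sqrt, each = n)
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  gaps <- diff(ev[seq_len(k_max + 1)])
  which.max(gaps[-1]) + 1L  # gap after position k, k >= 2
}
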