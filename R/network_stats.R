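#' Global topology statistics of a correlation network
#'
#' Computes five classical global parameters of the unweighted skeleton of a
#' correlation graph (edges present/absent; weights are ignored):
#'
#' * `density` — `2m / (n (n - 1))`, the fraction of realized edges;
#' * `shannon_entropy` — Shannon entropy (nats) of the empirical degree
#'   distribution, `-sum(f_d log f_d)`; 0 iff the graph is degree-regular;
#' * `centralization` — Freeman degree centralization,
#'   `sum(d_max - d_i) / ((n - 1) (n - 2))`; 1 for a star, 0 for regular
#'   graphs;
#' * `heterogeneity` — coefficient of variation of the degrees (sample
#'   sd / mean); optionally the degree variance via `heterogeneity_measure`;
#' * `clustering_coefficient` — global transitivity,
#'   `3 * triangles / connected triples`.
#'
#' @param graph An [igraph::igraph] with at least 2 nodes.
#' @param heterogeneity_measure `"cv"` (default) or `"variance"`.
#' @return An object of class `network_summary`: named list of the five
#'   statistics.
#' @export
summarize_network <- function(graph, heterogeneity_measure = c("cv", "variance")) {
  heterogeneity_measure <- match.arg(heterogeneity_measure)
  n <- igraph::vcount(graph)
  if (n < 2) stop("network summary needs at least 2 nodes")
  deg <- igraph::degree(graph)
  m <- igraph::ecount(graph)

  density <- 2 * m / (n * (n - 1))

  f <- as.numeric(table(deg)) / n
  entropy <- -sum(f * log(f))

  centralization <- if (n > 2) sum(max(deg) - deg) / ((n - 1) * (n - 2)) else 0

  mean_deg <- mean(deg)
  if (mean_deg == 0) {
    warning("graph has no edges; heterogeneity reported as 0")
    heterogeneity <- 0
  } else {
    heterogeneity <- switch(heterogeneity_measure,
      cv = stats::sd(deg) / mean_deg,
      variance = stats::var(deg)
    )
  }

  trans <- igraph::transitivity(graph, type = "global")
  if (is.nan(trans)) trans <- 0  # no connected triples

  structure(list(
    density = density,
    shannon_entropy = entropy,
    centralization = centralization,
    heterogeneity = heterogeneity,
    clustering_coefficient = trans
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("network_summary:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %.4f\n", nm, x[[nm]]))
  invisible(x)
}

network_parameters <- c("density", "shannon_entropy", "centralization",
                        "heterogeneity", "clustering_coefficient")

#' Bootstrap distributions of network parameters for one group
#'
#' Resamples a group's samples (the biological replicates) with replacement,
#' rebuilds the significance-filtered Spearman network on each resample and
#' summarizes its topology, yielding a bootstrap distribution of each of the
#' five global parameters.
#'
#' A resample in which every taxon is constant carries no network and is
#' redrawn; the redraw count is reported in the `redraws` attribute, and more
#' than 50% redraws aborts.
#'
#' @param table A [count_table()].
#' @param group Group label to bootstrap.
#' @param B Number of bootstrap replicates (default 1000).
#' @param alpha Edge retention threshold passed to [build_graph()].
#' @param seed Integer seed; replicate `b` draws from a stream derived from
#'   `seed` and `b`, so the full replicate set is reproducible.
#' @param use_relative Correlate relative abundances (default) rather than
#'   raw counts.
#' @return Object of class `bootstrap_distribution`: data frame of `B` rows,
#'   one column per parameter, with attributes `group`, `B`, `redraws`.
#' @export
bootstrap_network_stats <- function(table, group, B = 1000L, alpha = 0.05,
                                    seed = 1L, use_relative = TRUE) {
  stopifnot(inherits(table, "count_table"), B >= 1)
  rows <- group_indices(table, group)
  if (length(rows) < 3) stop("group needs at least 3 samples to bootstrap")
  x <- if (use_relative) relative_abundance(table)[rows, , drop = FALSE]
       else table$counts[rows, , drop = FALSE]
  n <- nrow(x)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  out <- matrix(NA_real_, B, length(network_parameters),
                dimnames = list(NULL, network_parameters))
  redraws <- 0L
  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      set.seed(split_seed(seed, 1000L + b + 7919L * attempt))
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch({
        corr <- suppressWarnings(spearman_matrix(x[idx, , drop = FALSE]))
        summarize_network(suppressWarnings(build_graph(corr, alpha)))
      }, error = function(e) NULL)
      if (!is.null(res)) break
      redraws <- redraws + 1L
      attempt <- attempt + 1L
      if (redraws > B / 2) stop("more than 50% of bootstrap resamples were degenerate")
    }
    out[b, ] <- unlist(res)
  }
  structure(as.data.frame(out), class = c("bootstrap_distribution", "data.frame"),
            group = group, B = B, redraws = redraws)
}

#' Compare a network parameter across groups
#'
#' One-way ANOVA with Tukey HSD post-hoc on the bootstrap replicate vectors
#' of one topology parameter, as used to compare the groups' network
#' organization.
#'
#' @param boots Named list of `bootstrap_distribution` objects (or plain data
#'   frames of replicates), one per group; names are the group labels.
#' @param parameter One of `density`, `shannon_entropy`, `centralization`,
#'   `heterogeneity`, `clustering_coefficient`.
#' @return The [anova_tukey()] result: list with `F`, `p`, `df`, and the
#'   Tukey pairwise table.
#' @export
compare_network_groups <- function(boots, parameter) {
  stopifnot(parameter %in% network_parameters, length(boots) >= 2)
  if (is.null(names(boots)) || any(names(boots) == "")) {
    stop("`boots` must be a named list (group labels)")
  }
  values <- unlist(lapply(boots, function(b) b[[parameter]]), use.names = FALSE)
  groups <- rep(names(boots), vapply(boots, nrow, integer(1)))
  anova_tukey(values, groups)
}
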