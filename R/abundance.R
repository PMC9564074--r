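#' Relative abundance
#'
#' Converts counts to per-sample proportions. Every row of the result sums
#' to 1.
#'
#' @param table A [count_table()] or a nonnegative numeric matrix
#'   (samples x taxa).
#' @return Numeric matrix of proportions with the input's dimnames.
#' @export
relative_abundance <- function(table) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  totals <- rowSums(x)
  if (any(totals == 0)) {
    bad <- rownames(x)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop(sprintf("sample(s) with zero total count: %s",
                 paste(bad, collapse = ", ")))
  }
  sweep(x, 1, totals, "/")
}

#' Per-sample richness and Shannon diversity
#'
#' Richness is the number of taxa observed (count > 0) in a sample; Shannon
#' diversity is `H = -sum(p_i * log(p_i))` over the taxa present, in natural
#' log units by default.
#'
#' @param table A [count_table()].
#' @param base Logarithm base for Shannon diversity (default `exp(1)`,
#'   i.e. nats; use 2 for bits).
#' @return Data frame with one row per sample: `sample`, `group`,
#'   `richness`, `shannon`.
#' @export
diversity_profile <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "count_table"))
  p <- relative_abundance(table)
  shannon <- apply(p, 1, function(row) {
    row <- row[row > 0]
    -sum(row * log(row, base = base))
  })
  data.frame(
    sample = rownames(table$counts),
    group = as.character(table$groups),
    richness = as.integer(rowSums(table$counts > 0)),
    shannon = as.numeric(shannon),
    row.names = NULL
  )
}

#' Per-group mean shares of the globally most abundant taxa
#'
#' Ranks taxa by mean relative abundance pooled over all samples (so every
#' group shares one legend), keeps the top `k`, and reports each group's mean
#' share of those taxa plus an `"Other"` remainder. Ties in the global
#' ranking are broken by taxon name.
#'
#' @param table A [count_table()].
#' @param k Number of taxa to name (default 20). If `k >= n_taxa`, all taxa
#'   are named and `"Other"` is exactly 0.
#' @return Data frame in long form: `group`, `taxon`, `mean_share`; taxa
#'   ordered by global rank with `"Other"` last. Shares sum to 1 per group.
#' @export
top_k_taxa <- function(table, k = 20L) {
  stopifnot(inherits(table, "count_table"), k >= 1)
  p <- relative_abundance(table)
  pooled <- colMeans(p)
  ord <- order(-pooled, colnames(p))
  top <- ord[seq_len(min(k, ncol(p)))]
  res <- do.call(rbind, lapply(levels(table$groups), function(g) {
    rows <- table$groups == g
    gm <- colMeans(p[rows, , drop = FALSE])
    data.frame(
      group = g,
      taxon = c(colnames(p)[top], "Other"),
      mean_share = c(gm[top], 1 - sum(gm[top])),
      row.names = NULL
    )
  }))
  res$taxon <- factor(res$taxon, levels = c(colnames(p)[top], "Other"))
  res
}
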