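#' Min-max rescaling of an omics block to [0, 1]
#'
#' Rescales every feature to the unit interval, `(x - min) / (max - min)`,
#' the display convention used before assembling the multi-omic network.
#' Constant features cannot be rescaled; they are mapped to all-zero and
#' recorded in the `flagged` attribute. Because the downstream correlations
#' are rank-based, this rescaling never changes which edges are retained.
#'
#' @param block An [omics_block()] or numeric matrix.
#' @return Object of the same kind with every feature in `[0, 1]`; the
#'   attribute `flagged` on the values matrix lists constant features.
#' @export
rescale_unit <- function(block) {
  x <- if (inherits(block, "omics_block")) block$values else as.matrix(block)
  if (any(!is.finite(x))) stop("non-finite values cannot be rescaled")
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  flagged <- colnames(x)[span == 0]
  scaled <- sweep(x, 2, rng[1, ], "-")
  scaled <- sweep(scaled, 2, ifelse(span == 0, 1, span), "/")
  scaled[, span == 0] <- 0
  attr(scaled, "flagged") <- flagged
  if (inherits(block, "omics_block")) {
    out <- omics_block(scaled, block$tag)
    attr(out$values, "flagged") <- flagged
    out
  } else {
    scaled
  }
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary dependence:
#' the BH factor at rank `k` is inflated by the harmonic sum
#' `c(m) = sum(1/i, i = 1..m)`, the cumulative minimum is enforced from the
#' largest rank down, and values are capped at 1. Delegates to
#' [stats::p.adjust()] with `method = "BY"` after validation.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and names.
#' @export
by_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BY")
}

#' Multi-omic correlation network
#'
#' Integrates several omics blocks (genus abundances, pathway abundances,
#' bone phenotypes, blood pressure) into one correlation network over the
#' pooled samples: blocks are inner-joined on sample IDs, each feature is
#' min-max rescaled to `[0, 1]`, features are tag-prefixed and concatenated,
#' the full Spearman matrix is computed, all off-diagonal p-values are
#' Benjamini-Yekutieli adjusted jointly, and pairs with adjusted p below
#' `alpha` become edges weighted by `|rho|`.
#'
#' @param blocks List of [omics_block()] objects (>= 2) with distinct tags.
#' @param alpha Threshold on the BY-adjusted p-value (default 0.05).
#' @param between_only Restrict testing (and hence the BY family) to pairs
#'   of features from different blocks (default FALSE: all pairs).
#' @return An [igraph::igraph]; vertices carry `name` (`tag.feature`) and
#'   `block` attributes, edges carry `weight` (`|rho|`), `rho`, `p` (raw)
#'   and `p_adjusted`. Constant features are excluded (with a warning), so
#'   the node set is exactly the non-degenerate features.
#' @export
multiomic_graph <- function(blocks, alpha = 0.05, between_only = FALSE) {
  stopifnot(length(blocks) >= 2)
  if (!all(vapply(blocks, inherits, TRUE, "omics_block"))) {
    stop("`blocks` must be a list of omics_block objects")
  }
  tags <- vapply(blocks, `[[`, "", "tag")
  if (anyDuplicated(tags)) stop("block tags must be distinct")

  shared <- Reduce(intersect, lapply(blocks, function(b) rownames(b$values)))
  if (length(shared) < 4) {
    stop("fewer than 4 samples shared across blocks after inner join")
  }
  n_all <- length(unique(unlist(lapply(blocks, function(b) rownames(b$values)))))
  if (n_all > length(shared)) {
    message(sprintf("dropping %d sample(s) missing from some block",
                    n_all - length(shared)))
  }

  mats <- lapply(blocks, function(b) {
    v <- rescale_unit(b)$values[shared, , drop = FALSE]
    colnames(v) <- paste(b$tag, colnames(v), sep = ".")
    v
  })
  combined <- do.call(cbind, mats)
  block_of <- rep(tags, vapply(mats, ncol, integer(1)))
  names(block_of) <- colnames(combined)

  corr <- spearman_matrix(combined)
  block_of <- block_of[corr$features]

  ut <- upper.tri(corr$rho)
  idx <- which(ut, arr.ind = TRUE)
  test <- rep(TRUE, nrow(idx))
  if (between_only) {
    test <- block_of[idx[, 1]] != block_of[idx[, 2]]
  }
  padj <- rep(NA_real_, nrow(idx))
  padj[test] <- by_adjust(corr$pvalue[ut][test])

  keep <- !is.na(padj) & padj < alpha
  edges <- data.frame(
    from = corr$features[idx[keep, 1]],
    to = corr$features[idx[keep, 2]],
    weight = abs(corr$rho[ut][keep]),
    rho = corr$rho[ut][keep],
    p = corr$pvalue[ut][keep],
    p_adjusted = padj[keep]
  )
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = corr$features, block = unname(block_of))
  )
}
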