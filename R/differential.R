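#' Pairwise log2 fold change of group mean abundance
#'
#' `log2((mean_A + pc) / (mean_B + pc))` of per-group mean relative
#' abundances, with a pseudocount so features absent from one group remain
#' displayable. Antisymmetric under swapping the groups.
#'
#' @param table A [count_table()].
#' @param group_a,group_b Group labels (fold change of `a` over `b`).
#' @param pseudocount Positive constant added to both means (default 0.5;
#'   for relative-abundance tables a pseudocount on the order of half a read,
#'   `0.5 / depth`, is more informative and is what [run_pipeline()] uses).
#' @return Named numeric vector, one value per taxon.
#' @export
log2_fold_change <- function(table, group_a, group_b, pseudocount = 0.5) {
  stopifnot(inherits(table, "count_table"), pseudocount > 0)
  p <- relative_abundance(table)
  ma <- colMeans(p[group_indices(table, group_a), , drop = FALSE])
  mb <- colMeans(p[group_indices(table, group_b), , drop = FALSE])
  log2((ma + pseudocount) / (mb + pseudocount))
}

#' Nonparametric differential-abundance selection
#'
#' Screens every feature for differential abundance across the experimental
#' groups with a Kruskal-Wallis rank test on relative abundances, adjusts
#' the p-values by Benjamini-Hochberg across features, and selects features
#' with adjusted p below `alpha`. Being rank-based on proportions, the test
#' is invariant to sequencing depth and to monotone transforms.
#'
#' Features that are constant across all samples carry no information; their
#' p-value is set to 1 by convention and a message is logged.
#'
#' @param table A [count_table()] (relative abundances are tested), or a
#'   numeric samples-by-features matrix with `groups` supplied.
#' @param alpha Selection threshold on the BH-adjusted p-value
#'   (default 0.05).
#' @param groups Group labels when `table` is a plain matrix.
#' @return Data frame, one row per feature: `feature`, `p`, `p_adjusted`,
#'   `selected`, plus one `lfc_<A>_vs_<B>` column per group pair (for count
#'   tables).
#' @export
select_differential <- function(table, alpha = 0.05, groups = NULL) {
  if (inherits(table, "count_table")) {
    x <- relative_abundance(table)
    groups <- table$groups
  } else {
    x <- as.matrix(table)
    if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
    if (is.null(groups)) stop("`groups` required for a plain matrix")
    groups <- factor(groups, levels = unique(as.character(groups)))
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")

  pvals <- apply(x, 2, function(col) {
    if (stats::var(col) == 0) return(NA_real_)
    stats::kruskal.test(col, groups)$p.value
  })
  n_const <- sum(is.na(pvals))
  if (n_const > 0) {
    message(sprintf("%d constant feature(s) assigned p = 1", n_const))
    pvals[is.na(pvals)] <- 1
  }
  padj <- stats::p.adjust(pvals, method = "BH")
  res <- data.frame(feature = colnames(x), p = unname(pvals),
                    p_adjusted = unname(padj),
                    selected = unname(padj < alpha), row.names = NULL)
  if (inherits(table, "count_table")) {
    depth <- stats::median(rowSums(table$counts))
    for (pr in utils::combn(levels(groups), 2, simplify = FALSE)) {
      res[[sprintf("lfc_%s_vs_%s", pr[1], pr[2])]] <-
        unname(log2_fold_change(table, pr[1], pr[2], pseudocount = 0.5 / depth))
    }
  }
  res
}

#' Principal-component projection of selected features
#'
#' Projects samples onto the first two principal components of a (column-
#' centered, optionally standardized) feature matrix, reporting the scores
#' and the fractions of variance each component explains.
#'
#' @param x Numeric matrix, samples in rows, features in columns
#'   (>= 2 features, >= 3 samples).
#' @param standardize Scale features to unit variance before the SVD
#'   (default FALSE).
#' @return List with `scores` (n x 2 matrix, columns `PC1`, `PC2`) and
#'   `explained` (length-2 vector of variance fractions). PC signs are
#'   arbitrary, as for any SVD.
#' @export
pc_projection <- function(x, standardize = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 features")
  if (nrow(x) < 3) stop("need at least 3 samples")
  v <- apply(x, 2, stats::var)
  if (standardize && any(v == 0)) {
    stop(sprintf("cannot standardize zero-variance feature(s): %s",
                 paste(colnames(x)[v == 0], collapse = ", ")))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  if (all(pc$sdev < .Machine$double.eps^0.5)) {
    stop(sprintf("feature matrix has rank 0 after centering; degenerate feature(s): %s",
                 paste(colnames(x)[v == 0], collapse = ", ")))
  }
  ev <- pc$sdev^2
  list(scores = pc$x[, 1:2, drop = FALSE],
       explained = ev[1:2] / sum(ev))
}
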