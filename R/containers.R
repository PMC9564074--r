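#' Genus-level count table
#'
#' Lightweight container for a samples-by-taxa integer count matrix with a
#' group label per sample. Rows are biological samples (animals), columns
#' are genus-level taxa.
#'
#' @param counts Integer matrix, samples in rows, taxa in columns. Row and
#'   column names are used as sample IDs and taxon names; defaults are
#'   generated when absent.
#' @param groups Character or factor of group labels, one per sample.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (named integer matrix) and `groups` (factor aligned to rows).
#' @export
count_table <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("`counts` must be a numeric matrix")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (length(groups) != nrow(counts)) {
    stop("`groups` must have one label per sample (row)")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("S%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  }
  groups <- factor(groups, levels = unique(as.character(groups)))
  structure(list(counts = counts, groups = groups), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(
    "count_table: %d samples x %d taxa, groups: %s\n",
    nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s (n=%d)", levels(x$groups), table(x$groups)),
          collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Continuous omics block
#'
#' A samples-by-features matrix of continuous measurements tagged with the
#' omic layer it belongs to (genus relative abundance, metabolic pathway,
#' bone phenotype, or blood pressure). Blocks are aligned on sample IDs
#' (row names) when integrated into a multi-omic network.
#'
#' @param values Numeric matrix, samples in rows, features in columns;
#'   row names are sample IDs.
#' @param tag Single string naming the layer, e.g. `"genus"`, `"pathway"`,
#'   `"phenotype"`, `"blood_pressure"`.
#' @return An object of class `omics_block` with elements `values` and `tag`.
#' @export
omics_block <- function(values, tag) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (is.null(rownames(values))) stop("`values` must carry sample IDs as row names")
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%03d", seq_len(ncol(values)))
  }
  stopifnot(is.character(tag), length(tag) == 1L)
  structure(list(values = values, tag = tag), class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("omics_block [%s]: %d samples x %d features\n",
              x$tag, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Internal: group labels validated against a count_table
group_indices <- function(table, group) {
  if (!group %in% levels(table$groups)) {
    stop(sprintf("unknown group label '%s' (have: %s)", group,
                 paste(levels(table$groups), collapse = ", ")))
  }
  which(table$groups == group)
}
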