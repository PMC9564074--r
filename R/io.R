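#' Write / read a count table as TSV
#'
#' The count matrix is written with samples in rows (first column
#' `sample_id`) and a companion two-column metadata file maps sample IDs to
#' group labels. Both files round-trip bit-identically through
#' [read_count_table()].
#'
#' @param table A [count_table()].
#' @param counts_path,metadata_path Output TSV paths.
#' @return `table`, invisibly.
#' @export
write_count_table <- function(table, counts_path, metadata_path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = rownames(table$counts),
                     group = as.character(table$groups))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(counts_path, metadata_path) {
  if (!file.exists(counts_path)) stop(sprintf("counts file not found: %s", counts_path))
  if (!file.exists(metadata_path)) stop(sprintf("metadata file not found: %s", metadata_path))
  df <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  groups <- meta$group[match(df[[1]], meta$sample_id)]
  if (any(is.na(groups))) stop("metadata is missing some samples")
  count_table(counts, groups)
}

#' Write / read an omics block as TSV
#'
#' @param block An [omics_block()].
#' @param path TSV path; the block tag is stored in a `# tag:` comment line.
#' @return The block, invisibly (read: the block).
#' @export
write_omics_block <- function(block, path) {
  stopifnot(inherits(block, "omics_block"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tag: %s", block$tag), con)
  df <- data.frame(sample_id = rownames(block$values), block$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(block)
}

#' @rdname write_omics_block
#' @export
read_omics_block <- function(path) {
  if (!file.exists(path)) stop(sprintf("omics block file not found: %s", path))
  first <- readLines(path, n = 1)
  tag <- if (startsWith(first, "# tag:")) trimws(sub("# tag:", "", first)) else "unknown"
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  omics_block(vals, tag)
}

# Deterministic numeric TSV writer used by the pipeline (fixed significant
# digits so manifests hash identically across runs).
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
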