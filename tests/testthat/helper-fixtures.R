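# Small configurations reused across tests. All sizes are deliberately tiny
# so individual tests run in well under a second.

null_config <- function(n_per_group = 8L, n_taxa = 20L, n_groups = 3L,
                        depth = 2000L, seed = 1L) {
  synthetic_config(n_groups = n_groups, n_samples_per_group = n_per_group,
                   n_taxa = n_taxa, sequencing_depth = depth, seed = seed)
}

one_block_config <- function(rho = 0.7, block = 12L, n_taxa = 20L,
                             n_per_group = 40L, depth = 5000L, seed = 1L) {
  synthetic_config(
    n_groups = 1L, n_samples_per_group = n_per_group, n_taxa = n_taxa,
    sequencing_depth = depth,
    block_spec = list(list(list(size = block, rho = rho))),
    seed = seed
  )
}

four_block_config <- function(rho = 0.7, n_taxa = 12L, n_per_group = 40L,
                              depth = 5000L, seed = 1L) {
  synthetic_config(
    n_groups = 1L, n_samples_per_group = n_per_group, n_taxa = n_taxa,
    sequencing_depth = depth,
    block_spec = list(rep(list(list(size = 3L, rho = rho)), 4)),
    seed = seed
  )
}

# Tiny deterministic count table for hand-checkable summaries.
tiny_table <- function() {
  counts <- rbind(
    c(10, 5, 0, 1, 4, 0),
    c(8, 6, 1, 0, 5, 0),
    c(2, 1, 9, 8, 0, 0),
    c(1, 2, 10, 7, 0, 0)
  )
  colnames(counts) <- paste0("t", 1:6)
  rownames(counts) <- paste0("S", 1:4)
  count_table(counts, c("A", "A", "B", "B"))
}
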