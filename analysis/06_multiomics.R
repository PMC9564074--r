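# The multi-omic correlation network: genera + pathways + bone phenotypes +
# blood pressure, pooled over all 24 animals, edges kept at BY-adjusted
# p < 0.05 with weight |rho|.

source("analysis/00_config.R")
study <- load_study()
tab <- study$table
phen <- study$phenotypes

blocks <- list(
  omics_block(relative_abundance(tab), "genus"),
  study$pathways,
  omics_block(phen$values[, "SBP", drop = FALSE], "blood_pressure"),
  omics_block(phen$values[, setdiff(colnames(phen$values), "SBP"),
                          drop = FALSE], "phenotype")
)
net <- suppressWarnings(multiomic_graph(blocks, alpha = 0.05))
write.table(edge_table(net), file.path(OUT, "multiomic_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
igraph::write_graph(net, file.path(OUT, "multiomic_network.graphml"),
                    format = "graphml")

et <- edge_table(net)
vb <- setNames(igraph::V(net)$block, igraph::V(net)$name)
cat(sprintf("Multi-omic network: %d nodes, %d edges (%d between blocks)\n",
            igraph::vcount(net), nrow(et),
            sum(vb[et$from] != vb[et$to])))
bp_edges <- et[et$from == "blood_pressure.SBP" | et$to == "blood_pressure.SBP", ]
cat(sprintf("Blood pressure connects to %d features:\n", nrow(bp_edges)))
if (nrow(bp_edges)) {
  partner <- ifelse(bp_edges$from == "blood_pressure.SBP",
                    bp_edges$to, bp_edges$from)
  for (i in seq_len(nrow(bp_edges))) {
    cat(sprintf("  %-22s |rho| = %.2f (BY-adjusted p = %.3g)\n",
                partner[i], bp_edges$weight[i], bp_edges$p_adjusted[i]))
  }
}
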