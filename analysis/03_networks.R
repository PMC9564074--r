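# Per-group Spearman correlation networks (edges: p < 0.05, weight = |rho|)
# with spectral clustering of the genera.

source("analysis/00_config.R")
study <- load_study()
tab <- study$table
relab <- relative_abundance(tab)

for (g in levels(tab$groups)) {
  corr <- suppressWarnings(spearman_matrix(relab[tab$groups == g, ]))
  net <- build_graph(corr, 0.05)
  write.table(edge_table(net),
              file.path(OUT, sprintf("network_edges_%s.tsv", g)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  k <- choose_k_eigengap(net)
  cl <- spectral_clusters(net, k, seed = SEED)
  write.table(data.frame(taxon = names(cl), cluster = as.integer(cl)),
              file.path(OUT, sprintf("network_clusters_%s.tsv", g)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- summarize_network(net)
  cat(sprintf(
    "%-10s %4d edges | density %.3f entropy %.2f centralization %.3f heterogeneity %.2f clustering %.2f | k = %d clusters\n",
    g, igraph::ecount(net), s$density, s$shannon_entropy, s$centralization,
    s$heterogeneity, s$clustering_coefficient, k))
}
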