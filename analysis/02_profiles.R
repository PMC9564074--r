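# Abundance profiles: per-sample richness and Shannon diversity, the top-20
# genus summary, and the Mann-Whitney richness comparisons.

source("analysis/00_config.R")
study <- load_study()
tab <- study$table

div <- diversity_profile(tab)
write.table(div, file.path(OUT, "diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Richness (mean per group):\n")
print(tapply(div$richness, div$group, mean))
cat("Shannon diversity (mean per group, nats):\n")
print(round(tapply(div$shannon, div$group, mean), 3))

top <- top_k_taxa(tab, 20)
write.table(top, file.path(OUT, "top20_taxa.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nTop-20 genera cover %.1f%% of reads (pooled)\n",
            100 * (1 - mean(top$mean_share[top$taxon == "Other"]))))

for (pr in combn(levels(tab$groups), 2, simplify = FALSE)) {
  mw <- mann_whitney_u(div$richness[div$group == pr[1]],
                       div$richness[div$group == pr[2]])
  cat(sprintf("Mann-Whitney richness %s vs %s: U = %g, p = %.3f\n",
              pr[1], pr[2], mw$U_x, mw$p))
}
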