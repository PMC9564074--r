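# Community-level composition tests: Bray-Curtis PERMANOVA over the three
# groups and pairwise Adonis with BH adjustment.

source("analysis/00_config.R")
study <- load_study()
tab <- study$table

d <- bray_curtis(tab)
write.table(as.matrix(d), file.path(OUT, "bray_curtis.tsv"),
            sep = "\t", quote = FALSE)

pm <- permanova(d, tab$groups, n_perm = 999, seed = SEED)
print(pm)
write.table(data.frame(pseudo_F = pm$pseudo_F, R2 = pm$R2, p = pm$p,
                       n_permutations = pm$n_permutations),
            file.path(OUT, "permanova.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pa <- pairwise_adonis(d, tab$groups, n_perm = 999, seed = SEED + 1)
write.table(pa, file.path(OUT, "pairwise_adonis.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Pairwise Adonis:\n")
print(pa, digits = 3)
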