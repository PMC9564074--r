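# Bootstrap distributions (B = 1000, resampling animals within a group) of
# the five global topology parameters, compared across groups by one-way
# ANOVA with Tukey HSD.

source("analysis/00_config.R")
study <- load_study()
tab <- study$table
groups <- levels(tab$groups)

boots <- lapply(seq_along(groups), function(i) {
  bootstrap_network_stats(tab, groups[i], B = 1000, alpha = 0.05,
                          seed = SEED + i)
})
names(boots) <- groups
for (g in groups) {
  write.table(boots[[g]], file.path(OUT, sprintf("bootstrap_%s.tsv", g)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

params <- c("density", "shannon_entropy", "centralization",
            "heterogeneity", "clustering_coefficient")
rows <- list()
for (par in params) {
  cmp <- compare_network_groups(boots, par)
  cat(sprintf("%-24s means: %s | F = %.1f, p = %.3g\n", par,
              paste(sprintf("%s %.3f", groups,
                            sapply(boots, function(b) mean(b[[par]]))),
                    collapse = ", "),
              cmp$F, cmp$p))
  rows[[par]] <- data.frame(parameter = par, F = cmp$F, p = cmp$p,
                            pair = paste(cmp$tukey$group_a, cmp$tukey$group_b,
                                         sep = " vs "),
                            tukey_p = cmp$tukey$p_adjusted)
}
write.table(do.call(rbind, rows), file.path(OUT, "network_comparison.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
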