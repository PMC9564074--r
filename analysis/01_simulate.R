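# Simulate the synthetic study cohort and write its tables.

source("analysis/00_config.R")

tab <- generate_counts(CONFIG)
write_count_table(tab, counts_path, metadata_path)
write_omics_block(generate_phenotypes(CONFIG, tab), phenotypes_path)
write_omics_block(generate_pathways(CONFIG, tab), pathways_path)

cat(sprintf("Simulated %d samples x %d genera at depth %d (seed %d)\n",
            nrow(tab$counts), ncol(tab$counts), CONFIG$sequencing_depth, SEED))
cat(sprintf("Groups: %s\n", paste(levels(tab$groups), collapse = ", ")))
cat(sprintf("Tables written under %s\n", OUT))
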