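# Shared settings for the analysis drivers. Each numbered script can be run
# on its own from the repository root:
#   Rscript analysis/01_simulate.R
# Results accumulate under results/study/.

library(gutorg)

SEED <- 20220924L
OUT <- "results/study"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

# The synthetic study: 3 groups x 8 rats, 200 genera at 50000 reads/sample.
# The control community carries one 16-genus correlation block that is
# fragmented into four 4-genus blocks under hypertension and partly restored
# (two 8-genus blocks) under treatment; four genera carry planted
# enrichment/suppression; blood pressure and four trabecular phenotypes are
# linked to planted taxa.
CONFIG <- study_config(seed = SEED)

counts_path <- file.path(OUT, "counts.tsv")
metadata_path <- file.path(OUT, "metadata.tsv")
phenotypes_path <- file.path(OUT, "phenotypes.tsv")
pathways_path <- file.path(OUT, "pathways.tsv")

load_study <- function() {
  if (!file.exists(counts_path)) {
    stop("run analysis/01_simulate.R first")
  }
  list(table = read_count_table(counts_path, metadata_path),
       phenotypes = read_omics_block(phenotypes_path),
       pathways = read_omics_block(pathways_path))
}
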