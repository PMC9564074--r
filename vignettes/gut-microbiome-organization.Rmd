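---
title: "Correlation-network organization analysis of gut microbiome count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-network organization analysis of gut microbiome count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question this package addresses

Composition summaries (richness, diversity, relative abundance) often fail to
distinguish experimental groups in small animal cohorts even when a treatment
has clearly reorganized the gut community. `gutorg` implements an analysis of
community *organization*: instead of asking "which genera changed in
abundance", it asks "how did the correlation structure among genera change".
The motivating design is a hypertension study — three groups of eight rats
(normotensive controls, mineralocorticoid-salt hypertensive animals, and
hypertensive animals given an ACE inhibitor) with genus-level 16S counts,
metagenomic pathway abundances, trabecular bone phenotypes, and blood
pressure — but every function takes an ordinary count table with group
labels.

The pipeline has five analytic layers:

1. **Abundance profiles** — per-sample richness and Shannon diversity, and
   pooled top-*k* genus summaries.
2. **Per-group correlation networks** — significance-filtered Spearman
   networks over genera, clustered spectrally.
3. **Bootstrap topology inference** — five global network parameters with
   bootstrap distributions per group, compared by ANOVA + Tukey HSD.
4. **Differential features** — a nonparametric screen with fold-change
   summaries and principal-component projections.
5. **Multi-omic integration** — one Benjamini–Yekutieli-filtered Spearman
   network joining genera, pathways, bone phenotypes, and blood pressure.

A seeded synthetic-data generator with planted structure makes every layer
testable without any sequencing data.

# The synthetic cohort

## Model

Counts follow a logistic-normal/multinomial model. For sample $s$ in group
$g$ with $p$ taxa:

$$
z_s \sim \mathcal N_p(0, R_g), \qquad
\eta_s = \mu + \sigma z_s + \delta_g, \qquad
x_s \sim \text{Multinomial}\!\left(N,\ \text{softmax}(\eta_s)\right)
$$

* $\mu$ — per-taxon baseline log abundances, drawn once per configuration
  from a lognormal (`baseline_sdlog = 1.5`). This produces the
  characteristic abundance skew of real genus tables: a few dominant genera
  and a long tail (the default cohort's top 20 genera carry about 60% of
  reads).
* $R_g$ — group-specific block-equicorrelation matrix: each planted block
  of size $b$ has constant within-block correlation $\rho \in [0, 1)$
  (always positive definite), zero elsewhere. This is the "organization"
  signal: e.g. the default `study_config()` gives the control group one
  16-genus block, the hypertensive group four 4-genus fragments, and the
  treated group two 8-genus blocks.
* $\delta_g$ — planted effects, `log2_effect` units on the latent log scale,
  so a value of 2 is approximately a 4-fold change of relative abundance.
* $N$ — sequencing depth, default 50000 reads/sample; every sample's counts
  sum to $N$ exactly. Depths are equal across samples by default (no
  rarefaction step is modeled), configurable.

Phenotypes are linear in the centered-log-ratio (clr) abundance of a linked
taxon: $y_s = a_{g(s)} + \beta\,\mathrm{clr}(x_s)_j + \varepsilon_s$.
Pathway abundances are nonnegative mixtures of a few taxa's relative
abundances with multiplicative lognormal noise.

## Reproducibility scheme

One master seed feeds a fixed per-operation stream: operation $k$ uses
`(seed * 1009 + k) mod (2^31 - 1)` (counts = 1, phenotypes = 2,
pathways = 3; bootstrap replicate $b$ uses offset $1000 + b$). Each
operation is therefore bit-reproducible in isolation, and generator calls
save and restore the caller's RNG state.

## What the generator does and does not emulate

It reproduces the *statistical* structure the analysis consumes:
compositional counts with realistic skew, group-specific correlation blocks,
planted fold changes, taxon-linked continuous phenotypes. It does not model
sequence-level artifacts (chimeras, primer bias), overdispersion beyond the
logistic-normal's, phylogenetic relatedness, or zero-inflation beyond what
the multinomial at finite depth produces. Passing tests therefore show the
*methods* behave correctly on data with known truth — not that any
biological conclusion from real data is right.

One property of compositional data deserves emphasis because it shaped both
defaults and tests: **closure-induced anticorrelation**. When planted blocks
occupy most of the community, softmax normalization forces strong *negative*
correlations between blocks, and a network whose edges are $|\rho|$ merges
them. Planted blocks embedded in a larger community (12 block taxa among
50–200 genera) keep cross-block correlations near zero; block-recovery tests
use that regime deliberately.

# Per-group correlation networks

`spearman_matrix()` computes Spearman's $\rho$ as the Pearson correlation of
midranks (average ranks under ties), with two-sided p-values from the
$t$ approximation, $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n - 2$ degrees of
freedom — the standard choice at the $n = 8$–24 of animal cohorts. Constant
taxa carry no rank information and are dropped with a warning.
`build_graph(corr, alpha = 0.05)` keeps a pair as an edge iff its *raw*
p-value is below `alpha` — deliberately without multiple-testing correction,
because the genus–genus network is descriptive and its downstream statistics
are compared *between groups*, where the edge-selection rule is identical.
The edge weight is $|\rho|$: the network encodes the magnitude of
association, not its sign. By default correlations are computed on relative
abundances; with equal sequencing depths this coincides with ranks of raw
counts.

`spectral_clusters()` performs normalized spectral clustering: the $k$
smallest eigenvectors of $L = I - D^{-1/2} A D^{-1/2}$ of the weighted
adjacency, row-normalized, then k-means with a fixed seed and 25 restarts.
Isolated nodes sit at the origin of the embedding and are assigned
deterministically. Because no biological ground truth fixes $k$, the default
comes from the eigengap heuristic (`choose_k_eigengap()`): the position of
the largest gap in the ascending Laplacian spectrum, searched over
$2 \le k \le 10$.

# Global topology statistics and bootstrap inference

`summarize_network()` works on the unweighted skeleton — the five parameters
are classical presence/absence measures:

| parameter | definition | range |
|---|---|---|
| density | $2m / (n(n-1))$ | $[0,1]$ |
| Shannon entropy | $-\sum_d f_d \ln f_d$ over the empirical degree distribution | $\ge 0$, 0 iff regular |
| centralization | Freeman degree centralization $\sum_i (d_{\max} - d_i) / ((n-1)(n-2))$ | $[0,1]$, 1 for a star |
| heterogeneity | coefficient of variation of degrees (sample sd / mean) | $\ge 0$ |
| clustering coefficient | global transitivity, $3 \times$ triangles / connected triples | $[0,1]$ |

"Network entropy", "centrality" and "heterogeneity" have no single canonical
definition; the choices above are the common graph-descriptive ones (degree-
distribution entropy; centralization as the one-number global version of
degree centrality; degree CV, with degree variance available via
`heterogeneity_measure = "variance"`). Degenerate cases are pinned down
explicitly: an edgeless graph reports heterogeneity 0 with a warning, a
triangle-free graph reports transitivity 0, and centralization is defined as
0 for $n \le 2$.

`bootstrap_network_stats()` resamples *animals* (the biological replicates)
within a group with replacement — not taxa — rebuilds the network per
resample, and returns $B$ replicate values of each parameter (default
$B = 1000$). A resample in which every taxon is constant is redrawn (counted;
more than 50% redraws aborts). Group differences in any parameter are then
tested by one-way ANOVA with Tukey HSD on the replicate vectors
(`compare_network_groups()`).

Note the bootstrap distributions describe sampling variability of the
*network construction*, with $n = 8$ animals a resample contains about
$1 - (7/8)^8 \approx 66\%$ unique animals, so bootstrap networks are denser
and noisier than the point-estimate network; comparisons are meaningful
across groups, not against the point estimate.

# Differential features

The differential-abundance engine is deliberately simple and nonparametric:
per-feature Kruskal–Wallis across groups on relative abundances, then
Benjamini–Hochberg across features, selection at adjusted $p <$ `alpha`.
Negative-binomial GLM machinery (DESeq2/EdgeR-style) is intentionally *not*
reimplemented; the rank test is a behavioral substitute whose guarantees —
FDR control under the null and power $\ge 0.8$ against a planted 4-fold
effect at $n = 30$/group — are exactly what the test suite verifies.
Being rank-based on proportions it is invariant to sequencing depth and to
monotone transforms. At $n = 8$/group with 200 features the BH-corrected
screen is intentionally conservative and may select nothing; the raw
$p < 0.05$ screen is reported alongside for descriptive use.

Fold changes are $\log_2((\bar p_A + c)/(\bar p_B + c))$ of group-mean
relative abundances. The generic default is $c = 0.5$; because a constant of
that size dominates proportions, the pipeline passes $c = 0.5/\text{median
depth}$ (half a read) where fold changes accompany selection. Constant
features get $p = 1$ by convention, with a logged message.

`pc_projection()` returns scores on the first two principal components and
their explained-variance fractions. Input of rank 1 (all samples on a line)
is valid and reports fractions $(1, 0)$; only rank-0 input (all samples
identical) errors. PC signs are arbitrary; tests compare up to sign.

# Multi-omic integration

`multiomic_graph()` inner-joins the blocks on sample IDs (dropping, with a
report, samples missing from any block; fewer than 4 shared samples is an
error), min-max rescales every feature to $[0,1]$, tag-prefixes feature
names, computes the full Spearman matrix, and adjusts *all* off-diagonal
p-values jointly by Benjamini–Yekutieli — the step-up procedure whose
harmonic inflation factor $c(m) = \sum_{i \le m} 1/i$ keeps FDR control
under arbitrary dependence, which matters because abundances, pathways and
phenotypes here are anything but independent. Pairs with adjusted
$p < 0.05$ become edges weighted by $|\rho|$.

Two invariants are worth stating. First, the min-max rescaling is performed
for fidelity to the stated display convention but is provably edge-neutral:
Spearman correlation is rank-based, and the test suite asserts the edge set
is invariant to affine (and any monotone) transformations of the inputs.
Second, the joint BY family spans within-block pairs too by default;
`between_only = TRUE` restricts the family to cross-block pairs when only
the inter-omic links are of interest (a smaller family, hence more power,
at the price of not reporting within-block structure).

# Community-level tests

`permanova()` implements the permutational MANOVA partition on squared
distances: $SS_{\text{total}} = \sum_{i<j} d_{ij}^2 / n$, within-group sums
analogously per group, pseudo-$F = (SS_B/(g-1))/(SS_W/(n-g))$, and a
permutation p-value including the observed statistic,
$(\#\{F^\pi \ge F\} + 1)/(n_{\text{perm}} + 1)$ — the bias-free convention.
An `exhaustive = TRUE` mode enumerates all label permutations (feasible to
$n = 8$) and returns the exact p. The default distance is Bray–Curtis on
relative abundances via `vegan::vegdist()`; the implementation is verified
against `vegan::adonis2` (pseudo-$F$, $R^2$) and against one-way ANOVA,
to which PERMANOVA provably reduces on Euclidean distances of univariate
data. `pairwise_adonis()` runs each group pair with BH (default) or BY
adjustment across pairs. Richness comparisons use the Mann–Whitney U test
(exact p when small and tie-free, normal approximation with tie and
continuity corrections otherwise); other univariate group comparisons use
`anova_tukey()`.

# The pipeline and determinism

`run_pipeline()` chains all stages, writes every artifact as TSV (GraphML
for the multi-omic network), and ends with a manifest of MD5 content hashes.
Numeric TSVs are written at 10 significant digits through a single writer so
manifests are hash-stable; rerunning with the same configuration and seed
reproduces identical hashes, which the test suite asserts. Stage seeds are
derived from the master seed, so stages can be rerun in isolation. A
one-group design skips every comparative stage with an explicit log line
rather than failing.

# Numerical choices and test problem sizes

* Shannon diversity and degree entropy are in nats by default (`base = 2`
  available); the top-*k* ranking is pooled across groups so all groups
  share one legend, ties broken lexicographically.
* $\rho$ is clipped to $[-1, 1]$ before the $t$ transform; $|\rho| = 1$
  maps to $p = 0$.
* k-means uses 25 restarts under a fixed seed; spectral embeddings are exact
  eigendecompositions (dense, fine for networks of a few hundred nodes).
* Monte-Carlo tests freeze their seeds and use sizes chosen to keep each
  test in seconds while leaving clear margins: oracle equivalence on 50–100
  random instances; type-I-error checks at 500 simulations; planted-recovery
  checks at 20–100 repetitions with 12 planted taxa in a 50-genus community
  at depth 50000; power checks at 30–50 repetitions with $n = 30$/group.
* The default study cohort (3 × 8 animals, 200 genera) is intentionally a
  *weak-signal* regime: with eight animals the genus-level screens are
  expected to be conservative, which is the phenomenon that motivates the
  organization-level analysis.

# Known limitations

* Spearman networks ignore compositionality; closure-induced negative
  correlation is handled by study design (blocks small relative to the
  community), not by a compositional estimator (SparCC-style methods are out
  of scope).
* The fragmentation of a correlation block at fixed $\rho$ *reduces* total
  correlation mass, so fragmented communities have sparser planted networks;
  degree-entropy comparisons between one-block and fragmented configurations
  are direction-unstable when both networks are near-regular, and the test
  suite documents this regime honestly.
* The $t$ approximation for Spearman p-values is slightly liberal at
  $n = 8$ with heavy ties; an exact-permutation mode was considered and left
  out because the group-comparison layers only require the selection rule to
  be identical across groups.
* Bootstrap ANOVA on $B = 1000$ replicates treats replicates as
  observations; its p-values quantify separation of bootstrap distributions,
  not a sampling-theoretic group test, and should be read comparatively.
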