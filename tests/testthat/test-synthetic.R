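test_that("counts are multinomial at the configured depth and seeded deterministically", {
  cfg <- null_config(seed = 11)
  tab <- generate_counts(cfg)
  expect_s3_class(tab, "count_table")
  expect_identical(dim(tab$counts), c(24L, 20L))
  expect_true(all(tab$counts >= 0))
  expect_true(all(tab$counts == round(tab$counts)))
  expect_true(all(rowSums(tab$counts) == cfg$sequencing_depth))
  expect_identical(generate_counts(cfg)$counts, tab$counts)
  # a different seed moves the data
  expect_false(identical(generate_counts(null_config(seed = 12))$counts, tab$counts))
})

test_that("null configuration makes taxa exchangeable up to sampling noise", {
  cfg <- synthetic_config(n_groups = 1, n_samples_per_group = 200, n_taxa = 10,
                          sequencing_depth = 5000, baseline_sdlog = 0, seed = 3)
  tab <- generate_counts(cfg)
  shares <- colMeans(relative_abundance(tab))
  # flat baselines: every taxon should sit near 1/10
  expect_true(all(abs(shares - 0.1) < 0.02))
})

test_that("a planted log2 effect raises the group's mean relative abundance", {
  hits <- 0L
  for (s in 1:100) {
    cfg <- synthetic_config(
      n_groups = 2, n_samples_per_group = 30, n_taxa = 15,
      sequencing_depth = 2000,
      effect_spec = data.frame(taxon = 1L, group = 2L, log2_effect = 2),
      seed = s
    )
    relab <- relative_abundance(generate_counts(cfg))
    g <- rep(1:2, each = 30)
    if (mean(relab[g == 2, 1]) > mean(relab[g == 1, 1])) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("planted correlation blocks are recoverable and contained", {
  # block of 12 genera embedded in a 50-genus community at realistic depth
  cfg <- one_block_config(rho = 0.7, block = 12, n_taxa = 50,
                          n_per_group = 100, depth = 50000, seed = 5)
  relab <- relative_abundance(generate_counts(cfg))
  rho <- suppressWarnings(spearman_matrix(relab))$rho
  within <- rho[1:12, 1:12][upper.tri(diag(12))]
  across <- rho[1:12, 13:50]
  expect_gte(mean(within), 0.4)
  expect_lte(mean(abs(across)), 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_samples_per_group = 1), "2 samples")
  expect_error(one_block_config(rho = 1.0), "rho")
  expect_error(one_block_config(block = 30, n_taxa = 20), "n_taxa")
  expect_error(synthetic_config(
    n_groups = 1, n_taxa = 5,
    block_spec = list(list(list(size = 3, rho = 0.5),
                           list(size = 3, rho = 0.5)))),
    "exceed")
  expect_error(synthetic_config(
    n_taxa = 5,
    phenotype_spec = list(list(name = "x", taxon = 9, slope = 1,
                               noise_sd = 1, group_shift = c(0, 0, 0)))),
    "out of range")
})

test_that("unlinked noiseless phenotypes equal their group constants; linked ones track the taxon", {
  cfg <- synthetic_config(
    n_groups = 3, n_samples_per_group = 8, n_taxa = 10, sequencing_depth = 2000,
    phenotype_spec = list(
      list(name = "flat", taxon = NA, slope = 0, noise_sd = 0,
           group_shift = c(1, 2, 3)),
      list(name = "linked", taxon = 2, slope = 5, noise_sd = 0.1,
           group_shift = c(0, 0, 0))
    ),
    seed = 21
  )
  tab <- generate_counts(cfg)
  ph <- generate_phenotypes(cfg, tab)
  g <- as.integer(tab$groups)
  expect_equal(ph$values[, "flat"], c(1, 2, 3)[g], ignore_attr = TRUE)
  # the linked phenotype correlates strongly with the clr of its taxon
  rho <- cor(ph$values[, "linked"], clr_transform(tab)[, 2], method = "spearman")
  expect_gt(abs(rho), 0.8)
  # seeded determinism
  expect_identical(generate_phenotypes(cfg, tab)$values, ph$values)
})

test_that("null phenotypes are uncorrelated with taxa in most runs", {
  ok <- 0L
  for (s in 1:20) {
    cfg <- synthetic_config(
      n_groups = 3, n_samples_per_group = 8, n_taxa = 5, sequencing_depth = 2000,
      phenotype_spec = list(list(name = "noise", taxon = NA, slope = 0,
                                 noise_sd = 1, group_shift = c(0, 0, 0))),
      seed = 100 + s
    )
    tab <- generate_counts(cfg)
    ph <- generate_phenotypes(cfg, tab)
    r <- abs(cor(ph$values[, 1], relative_abundance(tab)))
    if (max(r) < 0.5) ok <- ok + 1L
  }
  expect_gte(ok, 18)  # >= 90% of seeds
})

test_that("pathways are nonnegative mixtures; identity mixing reproduces a taxon", {
  cfg <- null_config(n_taxa = 10, seed = 9)
  tab <- generate_counts(cfg)
  pwy <- generate_pathways(cfg, tab)
  expect_true(all(pwy$values >= 0))
  expect_identical(generate_pathways(cfg, tab)$values, pwy$values)

  mixing <- matrix(0, 10, 2)
  mixing[3, 1] <- 1  # pathway 1 = taxon 3 exactly
  exact <- generate_pathways(cfg, tab, mixing = mixing, noise_sdlog = 0)
  expect_equal(unname(exact$values[, 1]), unname(relative_abundance(tab)[, 3]))
  # all-zero mixing column degenerates to constant zero, flagged on rescale
  expect_true(all(exact$values[, 2] == 0))
  expect_identical(attr(rescale_unit(exact)$values, "flagged"), "pwy002")
})

test_that("generator calls leave the caller's RNG stream untouched", {
  set.seed(42)
  before <- .Random.seed
  invisible(generate_counts(null_config(seed = 1)))
  expect_identical(.Random.seed, before)
})
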