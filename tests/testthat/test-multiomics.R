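sample_ids <- function(n) sprintf("S%03d", seq_len(n))

test_that("min-max rescaling: arithmetic, idempotence, degenerate flagging", {
  m <- matrix(c(2, 4, 6), 3, dimnames = list(sample_ids(3), "f"))
  expect_equal(unname(rescale_unit(m)[, 1]), c(0, 0.5, 1))
  already <- matrix(c(0, 0.25, 1), 3, dimnames = list(sample_ids(3), "f"))
  expect_equal(unname(rescale_unit(already)), unname(already), ignore_attr = TRUE)
  const <- matrix(c(5, 5, 5, 1, 2, 3), 3,
                  dimnames = list(sample_ids(3), c("flat", "ok")))
  out <- rescale_unit(const)
  expect_equal(unname(out[, "flat"]), c(0, 0, 0))
  expect_identical(attr(out, "flagged"), "flat")
  expect_error(rescale_unit(matrix(c(1, NA), 1)), "finite")
})

test_that("BY adjustment matches hand-derived values and p.adjust semantics", {
  expect_equal(by_adjust(0.03), 0.03)                    # m = 1 identity
  got <- by_adjust(c(0.01, 0.02, 0.04))                  # c(3) = 11/6
  expect_equal(got, c(0.055, 0.055, 0.04 * 11 / 6), tolerance = 1e-12)
  expect_equal(by_adjust(rep(1, 5)), rep(1, 5))          # cap at 1
  expect_error(by_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(by_adjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("BY and BH match brute-force step-up oracles and BY >= BH", {
  set.seed(90)
  for (i in 1:20) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    by <- by_adjust(p)
    expect_lt(max(abs(by - oracle_by(p))), 1e-12)
    bh <- p.adjust(p, "BH")
    expect_lt(max(abs(bh - oracle_bh(p))), 1e-12)
    expect_true(all(by >= bh - 1e-15))
    # monotone: order of adjusted values preserves order of raw values
    expect_true(all(diff(by[order(p)]) >= -1e-15))
  }
})

test_that("multi-omic graph joins blocks, tags nodes, and finds a duplicated feature", {
  set.seed(91)
  n <- 10
  base <- rnorm(n)
  a <- omics_block(matrix(c(base, rnorm(n)), n,
                          dimnames = list(sample_ids(n), c("x", "y"))), "genus")
  b <- omics_block(matrix(c(base * 3 + 1, rnorm(n)), n,
                          dimnames = list(sample_ids(n), c("x", "z"))), "phenotype")
  g <- multiomic_graph(list(a, b), alpha = 0.05)
  expect_setequal(igraph::V(g)$name,
                  c("genus.x", "genus.y", "phenotype.x", "phenotype.z"))
  expect_setequal(unique(igraph::V(g)$block), c("genus", "phenotype"))
  et <- edge_table(g)
  dup <- et[(et$from == "genus.x" & et$to == "phenotype.x") |
            (et$from == "phenotype.x" & et$to == "genus.x"), ]
  expect_identical(nrow(dup), 1L)   # monotone copy -> |rho| = 1 edge survives BY
  expect_equal(dup$weight, 1)
})

test_that("sample alignment: inner join drops unshared samples, few shared errors", {
  a <- omics_block(matrix(rnorm(12), 6, dimnames = list(sample_ids(6), c("x", "y"))),
                   "genus")
  b_vals <- matrix(rnorm(10), 5, dimnames = list(sample_ids(5), c("u", "v")))
  b <- omics_block(b_vals, "pathway")
  expect_message(multiomic_graph(list(a, b), alpha = 0.9), "dropping 1 sample")
  tiny <- omics_block(matrix(rnorm(6), 3, dimnames = list(sample_ids(3), c("u", "v"))),
                      "pathway")
  expect_error(multiomic_graph(list(a, tiny)), "fewer than 4")
  expect_error(multiomic_graph(list(a)), "length")
  expect_error(multiomic_graph(list(a, omics_block(b_vals, "genus"))), "distinct")
})

test_that("rescaling is edge-neutral: rank correlations ignore the display convention", {
  cfg <- synthetic_config(
    n_groups = 1, n_samples_per_group = 24, n_taxa = 8, sequencing_depth = 3000,
    phenotype_spec = list(list(name = "bp", taxon = 2, slope = 5, noise_sd = 0.2,
                               group_shift = 0)),
    seed = 92
  )
  tab <- generate_counts(cfg)
  ph <- generate_phenotypes(cfg, tab)
  genus <- omics_block(relative_abundance(tab), "genus")
  g1 <- multiomic_graph(list(genus, ph), alpha = 0.2)
  # scale/shift the inputs wildly: the edge set must not move
  genus2 <- omics_block(relative_abundance(tab) * 1e4 + 7, "genus")
  ph2 <- omics_block(ph$values * -3 + 100, "phenotype")
  g2 <- multiomic_graph(list(genus2, ph2), alpha = 0.2)
  e1 <- edge_table(g1); e2 <- edge_table(g2)
  expect_setequal(paste(e1$from, e1$to), paste(e2$from, e2$to))
})

test_that("between_only restricts the test family to cross-block pairs", {
  set.seed(93)
  n <- 12
  base <- rnorm(n)
  # a strong within-block pair (x ~ y) and a strong cross pair (x ~ u)
  a <- omics_block(matrix(c(base, base * 2 + 1, rnorm(n)), n,
                          dimnames = list(sample_ids(n), c("x", "y", "z"))),
                   "genus")
  b <- omics_block(matrix(c(-base, rnorm(n)), n,
                          dimnames = list(sample_ids(n), c("u", "v"))),
                   "phenotype")
  g_all <- multiomic_graph(list(a, b), alpha = 0.05)
  e_all <- edge_table(g_all)
  expect_true("genus.y" %in% c(e_all$from, e_all$to))  # within edge found
  g_btw <- multiomic_graph(list(a, b), alpha = 0.05, between_only = TRUE)
  e_btw <- edge_table(g_btw)
  blocks <- setNames(igraph::V(g_btw)$block, igraph::V(g_btw)$name)
  expect_gte(nrow(e_btw), 1L)
  expect_true(all(blocks[e_btw$from] != blocks[e_btw$to]))
})
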