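test_that("spearman_matrix reproduces textbook values and limits", {
  x <- 1:5
  y <- c(2, 1, 4, 3, 5)
  res <- spearman_matrix(cbind(a = x, b = y))
  expect_equal(res$rho["a", "b"], 0.8)  # 1 - 6*4/(5*24)
  res2 <- spearman_matrix(cbind(a = x, b = exp(x)))  # monotone identical
  expect_equal(res2$rho["a", "b"], 1)
  expect_equal(res2$pvalue["a", "b"], 0)
  res3 <- spearman_matrix(cbind(a = x, b = -x))
  expect_equal(res3$rho["a", "b"], -1)
})

test_that("spearman_matrix matches the midrank-then-Pearson oracle with and without ties", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    p <- sample(3:6, 1)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("c", 1:p)))
    if (i %% 2 == 0) {
      x <- round(x)  # inject ties
      if (any(apply(x, 2, var) == 0)) next
    }
    got <- spearman_matrix(x)
    expect_lt(max(abs(got$rho - oracle_spearman(x))), 1e-12)
  }
})

test_that("p-values follow the t approximation with n-2 df", {
  set.seed(5)
  x <- matrix(rnorm(30), 10, 3)
  res <- spearman_matrix(x)
  rho <- res$rho[1, 2]
  t <- rho * sqrt((10 - 2) / (1 - rho^2))
  expect_equal(res$pvalue[1, 2], 2 * pt(-abs(t), df = 8))
})

test_that("degenerate inputs are handled per contract", {
  expect_error(spearman_matrix(matrix(rnorm(4), 2, 2)), "3 samples")
  expect_error(spearman_matrix(matrix(1, 5, 3)), "constant")
  x <- cbind(a = rnorm(6), b = rep(2, 6), c = rnorm(6))
  expect_warning(res <- spearman_matrix(x), "dropping")
  expect_identical(res$dropped, "b")
  expect_identical(res$features, c("a", "c"))
})

test_that("graph retains exactly the sub-alpha edges with |rho| weights", {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- -0.9
  rho[1, 3] <- rho[3, 1] <- 0.5
  rho[2, 3] <- rho[3, 2] <- 0.1
  p <- matrix(c(0, 0.04, 0.20, 0.04, 0, 0.6, 0.20, 0.6, 0), 3)
  corr <- structure(list(rho = rho, pvalue = p, features = c("a", "b", "c"),
                         dropped = character(), n_samples = 10),
                    class = "correlation_result")
  g <- build_graph(corr, 0.05)
  et <- edge_table(g)
  expect_identical(nrow(et), 1L)
  expect_setequal(c(et$from, et$to), c("a", "b"))
  expect_equal(et$weight, 0.9)    # negative correlation enters by magnitude
  expect_equal(et$rho, -0.9)
  expect_equal(as.numeric(igraph::vcount(g)), 3)  # isolated node kept
  # alpha = 1 disables the filter entirely
  expect_equal(as.numeric(igraph::ecount(build_graph(corr, 1))), 3)
})

test_that("lowering alpha never adds edges and weights are rank-invariant", {
  set.seed(8)
  x <- matrix(rnorm(80), 10, 8)
  corr <- spearman_matrix(x)
  alphas <- c(0.01, 0.05, 0.2, 0.5, 1)
  m <- vapply(alphas, function(a) as.numeric(igraph::ecount(build_graph(corr, a))),
              numeric(1))
  expect_true(all(diff(m) >= 0))
  # strictly monotone transforms of columns leave the graph unchanged
  y <- x
  y[, 1] <- exp(x[, 1]); y[, 4] <- x[, 4]^3 + 2
  ga <- edge_table(build_graph(spearman_matrix(x), 0.3))
  gb <- edge_table(build_graph(spearman_matrix(y), 0.3))
  expect_equal(ga, gb)
})

test_that("spectral clustering separates disconnected cliques and is seed-stable", {
  el <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- paste0("v", 1:8)
  lab <- spectral_clusters(g, 2, seed = 3)
  expect_identical(length(unique(lab[1:4])), 1L)
  expect_identical(length(unique(lab[5:8])), 1L)
  expect_false(lab[1] == lab[5])
  expect_identical(spectral_clusters(g, 2, seed = 3), lab)
  expect_error(spectral_clusters(g, 9, seed = 1), "exceeds")
})

test_that("strong planted two-block structure is recovered exactly", {
  # two 4-taxon blocks planted inside a 40-genus community; the network over
  # the planted taxa separates them perfectly (embedding the blocks in a
  # larger community keeps compositional-closure anticorrelation negligible)
  cfg <- synthetic_config(
    n_groups = 1, n_samples_per_group = 100, n_taxa = 40,
    sequencing_depth = 5000,
    block_spec = list(list(list(size = 4, rho = 0.8), list(size = 4, rho = 0.8))),
    seed = 13
  )
  relab <- relative_abundance(generate_counts(cfg))[, 1:8]
  g <- build_graph(spearman_matrix(relab), 0.05)
  lab <- spectral_clusters(g, 2, seed = 1)
  planted <- rep(1:2, each = 4)
  expect_equal(oracle_ari(lab, planted), 1.0)
})

test_that("eigengap heuristic finds the planted number of communities", {
  cfg <- four_block_config(rho = 0.8, n_per_group = 100, seed = 17)
  relab <- relative_abundance(generate_counts(cfg))
  g <- build_graph(suppressWarnings(spearman_matrix(relab)), 0.01)
  expect_identical(choose_k_eigengap(g), 4L)
})
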