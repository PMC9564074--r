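# Independent brute-force oracles used throughout the suite. These are
# deliberately naive implementations that share no code with the package.

# Midrank a vector by explicit sorting and tie-averaging.
oracle_midrank <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Spearman rho matrix: midrank every column, then pairwise Pearson.
oracle_spearman <- function(x) {
  p <- ncol(x)
  rho <- diag(p)
  ranks <- apply(x, 2, oracle_midrank)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    rho[i, j] <- rho[j, i] <- oracle_pearson(ranks[, i], ranks[, j])
  }
  rho
}

# Step-up FDR adjustments written directly from the definitions.
oracle_stepup <- function(p, factor) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  cur <- 1
  for (k in m:1) {
    cur <- min(cur, p[ord[k]] * factor * m / k)
    adj[ord[k]] <- cur
  }
  pmin(adj, 1)
}
oracle_bh <- function(p) oracle_stepup(p, 1)
oracle_by <- function(p) oracle_stepup(p, sum(1 / seq_along(p)))

# Global network statistics from an adjacency matrix, by explicit
# enumeration of degrees, triangles and connected triples.
oracle_network_stats <- function(A) {
  n <- nrow(A)
  deg <- unname(rowSums(A))
  m <- sum(A) / 2
  density <- 2 * m / (n * (n - 1))
  f <- as.numeric(table(deg)) / n
  entropy <- -sum(f * log(f))
  centralization <- if (n > 2) sum(max(deg) - deg) / ((n - 1) * (n - 2)) else 0
  heterogeneity <- if (mean(deg) == 0) 0 else sd(deg) / mean(deg)
  triangles <- 0
  triples <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i < j && j < k) {
          triangles <- triangles + A[i, j] * A[j, k] * A[i, k]
        }
      }
    }
    triples <- triples + choose(deg[i], 2)
  }
  clustering <- if (triples == 0) 0 else 3 * triangles / triples
  list(density = density, shannon_entropy = entropy,
       centralization = centralization, heterogeneity = heterogeneity,
       clustering_coefficient = clustering)
}

# One-way ANOVA F from textbook sums of squares.
oracle_anova_F <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ss_b <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ss_w <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  F <- (ss_b / df_b) / (ss_w / df_w)
  list(F = F, p = pf(F, df_b, df_w, lower.tail = FALSE))
}

# Random Erdos-Renyi igraph for oracle comparisons.
random_graph <- function(n, p) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  rownames(A) <- colnames(A) <- sprintf("v%02d", seq_len(n))
  list(A = A, g = igraph::graph_from_adjacency_matrix(A, mode = "undirected"))
}

# Adjusted Rand index between two labelings (contingency-table form).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
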