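#' Bray-Curtis dissimilarity between samples
#'
#' Computes the Bray-Curtis distance matrix on relative abundances,
#' `d(a, b) = sum|a_i - b_i| / sum(a_i + b_i)`; 0 for identical profiles, 1
#' for disjoint supports. The heavy lifting is delegated to
#' [vegan::vegdist()].
#'
#' @param table A [count_table()] or a nonnegative matrix (samples x taxa).
#' @param use_relative Normalize rows to proportions first (default TRUE;
#'   with equal sequencing depths the two choices coincide).
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(table, use_relative = TRUE) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  if (any(rowSums(x) == 0)) stop("zero-total sample: Bray-Curtis undefined")
  if (use_relative) x <- relative_abundance(x)
  vegan::vegdist(x, method = "bray")
}

# Pseudo-F from Anderson's partitioning of squared distances.
# d2: squared distance matrix; split: list of index vectors per group.
permanova_F <- function(d2, split, n, g) {
  ss_total <- sum(d2) / (2 * n)
  ss_within <- sum(vapply(split, function(idx) {
    sum(d2[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
  ss_between <- ss_total - ss_within
  list(F = (ss_between / (g - 1)) / (ss_within / (n - g)),
       R2 = ss_between / ss_total)
}

# All permutations of 1..n (n <= 8 guard), for exhaustive tests.
all_perms <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Permutational multivariate analysis of variance
#'
#' PERMANOVA on an inter-sample distance matrix: the pseudo-F statistic
#' partitions the sum of squared distances into between- and within-group
#' components (`SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` from
#' within-group pairs), and significance comes from permuting the group
#' labels. The p-value includes the observed statistic,
#' `p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1)`.
#'
#' @param dist A `dist` or square symmetric distance matrix.
#' @param groups Group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @param n_perm Number of random label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exhaustive Enumerate all label permutations instead of sampling
#'   (exact p; feasible for n <= 8). The identity permutation counts as one
#'   of the enumerated statistics.
#' @return Object of class `permanova_result`: list with `pseudo_F`, `R2`,
#'   `p`, `n_permutations`, `df`.
#' @export
permanova <- function(dist, groups, n_perm = 999L, seed = 1L,
                      exhaustive = FALSE) {
  d <- as.matrix(dist)
  n <- nrow(d)
  groups <- factor(groups)
  if (length(groups) != n) stop("one group label per sample required")
  g <- nlevels(groups)
  if (g < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("singleton group: PERMANOVA undefined")
  d2 <- d^2
  split0 <- split(seq_len(n), groups)
  obs <- permanova_F(d2, split0, n, g)

  if (exhaustive) {
    perms <- all_perms(n)
    Fs <- apply(perms, 1, function(pm) {
      permanova_F(d2, split(pm, groups), n, g)$F
    })
    p <- mean(Fs >= obs$F - 1e-12)
    n_used <- nrow(perms)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    count <- 0L
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      if (permanova_F(d2, split(pm, groups), n, g)$F >= obs$F - 1e-12) {
        count <- count + 1L
      }
    }
    p <- (count + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(pseudo_F = obs$F, R2 = obs$R2, p = p,
                 n_permutations = n_used, df = c(g - 1L, n - g)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$R2, x$p, x$n_permutations))
  invisible(x)
}

#' Pairwise Adonis comparisons
#'
#' Runs [permanova()] on every pair of groups and adjusts the per-pair
#' p-values for multiplicity.
#'
#' @inheritParams permanova
#' @param adjust Multiple-testing adjustment across pairs: `"BH"` (default)
#'   or `"BY"`.
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `pseudo_F`, `R2`, `p`, `p_adjusted`.
#' @export
pairwise_adonis <- function(dist, groups, n_perm = 999L, adjust = c("BH", "BY"),
                            seed = 1L) {
  adjust <- match.arg(adjust)
  d <- as.matrix(dist)
  groups <- factor(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    keep <- groups %in% pr
    fit <- permanova(d[keep, keep], droplevels(groups[keep]),
                     n_perm = n_perm, seed = split_seed(seed, i))
    data.frame(group_a = pr[1], group_b = pr[2],
               pseudo_F = fit$pseudo_F, R2 = fit$R2, p = fit$p)
  }))
  res$p_adjusted <- stats::p.adjust(res$p, method = adjust)
  res
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples (e.g. richness between groups). The U
#' statistics are computed from midranks; the two-sided p-value is the exact
#' permutation p when both samples are small and tie-free, and otherwise the
#' normal approximation with tie and continuity correction, via
#' [stats::wilcox.test()].
#'
#' @param x,y Numeric vectors (non-empty).
#' @return List with `U_x`, `U_y`, `p`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty input")
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y)
  U_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            correct = TRUE))
  list(U_x = U_x, U_y = nx * ny - U_x, p = wt$p.value)
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' Fits `values ~ group` by [stats::aov()] and reports the omnibus F-test
#' plus all pairwise comparisons adjusted by the studentized-range (Tukey
#' HSD) distribution.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation (>= 2 groups, each >= 2
#'   observations).
#' @return List with `F`, `p`, `df` (between, within), and `tukey`, a data
#'   frame of pairwise rows: `group_a`, `group_b`, `diff`, `p_adjusted`.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 observations")
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0)) stop("zero within-group variance in every group")
  fit <- stats::aov(values ~ groups, data = data.frame(values = values, groups = groups))
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(
    group_a = vapply(pairs, `[`, "", 1),
    group_b = vapply(pairs, `[`, "", 2),
    diff = tk[, "diff"],
    p_adjusted = tk[, "p adj"],
    row.names = NULL
  )
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df = c(tab[1, "Df"], tab[2, "Df"]), tukey = tukey)
}
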