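#' Configuration of the synthetic study
#'
#' Describes a synthetic microbiome study in the design of the hypertensive-rat
#' experiment the pipeline was written for: a small number of treatment groups
#' with equal numbers of animals, genus-level 16S counts at a fixed sequencing
#' depth, group-specific planted correlation blocks among taxa, planted
#' enrichment/suppression effects, and continuous phenotypes optionally linked
#' to a taxon.
#'
#' Counts are generated from a logistic-normal/multinomial model: a latent
#' Gaussian vector with block-structured correlation is added to per-taxon
#' baseline log-abundances, mapped through a softmax to a composition, and
#' read counts are drawn multinomially at `sequencing_depth`. Effects are
#' applied on the latent log scale so `log2_effect` is interpretable as an
#' approximate fold change of relative abundance.
#'
#' @param n_groups Number of experimental groups (default 3: control,
#'   hypertensive, treated).
#' @param n_samples_per_group Animals per group (default 8).
#' @param n_taxa Number of genus-level taxa (default 200).
#' @param sequencing_depth Reads per sample (default 50000).
#' @param block_spec List of length `n_groups`; element `g` is a list of
#'   `list(size =, rho =)` correlation blocks planted in group `g`
#'   (equicorrelation `rho` within the block, 0 across blocks). Blocks are
#'   laid out over the first taxa in order. `NULL` means no planted
#'   correlation anywhere.
#' @param effect_spec Data frame with columns `taxon` (index), `group`
#'   (index), `log2_effect`: per-group shifts of the latent log abundance in
#'   log2 units. `NULL` for none.
#' @param phenotype_spec List of `list(name =, taxon = index or NA, slope =,
#'   noise_sd =, group_shift = numeric(n_groups))` describing continuous
#'   phenotypes. A linked phenotype tracks the centered log-ratio abundance
#'   of its taxon with the given slope. `NULL` for none.
#' @param baseline_sdlog Standard deviation of the per-taxon baseline
#'   log-abundances (lognormal baseline means; default 1.5 gives a few
#'   dominant genera and a long tail, as real genus tables show).
#' @param latent_sd Standard deviation of the latent Gaussian fluctuation
#'   around the baseline (default 1).
#' @param group_labels Optional character vector of group names; defaults to
#'   Control / DOCA / Captopril for three groups, `G1..Gk` otherwise.
#' @param seed Integer master seed. Every generator operation derives its own
#'   stream from it (see Details), so each is individually reproducible.
#'
#' @details A single master seed feeds a fixed per-operation splitting scheme:
#' operation `k` (counts = 1, phenotypes = 2, pathways = 3, ...) uses
#' `(seed * 1009 + k) mod (2^31 - 1)`. Calling the same operation twice with
#' the same config yields bit-identical output regardless of what else ran.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_groups = 3L,
                             n_samples_per_group = 8L,
                             n_taxa = 200L,
                             sequencing_depth = 50000L,
                             block_spec = NULL,
                             effect_spec = NULL,
                             phenotype_spec = NULL,
                             baseline_sdlog = 1.5,
                             latent_sd = 1,
                             group_labels = NULL,
                             seed = 1L) {
  if (n_samples_per_group < 2) stop("configuration error: need >= 2 samples per group")
  if (n_taxa < 1 || n_groups < 1) stop("configuration error: empty design")
  if (is.null(group_labels)) {
    group_labels <- if (n_groups == 3) c("Control", "DOCA", "Captopril")
                    else paste0("G", seq_len(n_groups))
  }
  stopifnot(length(group_labels) == n_groups)
  if (is.null(block_spec)) block_spec <- rep(list(list()), n_groups)
  if (length(block_spec) != n_groups) {
    stop("configuration error: block_spec must have one entry per group")
  }
  for (g in seq_len(n_groups)) {
    sizes <- vapply(block_spec[[g]], function(b) as.numeric(b$size), numeric(1))
    rhos <- vapply(block_spec[[g]], function(b) as.numeric(b$rho), numeric(1))
    if (any(rhos < 0 | rhos >= 1)) {
      stop("configuration error: within-block rho must lie in [0, 1) to keep the block covariance positive definite")
    }
    if (length(sizes) && max(sizes) > n_taxa) {
      stop("configuration error: a block is larger than n_taxa")
    }
    if (sum(sizes) > n_taxa) {
      stop("configuration error: block sizes in a group exceed n_taxa")
    }
  }
  if (!is.null(effect_spec)) {
    effect_spec <- as.data.frame(effect_spec)
    stopifnot(all(c("taxon", "group", "log2_effect") %in% names(effect_spec)))
    if (any(effect_spec$taxon < 1 | effect_spec$taxon > n_taxa)) {
      stop("configuration error: effect taxon index out of range")
    }
    if (any(effect_spec$group < 1 | effect_spec$group > n_groups)) {
      stop("configuration error: effect group index out of range")
    }
  }
  if (!is.null(phenotype_spec)) {
    for (ph in phenotype_spec) {
      stopifnot(all(c("name", "taxon", "slope", "noise_sd", "group_shift") %in% names(ph)))
      if (length(ph$group_shift) != n_groups) {
        stop("configuration error: group_shift must have one value per group")
      }
      if (!is.na(ph$taxon) && (ph$taxon < 1 || ph$taxon > n_taxa)) {
        stop("linked taxon index out of range")
      }
    }
  }
  structure(list(
    n_groups = as.integer(n_groups),
    n_samples_per_group = as.integer(n_samples_per_group),
    n_taxa = as.integer(n_taxa),
    sequencing_depth = as.integer(sequencing_depth),
    block_spec = block_spec,
    effect_spec = effect_spec,
    phenotype_spec = phenotype_spec,
    baseline_sdlog = baseline_sdlog,
    latent_sd = latent_sd,
    group_labels = group_labels,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Per-operation seed stream: deterministic split of the master seed.
split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}

# Lower-triangular factor of an equicorrelation block (1-rho)I + rho J.
block_chol <- function(size, rho) {
  R <- matrix(rho, size, size)
  diag(R) <- 1
  U <- tryCatch(chol(R), error = function(e) {
    stop("configuration error: block covariance is not positive definite")
  })
  t(U)
}

# Latent mean shifts per group from effect_spec, in natural-log units.
effect_matrix <- function(config) {
  eff <- matrix(0, config$n_groups, config$n_taxa)
  if (!is.null(config$effect_spec)) {
    for (i in seq_len(nrow(config$effect_spec))) {
      e <- config$effect_spec[i, ]
      eff[e$group, e$taxon] <- eff[e$group, e$taxon] + log(2) * e$log2_effect
    }
  }
  eff
}

#' Simulate a genus-level count table
#'
#' Draws the synthetic study's 16S genus counts under the logistic-normal/
#' multinomial model of [synthetic_config()]. For each sample in group `g` a
#' latent vector `z` is drawn from a multivariate normal with the group's
#' planted block correlation (unit variances, zero correlation off-block),
#' scaled by `latent_sd`, added to the per-taxon baseline log-abundances and
#' the group's planted effects, softmax-mapped to a composition, and counts
#' are drawn `multinomial(sequencing_depth, composition)`.
#'
#' @param config A [synthetic_config()].
#' @return A [count_table()] with `n_groups * n_samples_per_group` samples.
#'   Each sample's counts sum to `sequencing_depth` exactly.
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr_seed <- split_seed(config$seed, 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)

  p <- config$n_taxa
  baseline <- log(stats::rlnorm(p, meanlog = 0, sdlog = config$baseline_sdlog))
  chols <- lapply(seq_len(config$n_groups), function(g) {
    lapply(config$block_spec[[g]], function(b) block_chol(b$size, b$rho))
  })
  eff <- effect_matrix(config)

  n <- config$n_groups * config$n_samples_per_group
  counts <- matrix(0L, n, p)
  groups <- character(n)
  row <- 0L
  for (g in seq_len(config$n_groups)) {
    blocks <- config$block_spec[[g]]
    for (s in seq_len(config$n_samples_per_group)) {
      row <- row + 1L
      z <- stats::rnorm(p)
      at <- 1L
      for (bi in seq_along(blocks)) {
        size <- blocks[[bi]]$size
        idx <- at:(at + size - 1L)
        z[idx] <- as.numeric(chols[[g]][[bi]] %*% z[idx])
        at <- at + size
      }
      latent <- baseline + config$latent_sd * z + eff[g, ]
      comp <- exp(latent - max(latent))
      comp <- comp / sum(comp)
      counts[row, ] <- as.integer(stats::rmultinom(1, config$sequencing_depth, comp))
      groups[row] <- config$group_labels[g]
    }
  }
  rownames(counts) <- sprintf("S%03d", seq_len(n))
  colnames(counts) <- sprintf("g%03d", seq_len(p))
  count_table(counts, groups)
}

# Save/restore the global RNG state so generator calls do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Centered log-ratio transform of a count table
#'
#' Adds a half-read pseudocount, converts to relative abundance and applies
#' the clr: `log(x_i / geometric mean(x))` per sample. Used by the phenotype
#' generator to link phenotypes to a taxon on a scale where correlations are
#' well behaved, and exported because it is generally useful for
#' compositional tables.
#'
#' @param table A [count_table()] or a nonnegative numeric matrix
#'   (samples x taxa).
#' @param pseudocount Added to every count before the log (default 0.5).
#' @return Numeric matrix of clr values, same dimensions and names.
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  lx <- log(x + pseudocount)
  sweep(lx, 1, rowMeans(lx), "-")
}

#' Simulate taxon-linked phenotypes
#'
#' Generates the continuous phenotypes declared in the config (blood
#' pressure, trabecular bone measures, ...). Each phenotype equals its
#' group-specific shift plus `slope` times the clr abundance of its linked
#' taxon (0 when unlinked) plus Gaussian noise.
#'
#' @param config A [synthetic_config()] with a non-empty `phenotype_spec`.
#' @param counts The [count_table()] generated from the same config.
#' @return An [omics_block()] tagged `"phenotype"`.
#' @export
generate_phenotypes <- function(config, counts) {
  stopifnot(inherits(config, "synthetic_config"), inherits(counts, "count_table"))
  if (is.null(config$phenotype_spec) || !length(config$phenotype_spec)) {
    stop("config declares no phenotypes")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(split_seed(config$seed, 2L))

  clr <- clr_transform(counts)
  g_of <- match(as.character(counts$groups), config$group_labels)
  n <- nrow(counts$counts)
  vals <- sapply(config$phenotype_spec, function(ph) {
    link <- if (is.na(ph$taxon)) rep(0, n) else clr[, ph$taxon]
    ph$group_shift[g_of] + ph$slope * link + stats::rnorm(n, sd = ph$noise_sd)
  })
  vals <- matrix(vals, nrow = n,
                 dimnames = list(rownames(counts$counts),
                                 vapply(config$phenotype_spec, `[[`, "", "name")))
  omics_block(vals, "phenotype")
}

#' Simulate microbial pathway abundances
#'
#' Emulates functionally profiled pathway abundances at reduced scale: each
#' pathway is a nonnegative linear combination of a small random subset of
#' taxa relative abundances, multiplied by lognormal noise.
#'
#' @param config A [synthetic_config()].
#' @param counts The [count_table()] generated from the same config.
#' @param n_pathways Number of pathways (default 20).
#' @param mixing Optional explicit nonnegative mixing matrix
#'   (`n_taxa` x `n_pathways`); when supplied, the random subset step is
#'   skipped. A pathway with all-zero weights yields a constant zero column
#'   (flagged as degenerate downstream).
#' @param noise_sdlog `sdlog` of the multiplicative lognormal noise
#'   (default 0.25; 0 disables noise exactly).
#' @return An [omics_block()] tagged `"pathway"`; all values are
#'   nonnegative.
#' @export
generate_pathways <- function(config, counts, n_pathways = 20L,
                              mixing = NULL, noise_sdlog = 0.25) {
  stopifnot(inherits(config, "synthetic_config"), inherits(counts, "count_table"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(split_seed(config$seed, 3L))

  p <- config$n_taxa
  relab <- relative_abundance(counts)
  if (is.null(mixing)) {
    mixing <- matrix(0, p, n_pathways)
    for (j in seq_len(n_pathways)) {
      k <- sample(1:5, 1)
      sub <- sample(p, k)
      mixing[sub, j] <- stats::runif(k, 0.2, 1)
    }
  } else {
    mixing <- as.matrix(mixing)
    if (nrow(mixing) != p) stop("mixing must have one row per taxon")
    if (any(mixing < 0)) stop("mixing weights must be nonnegative")
    n_pathways <- ncol(mixing)
  }
  vals <- relab %*% mixing
  if (noise_sdlog > 0) {
    vals <- vals * matrix(stats::rlnorm(length(vals), 0, noise_sdlog),
                          nrow(vals), ncol(vals))
  }
  colnames(vals) <- sprintf("pwy%03d", seq_len(n_pathways))
  rownames(vals) <- rownames(counts$counts)
  omics_block(vals, "pathway")
}

#' Default study-shaped configuration
#'
#' A ready-made [synthetic_config()] mirroring the design the pipeline
#' emulates: 3 groups of 8 animals, 200 genera at 50000 reads/sample; the
#' control community carries one large correlation block that is broken into
#' several small blocks in the hypertensive group and partly restored in the
#' treated group; four genera carry planted enrichment/suppression patterns
#' (one enriched under hypertension and rebalanced by treatment, two
#' suppressed, one enriched without rebalancing); blood pressure and four
#' trabecular bone phenotypes are linked to planted taxa.
#'
#' @param seed Master seed.
#' @param n_samples_per_group Animals per group (default 8).
#' @return A [synthetic_config()].
#' @export
study_config <- function(seed = 1L, n_samples_per_group = 8L) {
  blocks <- list(
    Control   = list(list(size = 16L, rho = 0.65)),
    DOCA      = list(list(size = 4L, rho = 0.65), list(size = 4L, rho = 0.65),
                     list(size = 4L, rho = 0.65), list(size = 4L, rho = 0.65)),
    Captopril = list(list(size = 8L, rho = 0.65), list(size = 8L, rho = 0.65))
  )
  # taxon 21: enriched under hypertension, rebalanced by treatment
  # taxa 22, 23: suppressed under hypertension, not restored
  # taxon 24: enriched under hypertension, not restored
  effects <- data.frame(
    taxon       = c(21L, 22L, 23L, 24L, 22L, 23L, 24L),
    group       = c(2L, 2L, 2L, 2L, 3L, 3L, 3L),
    log2_effect = c(2, -2, -2, 2, -2, -2, 2)
  )
  phen <- list(
    list(name = "SBP", taxon = 21L, slope = 8, noise_sd = 4,
         group_shift = c(125, 165, 140)),
    list(name = "BVTV", taxon = 21L, slope = -0.02, noise_sd = 0.015,
         group_shift = c(0.45, 0.32, 0.35)),
    list(name = "TbTh", taxon = 24L, slope = -0.004, noise_sd = 0.004,
         group_shift = c(0.085, 0.070, 0.078)),
    list(name = "TbSp", taxon = 21L, slope = 0.01, noise_sd = 0.012,
         group_shift = c(0.22, 0.30, 0.28)),
    list(name = "TbN", taxon = 21L, slope = -0.15, noise_sd = 0.25,
         group_shift = c(5.2, 4.2, 4.4))
  )
  synthetic_config(
    n_groups = 3L, n_samples_per_group = n_samples_per_group,
    n_taxa = 200L, sequencing_depth = 50000L,
    block_spec = blocks, effect_spec = effects, phenotype_spec = phen,
    seed = seed
  )
}
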