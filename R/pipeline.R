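#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Either a
#' [synthetic_config()] (data are simulated) or paths to an existing count
#' table + metadata TSV may be given.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading from
#'   files.
#' @param counts_path,metadata_path Input TSVs when `synthetic` is `NULL`.
#' @param alpha_edge Raw-p threshold for genus-network edges (default 0.05).
#' @param alpha_by BY-adjusted-p threshold for multi-omic edges
#'   (default 0.05).
#' @param B Bootstrap replicates per group (default 1000).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param k_clusters Spectral-cluster count, or `"auto"` for the eigengap
#'   heuristic.
#' @param top_k Taxa named in the abundance summary (default 20).
#' @param seed Master seed; each stage derives its own stream.
#' @param out_dir Output directory (created if needed).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, counts_path = NULL,
                            metadata_path = NULL, alpha_edge = 0.05,
                            alpha_by = 0.05, B = 1000L, n_perm = 999L,
                            k_clusters = "auto", top_k = 20L, seed = 1L,
                            out_dir = tempfile("gutorg_run_")) {
  stopifnot(alpha_edge > 0, alpha_edge < 1, alpha_by > 0, alpha_by < 1,
            B >= 1, n_perm >= 1)
  if (is.null(synthetic) && (is.null(counts_path) || is.null(metadata_path))) {
    stop("either `synthetic` or both input paths must be given")
  }
  structure(list(synthetic = synthetic, counts_path = counts_path,
                 metadata_path = metadata_path, alpha_edge = alpha_edge,
                 alpha_by = alpha_by, B = as.integer(B),
                 n_perm = as.integer(n_perm), k_clusters = k_clusters,
                 top_k = as.integer(top_k), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `synthetic`
#' mapping holds [synthetic_config()] fields, with `block_spec` as a list of
#' per-group lists of `{size, rho}` and `effect_spec` as a list of
#' `{taxon, group, log2_effect}` records.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    if (!is.null(s$effect_spec)) {
      s$effect_spec <- do.call(rbind, lapply(s$effect_spec, as.data.frame))
    }
    syn <- do.call(synthetic_config, s)
  }
  args <- y[setdiff(names(y), "synthetic")]
  do.call(pipeline_config, c(list(synthetic = syn), args))
}

stage_log <- function(log, stage, fmt, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
  message(line)
  c(log, line)
}

#' Run the end-to-end organization analysis
#'
#' Executes the full pipeline: simulate (or read) the genus count table,
#' profile abundances and diversity, build and cluster the per-group
#' correlation networks, bootstrap the topology parameters and compare them
#' across groups, select differential genera and pathways with PC
#' projections, assemble the multi-omic network, and run
#' PERMANOVA / pairwise Adonis. Every artifact is written as TSV (GraphML
#' for the multi-omic network) under `config$out_dir`, and a manifest with
#' MD5 content hashes is written last; rerunning with the same config and
#' seed reproduces identical hashes.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `manifest` (data frame of `file`, `md5`)
#'   and `log` (character vector of stage messages).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out, name)
    write_tsv(df, path)
    files <<- c(files, path)
    path
  }

  # stage 1: data
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    table <- generate_counts(sc)
    log <- stage_log(log, "simulate", "generated %d samples x %d taxa (seed %d)",
                     nrow(table$counts), ncol(table$counts), sc$seed)
    write_count_table(table, file.path(out, "counts.tsv"),
                      file.path(out, "metadata.tsv"))
    files <- c(files, file.path(out, c("counts.tsv", "metadata.tsv")))
    phen <- if (!is.null(sc$phenotype_spec)) generate_phenotypes(sc, table) else NULL
    pwy <- generate_pathways(sc, table)
    if (!is.null(phen)) {
      write_omics_block(phen, file.path(out, "phenotypes.tsv"))
      files <- c(files, file.path(out, "phenotypes.tsv"))
    }
    write_omics_block(pwy, file.path(out, "pathways.tsv"))
    files <- c(files, file.path(out, "pathways.tsv"))
  } else {
    table <- read_count_table(config$counts_path, config$metadata_path)
    phen <- NULL
    pwy <- NULL
    log <- stage_log(log, "load", "read %d samples x %d taxa from %s",
                     nrow(table$counts), ncol(table$counts), config$counts_path)
  }
  groups <- levels(table$groups)

  # stage 2: abundance profiles
  emit(diversity_profile(table), "diversity.tsv")
  emit(top_k_taxa(table, config$top_k), "top_taxa.tsv")
  log <- stage_log(log, "profile", "diversity and top-%d summary written",
                   config$top_k)

  # stage 3: per-group correlation networks
  relab <- relative_abundance(table)
  for (g in groups) {
    x <- relab[table$groups == g, , drop = FALSE]
    corr <- suppressWarnings(spearman_matrix(x))
    graph <- build_graph(corr, config$alpha_edge)
    emit(edge_table(graph), sprintf("network_edges_%s.tsv", g))
    k <- if (identical(config$k_clusters, "auto")) choose_k_eigengap(graph)
         else as.integer(config$k_clusters)
    labels <- spectral_clusters(graph, k, seed = split_seed(config$seed, 30L))
    emit(data.frame(taxon = names(labels), cluster = as.integer(labels)),
         sprintf("network_clusters_%s.tsv", g))
    log <- stage_log(log, "network", "%s: %d edges, k = %d clusters",
                     g, igraph::ecount(graph), k)
  }

  # stage 4: bootstrap topology comparison
  if (length(groups) >= 2) {
    boots <- lapply(groups, function(g) {
      bootstrap_network_stats(table, g, B = config$B, alpha = config$alpha_edge,
                              seed = split_seed(config$seed, 40L + match(g, groups)))
    })
    names(boots) <- groups
    for (g in groups) emit(boots[[g]], sprintf("bootstrap_%s.tsv", g))
    cmp <- do.call(rbind, lapply(network_parameters, function(par) {
      at <- compare_network_groups(boots, par)
      data.frame(parameter = par, F = at$F, p = at$p,
                 pair = paste(at$tukey$group_a, at$tukey$group_b, sep = " vs "),
                 tukey_p = at$tukey$p_adjusted)
    }))
    emit(cmp, "network_comparison.tsv")
    log <- stage_log(log, "bootstrap", "B = %d replicates per group compared",
                     config$B)
  } else {
    log <- stage_log(log, "bootstrap", "skipped: fewer than 2 groups")
  }

  # stage 5: differential genera (and pathways when simulated)
  if (length(groups) >= 2) {
    diff_gen <- select_differential(table, alpha = 0.05)
    emit(diff_gen, "differential_genera.tsv")
    sel <- diff_gen$feature[diff_gen$selected]
    if (length(sel) >= 2) {
      pc <- pc_projection(relab[, sel, drop = FALSE])
      emit(data.frame(sample = rownames(pc$scores), group = as.character(table$groups),
                      PC1 = pc$scores[, 1], PC2 = pc$scores[, 2]),
           "pc_scores_genera.tsv")
      log <- stage_log(log, "diff", "%d genera selected; PC1/PC2 explain %.1f%%/%.1f%%",
                       length(sel), 100 * pc$explained[1], 100 * pc$explained[2])
    } else {
      log <- stage_log(log, "diff", "%d genera selected; PC projection skipped",
                       length(sel))
    }
    if (!is.null(pwy)) {
      diff_pwy <- select_differential(pwy$values, groups = table$groups)
      emit(diff_pwy, "differential_pathways.tsv")
    }
  } else {
    log <- stage_log(log, "diff", "skipped: fewer than 2 groups")
  }

  # stage 6: multi-omic network
  if (!is.null(phen)) {
    genus_block <- omics_block(relab, "genus")
    blocks <- list(genus_block, pwy)
    if ("SBP" %in% colnames(phen$values)) {
      blocks <- c(blocks, list(
        omics_block(phen$values[, "SBP", drop = FALSE], "blood_pressure")))
      rest <- setdiff(colnames(phen$values), "SBP")
      if (length(rest)) {
        blocks <- c(blocks, list(
          omics_block(phen$values[, rest, drop = FALSE], "phenotype")))
      }
    } else {
      blocks <- c(blocks, list(phen))
    }
    mg <- suppressWarnings(multiomic_graph(blocks, alpha = config$alpha_by))
    emit(edge_table(mg), "multiomic_edges.tsv")
    igraph::write_graph(mg, file.path(out, "multiomic_network.graphml"),
                        format = "graphml")
    files <- c(files, file.path(out, "multiomic_network.graphml"))
    log <- stage_log(log, "multiomics", "%d nodes, %d BY-retained edges",
                     igraph::vcount(mg), igraph::ecount(mg))
  } else {
    log <- stage_log(log, "multiomics", "skipped: no phenotype block")
  }

  # stage 7: community-level statistics
  if (length(groups) >= 2) {
    d <- bray_curtis(table)
    pm <- permanova(d, table$groups, n_perm = config$n_perm,
                    seed = split_seed(config$seed, 70L))
    emit(data.frame(pseudo_F = pm$pseudo_F, R2 = pm$R2, p = pm$p,
                    n_permutations = pm$n_permutations), "permanova.tsv")
    emit(pairwise_adonis(d, table$groups, n_perm = config$n_perm,
                         seed = split_seed(config$seed, 71L)),
         "pairwise_adonis.tsv")
    div <- diversity_profile(table)
    mw <- do.call(rbind, lapply(utils::combn(groups, 2, simplify = FALSE),
      function(pr) {
        t <- mann_whitney_u(div$richness[div$group == pr[1]],
                            div$richness[div$group == pr[2]])
        data.frame(group_a = pr[1], group_b = pr[2], U = t$U_x, p = t$p)
      }))
    emit(mw, "richness_mann_whitney.tsv")
    log <- stage_log(log, "stats", "PERMANOVA p = %.4g (R2 = %.3f)", pm$p, pm$R2)
  } else {
    log <- stage_log(log, "stats", "skipped: fewer than 2 groups")
  }

  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    row.names = NULL
  )
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(log, file.path(out, "run_log.txt"))
  invisible(list(manifest = manifest, log = log))
}
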