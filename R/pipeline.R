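# End-to-end orchestration: pI profiling, ortholog asymmetry, gene content.
#
# The pipeline is configured by a YAML file (or equivalent list):
#
#   pka_set: expasy
#   genomes:
#     PS01: {fasta: PS01.faa, group: piezosensitive, pressure_opt: 0.1}
#     PZ01: {fasta: PZ01.faa, group: piezophile}
#   asymmetry:            # optional stage
#     reference: PS01     # substitutions are read reference -> target
#     targets: [PZ01]     # default: all piezophile genomes
#     clusters: clusters.tsv   # optional; RBH pairing when absent
#     window: 2
#     replicates: 100
#     seed: 42
#     min_identity: 0.3
#     min_sites: 50
#   cluster_table: clusters.tsv  # optional gene-content stage
#   cog_table: cog_counts.tsv    # optional COG stage
#
# Relative paths resolve against the config file's directory. All tables
# are written as TSV with '#'-prefixed header lines recording parameters;
# reruns with identical inputs and seeds are byte-identical.

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    base <- dirname(normalizePath(config))
    cfg <- yaml::read_yaml(config)
  } else {
    base <- getwd()
    cfg <- config
  }
  if (is.null(cfg$genomes) || length(cfg$genomes) == 0L) {
    stop("pipeline config must list at least one genome")
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  for (g in names(cfg$genomes)) {
    cfg$genomes[[g]]$fasta <- resolve(cfg$genomes[[g]]$fasta)
  }
  cfg$cluster_table <- resolve(cfg$cluster_table)
  cfg$cog_table <- resolve(cfg$cog_table)
  if (!is.null(cfg$asymmetry)) cfg$asymmetry$clusters <-
      resolve(cfg$asymmetry$clusters)
  if (is.null(cfg$pka_set)) cfg$pka_set <- "expasy"
  cfg
}

write_tsv <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", names(header), ": ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

round3 <- function(df, cols) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], 3L)
  df
}

#' Run the full comparative pipeline
#'
#' Reads all configured proteomes, runs the pI stage on every genome (and
#' the group bias comparison when both groups have two or more genomes),
#' the ortholog-asymmetry stage for each configured target against the
#' named reference, and the gene-content / COG stages when their tables
#' are supplied. All result tables are written under `out_dir` together
#' with a run manifest (parameters, seeds, input checksums). Any stage
#' error aborts with the stage name.
#'
#' @param config path to a YAML pipeline config, or an equivalent list.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- list(config = cfg, outputs = character(0))
  manifest <- list(package = "piezocomp",
                   version = as.character(utils::packageVersion("piezocomp")),
                   pka_set = cfg$pka_set,
                   stages = character(0), inputs = list())

  proteomes <- stage("read_proteomes", {
    lapply(stats::setNames(nm = names(cfg$genomes)), function(g) {
      e <- cfg$genomes[[g]]
      if (is.null(e$fasta) || !file.exists(e$fasta)) {
        stop("genome ", g, ": FASTA not found (", e$fasta, ")")
      }
      manifest$inputs[[basename(e$fasta)]] <<-
        unname(tools::md5sum(e$fasta))
      read_proteome(e$fasta, g, e$group,
                    if (is.null(e$pressure_opt)) NA_real_
                    else as.numeric(e$pressure_opt))
    })
  })

  pka <- pka_set(cfg$pka_set)
  profiles <- stage("pi_profile", lapply(proteomes, pi_profile, pka = pka))
  per_protein <- do.call(rbind, lapply(profiles, function(p)
    data.frame(genome_id = p$genome_id, protein_id = names(p$pi),
               pi = round(unname(p$pi), 3L), stringsAsFactors = FALSE)))
  report$outputs["pi_per_protein"] <- write_tsv(
    per_protein, file.path(out_dir, "pi_per_protein.tsv"),
    c(pka_set = cfg$pka_set))
  prof_tab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(genome_id = p$genome_id, group = p$group,
               pressure_opt = p$pressure_opt, n = length(p$pi),
               n_acidic = p$n_acidic, n_basic = p$n_basic,
               bias_pct = round(p$bias_pct, 3L), stringsAsFactors = FALSE)))
  report$outputs["pi_profiles"] <- write_tsv(
    prof_tab, file.path(out_dir, "pi_profiles.tsv"),
    c(pka_set = cfg$pka_set))
  manifest$stages <- c(manifest$stages, "pi_profile")
  report$profiles <- profiles

  sizes <- table(factor(prof_tab$group, GROUP_LEVELS))
  if (all(sizes >= 2L)) {
    cmp <- stage("compare_bias", compare_bias(profiles))
    report$bias_comparison <- cmp
    report$outputs["pi_bias_comparison"] <- write_tsv(
      data.frame(mean_piezophile = cmp$group_means[["piezophile"]],
                 mean_piezosensitive = cmp$group_means[["piezosensitive"]],
                 t = cmp$t, p = cmp$p),
      file.path(out_dir, "pi_bias_comparison.tsv"),
      c(test = "Welch two-sample t on per-genome pI bias"))
    manifest$stages <- c(manifest$stages, "compare_bias")
  }

  if (!is.null(cfg$asymmetry)) {
    a <- cfg$asymmetry
    if (is.null(a$reference)) {
      stop("pipeline stage 'asymmetry' failed: a reference genome id is ",
           "required (asymmetry.reference)", call. = FALSE)
    }
    if (is.null(proteomes[[a$reference]])) {
      stop("pipeline stage 'asymmetry' failed: reference genome '",
           a$reference, "' is not among the configured genomes",
           call. = FALSE)
    }
    targets <- a$targets
    if (is.null(targets)) {
      targets <- names(proteomes)[vapply(proteomes, `[[`, character(1L),
                                         "group") == "piezophile"]
    }
    if (length(targets) == 0L) {
      stop("pipeline stage 'asymmetry' failed: no target genomes",
           call. = FALSE)
    }
    if (is.null(a$seed)) {
      stop("pipeline stage 'asymmetry' failed: a seed is required",
           call. = FALSE)
    }
    clusters <- NULL
    if (!is.null(a$clusters)) {
      clusters <- stage("asymmetry", read_cluster_table(a$clusters))
      manifest$inputs[[basename(a$clusters)]] <-
        unname(tools::md5sum(a$clusters))
    }
    window <- if (is.null(a$window)) 2L else as.integer(a$window)
    reps <- if (is.null(a$replicates)) 100L else as.integer(a$replicates)
    min_id <- if (is.null(a$min_identity)) 0.3 else a$min_identity
    min_sites <- if (is.null(a$min_sites)) 50L else as.integer(a$min_sites)
    results <- list()
    for (tg in targets) {
      if (is.null(proteomes[[tg]])) {
        stop("pipeline stage 'asymmetry' failed: target genome '", tg,
             "' is not among the configured genomes", call. = FALSE)
      }
      pa <- stage("asymmetry", pair_asymmetry(
        proteomes[[a$reference]], proteomes[[tg]], clusters = clusters,
        window = window, n_replicates = reps, seed = a$seed,
        min_identity = min_id, min_sites = min_sites))
      results[[tg]] <- pa$result
      hdr <- c(reference = a$reference, target = tg, window = window,
               replicates = reps, seed = a$seed,
               min_identity = min_id, min_sites = min_sites,
               pairs_used = pa$n_pairs_used, pairs_total = pa$n_pairs_total,
               n_sites = pa$result$counts$n_sites,
               n_sites_raw = pa$result$counts$n_sites_raw)
      report$outputs[paste0("asym_pairs_", tg)] <- write_tsv(
        round3(pa$result$per_pair, c("index", "se", "z", "p")),
        file.path(out_dir, paste0("asym_pairs_", tg, ".tsv")), hdr)
      report$outputs[paste0("asym_residues_", tg)] <- write_tsv(
        round3(pa$result$per_residue, c("index", "se", "z")),
        file.path(out_dir, paste0("asym_residues_", tg, ".tsv")), hdr)
    }
    report$asymmetry <- results
    if (length(results) >= 2L) {
      cons <- consensus_substitutions(results, names(results))
      icols <- grep("^index_", names(cons), value = TRUE)
      report$outputs["asym_consensus"] <- write_tsv(
        round3(cons, icols),
        file.path(out_dir, "asym_consensus.tsv"),
        c(rule = "significant with the same direction in all comparisons"))
      report$consensus <- cons
    }
    manifest$stages <- c(manifest$stages, "asymmetry")
    manifest$asymmetry <- list(reference = a$reference, targets = targets,
                               window = window, replicates = reps,
                               seed = a$seed, min_identity = min_id,
                               min_sites = min_sites)
  }

  group_vec <- vapply(proteomes, `[[`, character(1L), "group")
  if (!is.null(cfg$cluster_table)) {
    part <- stage("gene_content", {
      manifest$inputs[[basename(cfg$cluster_table)]] <-
        unname(tools::md5sum(cfg$cluster_table))
      ct <- read_cluster_table(cfg$cluster_table)
      genomes_in <- unique(unlist(lapply(ct$clusters, names)))
      gcm <- gene_content_matrix(ct, group_vec[genomes_in])
      pan_partition(gcm)
    })
    report$partition <- part
    report$outputs["partition_summary"] <- write_tsv(
      data.frame(n_core = part$n_core, n_shell = part$n_shell,
                 n_cloud = part$n_cloud, n_total = part$n_total,
                 n_piezophile_exclusive =
                   length(part$group_exclusive$piezophile),
                 n_piezosensitive_exclusive =
                   length(part$group_exclusive$piezosensitive)),
      file.path(out_dir, "partition_summary.tsv"))
    report$outputs["partition_clusters"] <- write_tsv(
      part$per_cluster, file.path(out_dir, "partition_clusters.tsv"))
    excl <- do.call(rbind, lapply(names(part$group_exclusive), function(g) {
      ids <- part$group_exclusive[[g]]
      if (!length(ids)) return(NULL)
      data.frame(group = g, cluster_id = ids, stringsAsFactors = FALSE)
    }))
    if (!is.null(excl)) {
      report$outputs["group_exclusive"] <- write_tsv(
        excl, file.path(out_dir, "group_exclusive_clusters.tsv"))
    }
    manifest$stages <- c(manifest$stages, "gene_content")
  }

  if (!is.null(cfg$cog_table)) {
    cogcmp <- stage("cog_compare", {
      manifest$inputs[[basename(cfg$cog_table)]] <-
        unname(tools::md5sum(cfg$cog_table))
      cog <- read_cog_table(cfg$cog_table)
      labeled <- intersect(rownames(cog$counts), names(group_vec))
      cog_compare(cog, group_vec[labeled])
    })
    report$cog_comparison <- cogcmp
    report$outputs["cog_comparison"] <- write_tsv(
      round3(cogcmp, c("t")), file.path(out_dir, "cog_comparison.tsv"),
      c(test = "Welch two-sample t on per-genome relative abundance"))
    manifest$stages <- c(manifest$stages, "cog_compare")
  }

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  report$manifest <- manifest
  invisible(report)
}
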