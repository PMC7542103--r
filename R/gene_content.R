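# Pan-genome partitioning and COG functional-category comparison.

#' Build a presence/absence gene-content matrix
#'
#' @param clusters a [cluster_table].
#' @param groups named character vector `genome_id -> group`
#'   ("piezophile"/"piezosensitive"); must cover every genome referenced.
#' @return An object of class `gene_content_matrix`: logical `presence`
#'   matrix (clusters x genomes) and `groups`.
#' @export
gene_content_matrix <- function(clusters, groups) {
  stopifnot(inherits(clusters, "cluster_table"))
  genomes <- names(groups)
  if (!all(groups %in% GROUP_LEVELS)) {
    stop("groups must be one of: ", paste(GROUP_LEVELS, collapse = ", "))
  }
  referenced <- unique(unlist(lapply(clusters$clusters, names)))
  missing <- setdiff(referenced, genomes)
  if (length(missing)) {
    stop("genome '", missing[1L], "' appears in the cluster table but has ",
         "no group label")
  }
  presence <- t(vapply(clusters$clusters, function(m)
    genomes %in% names(m)[vapply(m, length, integer(1L)) > 0L],
    logical(length(genomes))))
  colnames(presence) <- genomes
  structure(list(presence = presence, groups = groups),
            class = "gene_content_matrix")
}

#' Core/shell/cloud pan-genome partition and group-exclusive clusters
#'
#' Core clusters are present in all genomes, cloud clusters in exactly
#' one, shell clusters in an intermediate number (2 to G-1). A cluster is
#' group-exclusive when present in every genome of one group and in none
#' of the other.
#'
#' @param x a [gene_content_matrix].
#' @return An object of class `partition_summary`: `n_core`, `n_shell`,
#'   `n_cloud`, `n_total`, `group_exclusive` (list of cluster-id vectors
#'   per group) and `per_cluster` table.
#' @export
pan_partition <- function(x) {
  stopifnot(inherits(x, "gene_content_matrix"))
  if (nrow(x$presence) == 0L) stop("empty gene-content matrix")
  G <- ncol(x$presence)
  if (G < 2L) stop("need at least 2 genomes to partition")
  n_genomes <- rowSums(x$presence)
  class <- ifelse(n_genomes == G, "core",
                  ifelse(n_genomes == 1L, "cloud", "shell"))
  group_exclusive <- lapply(GROUP_LEVELS, function(g) {
    inside <- names(x$groups)[x$groups == g]
    outside <- setdiff(names(x$groups), inside)
    if (length(inside) == 0L) return(character(0))
    keep <- rowSums(x$presence[, inside, drop = FALSE]) == length(inside) &
      rowSums(x$presence[, outside, drop = FALSE]) == 0L
    rownames(x$presence)[keep]
  })
  names(group_exclusive) <- GROUP_LEVELS
  structure(list(
    n_core = sum(class == "core"),
    n_shell = sum(class == "shell"),
    n_cloud = sum(class == "cloud"),
    n_total = nrow(x$presence),
    group_exclusive = group_exclusive,
    per_cluster = data.frame(cluster_id = rownames(x$presence),
                             n_genomes = n_genomes, class = class,
                             row.names = NULL, stringsAsFactors = FALSE)),
    class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  cat(sprintf("pan-genome partition: %d clusters (core %d, shell %d, cloud %d)\n",
              x$n_total, x$n_core, x$n_shell, x$n_cloud))
  for (g in names(x$group_exclusive)) {
    cat(sprintf("  %s-exclusive: %d\n", g, length(x$group_exclusive[[g]])))
  }
  invisible(x)
}

#' Compare COG category relative abundances between groups
#'
#' Per genome, each category count is divided by the genome's total
#' COG-annotated genes; per category, a Welch t-test compares the
#' relative abundances between the two groups.
#'
#' @param x a [cog_table].
#' @param groups named character vector `genome_id -> group`; at least 2
#'   genomes per group.
#' @param bh logical; add Benjamini-Hochberg adjusted p-values.
#' @return data.frame: category, group mean relative abundances, t, p
#'   (and `p_adj` when `bh`), ordered by p.
#' @export
cog_compare <- function(x, groups, bh = FALSE) {
  stopifnot(inherits(x, "cog_table"))
  counts <- x$counts[names(groups), , drop = FALSE]
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("genome '", names(totals)[totals == 0][1L],
         "' has zero annotated genes")
  }
  sizes <- table(factor(groups, GROUP_LEVELS))
  if (any(sizes < 2L)) {
    stop("need at least 2 genomes per group; got ",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))
  }
  rel <- counts / totals
  in_a <- groups == "piezophile"
  res <- do.call(rbind, lapply(colnames(rel), function(cat) {
    a <- rel[in_a, cat]
    b <- rel[!in_a, cat]
    wt <- welch_test(a, b)
    data.frame(category = cat, mean_piezophile = mean(a),
               mean_piezosensitive = mean(b), t = wt$t, p = wt$p,
               stringsAsFactors = FALSE)
  }))
  if (bh) res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}

#' Presence/absence grid for marker clusters
#'
#' Extracts selected marker clusters (e.g. diagnostic operons) as a
#' genomes x markers grid, genomes ordered by group — the layout used to
#' display attributes differentially present between strain groups.
#'
#' @param x a [gene_content_matrix].
#' @param marker_clusters character vector of cluster ids; unknown ids are
#'   an error.
#' @return Logical matrix, genomes (rows, grouped) x markers (columns).
#' @export
marker_table <- function(x, marker_clusters) {
  stopifnot(inherits(x, "gene_content_matrix"))
  unknown <- setdiff(marker_clusters, rownames(x$presence))
  if (length(unknown)) stop("unknown marker cluster '", unknown[1L], "'")
  ord <- order(factor(x$groups, GROUP_LEVELS), names(x$groups))
  t(x$presence[marker_clusters, names(x$groups)[ord], drop = FALSE])
}
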