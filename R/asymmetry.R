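# Directed amino-acid substitution asymmetry between single-copy orthologs.
#
# After aligning each reference/target ortholog pair, columns in or near
# gaps and columns with ambiguous residues are masked, directed
# substitutions a -> b are counted over the kept columns and pooled across
# clusters, and an asymmetry index is computed per directed pair,
#   (c_ab - c_ba) / (c_ab + c_ba),
# and per residue (gains vs losses). Uncertainty comes from a cluster-level
# bootstrap (clusters resampled with replacement), because substitutions
# within one protein are not independent sites.

#' Restrict a cluster table to single-copy clusters
#'
#' Keeps only clusters with exactly one member in every genome of
#' `genomes` — the precondition for unambiguous pairwise substitution
#' counting.
#'
#' @param x a [cluster_table].
#' @param genomes character vector of genome ids that must each contribute
#'   exactly one member.
#' @return A filtered [cluster_table].
#' @export
single_copy_clusters <- function(x, genomes) {
  stopifnot(inherits(x, "cluster_table"), length(genomes) >= 1L)
  keep <- vapply(x$clusters, function(m) {
    all(vapply(genomes, function(g)
      !is.null(m[[g]]) && length(m[[g]]) == 1L, logical(1L)))
  }, logical(1L))
  cluster_table(x$clusters[keep])
}

#' Gap-proximity and ambiguity column mask
#'
#' A column is excluded when it, or any column within `window` columns of
#' it, contains a gap in either row, or when either residue in it is an
#' ambiguity/rare code (X, B, Z, J, U, O). This is the strict reading of
#' "ambiguity removal with 2 adjacent sites"; `window = 0` gives the
#' lenient gap-columns-only variant.
#'
#' @param aln a [pairwise_alignment].
#' @param window nonnegative integer number of adjacent columns to exclude
#'   around every gap column (default 2).
#' @return A list of class `site_mask`: `keep` (logical per column),
#'   `window`.
#' @export
ambiguity_mask <- function(aln, window = 2L) {
  stopifnot(inherits(aln, "pairwise_alignment"), window >= 0L)
  r <- strsplit(aln$ref_aligned, "")[[1L]]
  t <- strsplit(aln$tgt_aligned, "")[[1L]]
  n <- length(r)
  gapcol <- r == "-" | t == "-"
  bad <- gapcol
  idx <- which(gapcol)
  if (length(idx) && window > 0L) {
    near <- unique(as.vector(outer(idx, seq(-window, window), `+`)))
    bad[near[near >= 1L & near <= n]] <- TRUE
  }
  bad <- bad | r %in% AA_AMBIGUOUS | t %in% AA_AMBIGUOUS
  structure(list(keep = !bad, window = as.integer(window)),
            class = "site_mask")
}

#' Count directed substitutions over kept alignment columns
#'
#' @param aln a [pairwise_alignment].
#' @param mask a [ambiguity_mask()] result of matching length.
#' @return An object of class `substitution_counts`: `C` (20x20 directed
#'   count matrix, reference residue in rows, target residue in columns,
#'   zero diagonal), `n_conserved`, `n_sites` (kept columns) and
#'   `n_sites_raw` (all alignment columns).
#' @export
count_substitutions <- function(aln, mask) {
  stopifnot(inherits(aln, "pairwise_alignment"), inherits(mask, "site_mask"))
  r <- strsplit(aln$ref_aligned, "")[[1L]]
  t <- strsplit(aln$tgt_aligned, "")[[1L]]
  if (length(mask$keep) != length(r)) stop("mask length != alignment length")
  rk <- r[mask$keep]
  tk <- t[mask$keep]
  tab <- table(factor(rk, AA20), factor(tk, AA20))
  C <- matrix(as.integer(tab), 20L, 20L, dimnames = list(AA20, AA20))
  n_conserved <- sum(diag(C))
  diag(C) <- 0L
  substitution_counts(C, n_conserved, sum(mask$keep), length(r))
}

#' Construct a substitution-count object
#'
#' @param C 20x20 integer matrix of directed counts (zero diagonal).
#' @param n_conserved conserved-site count.
#' @param n_sites kept-column count; must equal `sum(C) + n_conserved`.
#' @param n_sites_raw total alignment columns before masking.
#' @return An object of class `substitution_counts`.
#' @export
substitution_counts <- function(C, n_conserved, n_sites,
                                n_sites_raw = n_sites) {
  stopifnot(identical(dim(C), c(20L, 20L)), all(diag(C) == 0))
  if (sum(C) + n_conserved != n_sites) {
    stop("count invariant violated: sum(C) + n_conserved != n_sites")
  }
  structure(list(C = C, n_conserved = n_conserved, n_sites = n_sites,
                 n_sites_raw = n_sites_raw),
            class = "substitution_counts")
}

#' Pool per-cluster substitution counts
#'
#' @param counts_list nonempty list of `substitution_counts`.
#' @return Elementwise sum, an object of class `substitution_counts`.
#' @export
pool_counts <- function(counts_list) {
  stopifnot(length(counts_list) >= 1L)
  C <- Reduce(`+`, lapply(counts_list, `[[`, "C"))
  substitution_counts(
    C,
    sum(vapply(counts_list, `[[`, numeric(1L), "n_conserved")),
    sum(vapply(counts_list, `[[`, numeric(1L), "n_sites")),
    sum(vapply(counts_list, `[[`, numeric(1L), "n_sites_raw")))
}

# Unordered pair index bookkeeping: 190 pairs (a, b) with a < b in AA20
# order; linear indices into as.vector(C) for C[a, b] and C[b, a].
pair_index_table <- function() {
  idx <- which(upper.tri(matrix(0, 20, 20)), arr.ind = TRUE)
  data.frame(a = AA20[idx[, 1L]], b = AA20[idx[, 2L]],
             i_ab = (idx[, 2L] - 1L) * 20L + idx[, 1L],
             i_ba = (idx[, 1L] - 1L) * 20L + idx[, 2L],
             stringsAsFactors = FALSE)
}

asym_index <- function(fwd, rev) {
  tot <- fwd + rev
  ifelse(tot > 0, (fwd - rev) / tot, NA_real_)
}

#' Substitution asymmetry with cluster-bootstrap uncertainty
#'
#' Computes the asymmetry index for each of the 190 unordered residue
#' pairs and the gains-vs-losses index for each residue, with standard
#' errors from resampling clusters with replacement. A pair with no
#' observed substitutions in either direction has an undefined index and
#' is reported as `NA`, never 0. Significance is `|z| >= 1.96`; optional
#' Benjamini-Hochberg correction replaces the threshold with an adjusted
#' p-value cut at 0.05.
#'
#' @param cluster_counts list of per-cluster `substitution_counts`.
#' @param n_replicates number of bootstrap replicates (default 100).
#' @param seed integer random seed (mandatory; recorded in the result).
#' @param bh logical; apply Benjamini-Hochberg correction across pairs.
#' @return An object of class `asymmetry_result`: `per_pair` and
#'   `per_residue` data.frames, pooled `counts`, `n_replicates`, `seed`.
#' @export
asymmetry <- function(cluster_counts, n_replicates = 100L, seed, bh = FALSE) {
  stopifnot(length(cluster_counts) >= 1L, n_replicates >= 2L)
  if (missing(seed)) stop("a random seed is required for the bootstrap")
  pooled <- pool_counts(cluster_counts)
  pt <- pair_index_table()

  # 400 x n_clusters matrix of vectorized count matrices
  M <- vapply(cluster_counts, function(x) as.vector(x$C), numeric(400L))
  if (is.null(dim(M))) M <- matrix(M, nrow = 400L)
  n_clust <- ncol(M)

  set.seed(as.integer(seed))
  W <- vapply(seq_len(n_replicates), function(i)
    tabulate(sample.int(n_clust, n_clust, replace = TRUE), n_clust),
    numeric(n_clust))
  V <- M %*% W                                   # 400 x R pooled replicates

  # per-pair replicate indices
  rep_pair <- asym_index(V[pt$i_ab, , drop = FALSE],
                         V[pt$i_ba, , drop = FALSE])
  v <- as.vector(pooled$C)
  idx <- asym_index(v[pt$i_ab], v[pt$i_ba])
  se <- apply(rep_pair, 1L, stats::sd, na.rm = TRUE)
  se[is.na(idx)] <- NA_real_
  z <- ifelse(se > 0, idx / se, ifelse(idx == 0, NA_real_, sign(idx) * Inf))
  p <- 2 * stats::pnorm(-abs(z))
  sig <- !is.na(z) & abs(z) >= 1.96
  per_pair <- data.frame(a = pt$a, b = pt$b,
                         c_ab = v[pt$i_ab], c_ba = v[pt$i_ba],
                         index = idx, se = se, z = z, p = p,
                         significant = sig, stringsAsFactors = FALSE)
  if (bh) {
    per_pair$p_adj <- stats::p.adjust(per_pair$p, method = "BH")
    per_pair$significant <- !is.na(per_pair$p_adj) & per_pair$p_adj < 0.05
  }

  # per-residue gains (column sums) and losses (row sums)
  A_gain <- t(vapply(seq_len(20L), function(j) {
    m <- matrix(0, 20, 20); m[, j] <- 1; diag(m) <- 0; as.vector(m)
  }, numeric(400L)))
  A_loss <- t(vapply(seq_len(20L), function(i) {
    m <- matrix(0, 20, 20); m[i, ] <- 1; diag(m) <- 0; as.vector(m)
  }, numeric(400L)))
  gains <- as.vector(A_gain %*% v)
  losses <- as.vector(A_loss %*% v)
  rep_res <- asym_index(A_gain %*% V, A_loss %*% V)
  r_idx <- asym_index(gains, losses)
  r_se <- apply(rep_res, 1L, stats::sd, na.rm = TRUE)
  r_se[is.na(r_idx)] <- NA_real_
  r_z <- ifelse(r_se > 0, r_idx / r_se,
                ifelse(r_idx == 0, NA_real_, sign(r_idx) * Inf))
  per_residue <- data.frame(residue = AA20, gains = gains, losses = losses,
                            index = r_idx, se = r_se, z = r_z,
                            significant = !is.na(r_z) & abs(r_z) >= 1.96,
                            stringsAsFactors = FALSE)

  structure(list(per_pair = per_pair, per_residue = per_residue,
                 counts = pooled, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), bh = bh),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf(
    "asymmetry_result: %d kept sites (%d raw), %d conserved, %d significant pairs (%d replicates, seed %d)\n",
    x$counts$n_sites, x$counts$n_sites_raw, x$counts$n_conserved,
    sum(x$per_pair$significant, na.rm = TRUE), x$n_replicates, x$seed))
  invisible(x)
}

#' Align, mask, filter and count one reference/target proteome comparison
#'
#' Runs the full per-comparison pipeline: single-copy ortholog pairs
#' (from a supplied cluster table or [rbh_orthologs()]), global alignment,
#' ambiguity masking, a quality filter (minimum ungapped identity and
#' minimum kept sites, guarding against spurious pairings), pooled counts
#' and bootstrap asymmetry.
#'
#' @param ref,tgt [proteome] objects; substitutions are read ref -> tgt
#'   (conventionally piezosensitive reference, piezophile target).
#' @param clusters optional [cluster_table]; derived by RBH when `NULL`.
#' @param window ambiguity-mask window, see [ambiguity_mask()].
#' @param min_identity minimum ungapped identity to keep a pair.
#' @param min_sites minimum kept sites to keep a pair.
#' @inheritParams asymmetry
#' @return A list: `result` ([asymmetry()] output), `per_cluster` counts,
#'   `n_pairs_total`, `n_pairs_used`, `dropped` (ids of filtered pairs).
#' @export
pair_asymmetry <- function(ref, tgt, clusters = NULL, window = 2L,
                           n_replicates = 100L, seed, min_identity = 0.3,
                           min_sites = 50L, bh = FALSE) {
  stopifnot(inherits(ref, "proteome"), inherits(tgt, "proteome"))
  if (missing(seed)) stop("a random seed is required")
  if (is.null(clusters)) clusters <- rbh_orthologs(ref, tgt)
  clusters <- single_copy_clusters(clusters, c(ref$genome_id, tgt$genome_id))
  if (length(clusters$clusters) == 0L) stop("no single-copy clusters shared by ",
                                            ref$genome_id, " and ", tgt$genome_id)
  ref_seq <- stats::setNames(ref$records$sequence, ref$records$protein_id)
  tgt_seq <- stats::setNames(tgt$records$sequence, tgt$records$protein_id)
  per_cluster <- list()
  dropped <- character(0)
  for (cid in names(clusters$clusters)) {
    m <- clusters$clusters[[cid]]
    aln <- nw_align(ref_seq[[m[[ref$genome_id]]]],
                    tgt_seq[[m[[tgt$genome_id]]]])
    mask <- ambiguity_mask(aln, window = window)
    cnt <- count_substitutions(aln, mask)
    if (alignment_identity(aln) < min_identity || cnt$n_sites < min_sites) {
      dropped <- c(dropped, cid)
      next
    }
    per_cluster[[cid]] <- cnt
  }
  if (length(per_cluster) == 0L) {
    stop("all ", length(clusters$clusters),
         " ortholog pairs were removed by the identity/site filters")
  }
  list(result = asymmetry(per_cluster, n_replicates = n_replicates,
                          seed = seed, bh = bh),
       per_cluster = per_cluster,
       n_pairs_total = length(clusters$clusters),
       n_pairs_used = length(per_cluster),
       dropped = dropped)
}

#' Substitutions conserved across independent comparisons
#'
#' Flags directed residue pairs that are significant with the same
#' direction (index sign) in every supplied comparison — the
#' cross-comparison consensus rule used to call substitutions shared
#' between independent piezophile/piezosensitive contrasts.
#'
#' @param results list of [asymmetry()] results (>= 2).
#' @param labels comparison names, one per result.
#' @return data.frame: `a`, `b`, one `index_<label>` column per
#'   comparison, `direction` (`"a->b"`/`"b->a"` for consensus rows) and
#'   `conserved` flag.
#' @export
consensus_substitutions <- function(results, labels = names(results)) {
  stopifnot(length(results) >= 2L, length(labels) == length(results))
  pt <- pair_index_table()
  out <- data.frame(a = pt$a, b = pt$b, stringsAsFactors = FALSE)
  sig <- sgn <- matrix(NA, nrow(pt), length(results))
  for (k in seq_along(results)) {
    pp <- results[[k]]$per_pair
    out[[paste0("index_", labels[k])]] <- pp$index
    sig[, k] <- pp$significant
    sgn[, k] <- sign(pp$index)
  }
  all_sig <- apply(sig, 1L, function(x) all(!is.na(x) & x))
  same_sign <- apply(sgn, 1L, function(x)
    !any(is.na(x)) && length(unique(x)) == 1L && x[1L] != 0)
  out$conserved <- all_sig & same_sign
  out$direction <- ifelse(out$conserved,
                          ifelse(sgn[, 1L] > 0, "a->b", "b->a"),
                          NA_character_)
  out
}
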