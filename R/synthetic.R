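# Seeded synthetic data with known truth.
#
# Three generators emulate the statistical structure of a two-group
# piezophile/piezosensitive comparison: proteomes with a controlled
# basic-protein fraction, single-copy ortholog families diverged from a
# common ancestor with planted directional substitutions on the target
# (piezophile) lineage only, and COG category counts with planted group
# enrichments. Everything is deterministic under the spec seed.

# Typical bacterial amino-acid background frequencies (order AA20).
BASE_AA_FREQ <- c(A = 0.08, C = 0.01, D = 0.05, E = 0.06, F = 0.04,
                  G = 0.07, H = 0.02, I = 0.06, K = 0.06, L = 0.10,
                  M = 0.02, N = 0.04, P = 0.04, Q = 0.04, R = 0.05,
                  S = 0.06, T = 0.05, V = 0.07, W = 0.01, Y = 0.03)

# Composition for designed-basic proteins: K/R enriched, D/E depleted;
# designed-acidic is the mirror image. The shift is strong enough that a
# sampled protein lands on the intended side of pI 7 with probability
# essentially 1 at realistic lengths.
aa_composition <- function(class = c("basic", "acidic")) {
  class <- match.arg(class)
  f <- BASE_AA_FREQ
  up <- if (class == "basic") c("K", "R") else c("D", "E")
  down <- if (class == "basic") c("D", "E") else c("K", "R")
  f[up] <- f[up] * 3
  f[down] <- f[down] * 0.25
  f / sum(f)
}

#' Specification of a synthetic piezophile/piezosensitive study
#'
#' Defaults mirror a seven-strain, two-group comparison: 4 piezophiles
#' vs 3 piezosensitive genomes, a basic-protein fraction of 0.50 vs 0.35
#' (a +30-point pI-bias shift toward the piezophiles), 100 single-copy
#' ortholog families at 10% per-lineage divergence with planted E->A and
#' E->K excesses on the piezophile lineage, and a 1.5x enrichment of COG
#' category L (replication/recombination/repair) in the piezophiles.
#'
#' @param seed integer random seed driving all generators.
#' @param n_piezophile,n_piezosensitive genomes per group.
#' @param proteome_size proteins per genome.
#' @param length_mean,length_sd protein length distribution (residues,
#'   lognormal).
#' @param basic_fraction named vector, target fraction of designed-basic
#'   proteins per group.
#' @param n_ortholog_families single-copy families for the asymmetry
#'   stage.
#' @param divergence per-site substitution probability per lineage, in
#'   `[0, 1)`; values >= 0.5 warn (ortholog recovery degrades).
#' @param planted_asym named vector of excess probabilities, names of the
#'   form `"E->A"`: the probability that an ancestral `E` site becomes
#'   `A` on the target lineage, on top of the symmetric background.
#' @param indel_prob per-site deletion probability on the target lineage
#'   (default 0; nonzero values exercise the gap mask but make truth
#'   counts alignment-dependent).
#' @param cog_genes_per_genome annotated genes per genome for the COG
#'   generator.
#' @param cog_enrichment list per group of named category multipliers.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_piezophile = 4L, n_piezosensitive = 3L,
                           proteome_size = 2000L,
                           length_mean = 300, length_sd = 150,
                           basic_fraction = c(piezophile = 0.50,
                                              piezosensitive = 0.35),
                           n_ortholog_families = 100L,
                           divergence = 0.10,
                           planted_asym = c("E->A" = 0.02, "E->K" = 0.02),
                           indel_prob = 0,
                           cog_genes_per_genome = 3000L,
                           cog_enrichment = list(piezophile = c(L = 1.5))) {
  stopifnot(length(seed) == 1L, n_piezophile >= 1L, n_piezosensitive >= 1L,
            proteome_size >= 1L, length_mean > 0, length_sd >= 0,
            n_ortholog_families >= 1L)
  if (any(basic_fraction < 0 | basic_fraction > 1)) {
    stop("basic_fraction must lie in [0, 1]")
  }
  stopifnot(all(GROUP_LEVELS %in% names(basic_fraction)))
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  if (length(planted_asym)) {
    stopifnot(all(planted_asym >= 0 & planted_asym <= 1))
    pairs <- strsplit(names(planted_asym), "->", fixed = TRUE)
    ok <- vapply(pairs, function(p) length(p) == 2L && all(p %in% AA20) &&
                   p[1L] != p[2L], logical(1L))
    if (!all(ok)) stop("planted_asym names must be of the form 'E->A' over ",
                       "distinct standard residues")
  }
  stopifnot(indel_prob >= 0, indel_prob < 1)
  structure(list(seed = as.integer(seed),
                 n_piezophile = as.integer(n_piezophile),
                 n_piezosensitive = as.integer(n_piezosensitive),
                 proteome_size = as.integer(proteome_size),
                 length_mean = length_mean, length_sd = length_sd,
                 basic_fraction = basic_fraction,
                 n_ortholog_families = as.integer(n_ortholog_families),
                 divergence = divergence, planted_asym = planted_asym,
                 indel_prob = indel_prob,
                 cog_genes_per_genome = as.integer(cog_genes_per_genome),
                 cog_enrichment = cog_enrichment),
            class = "synthetic_spec")
}

synthetic_genome_ids <- function(spec) {
  c(stats::setNames(rep("piezophile", spec$n_piezophile),
                    sprintf("PZ%02d", seq_len(spec$n_piezophile))),
    stats::setNames(rep("piezosensitive", spec$n_piezosensitive),
                    sprintf("PS%02d", seq_len(spec$n_piezosensitive))))
}

# lognormal lengths with the requested mean/sd, floored at 30 residues
sample_lengths <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  pmax(30L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
}

# sample n sequences of given lengths from one residue composition
sample_sequences <- function(lengths, comp) {
  if (length(lengths) == 0L) return(character(0))
  res <- sample(AA20, sum(lengths), replace = TRUE, prob = comp)
  vapply(split(res, rep.int(seq_along(lengths), lengths)),
         paste, character(1L), collapse = "")
}

#' Generate synthetic proteomes with controlled basic-protein fractions
#'
#' Each genome gets `proteome_size` proteins; a protein is designed basic
#' (K/R-enriched composition) with its group's `basic_fraction`
#' probability and designed acidic otherwise.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `proteomes` (named list of [proteome] objects) and
#'   `truth` (data.frame genome_id, protein_id, class).
#' @export
gen_proteomes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  groups <- synthetic_genome_ids(spec)
  comp <- list(basic = aa_composition("basic"),
               acidic = aa_composition("acidic"))
  proteomes <- list()
  truth <- list()
  for (g in names(groups)) {
    n <- spec$proteome_size
    cls <- ifelse(stats::runif(n) < spec$basic_fraction[[groups[[g]]]],
                  "basic", "acidic")
    lens <- sample_lengths(n, spec$length_mean, spec$length_sd)
    seqs <- character(n)
    for (k in c("basic", "acidic")) {
      i <- which(cls == k)
      seqs[i] <- sample_sequences(lens[i], comp[[k]])
    }
    ids <- sprintf("p%05d", seq_len(n))
    proteomes[[g]] <- proteome(
      g, groups[[g]],
      data.frame(protein_id = ids, description = paste("designed", cls),
                 sequence = seqs, stringsAsFactors = FALSE))
    truth[[g]] <- data.frame(genome_id = g, protein_id = ids, class = cls,
                             stringsAsFactors = FALSE)
  }
  list(proteomes = proteomes, truth = do.call(rbind, c(truth,
                                                       make.row.names = FALSE)))
}

# mutate each site with probability p to a uniformly chosen other residue
mutate_symmetric <- function(chars, p) {
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit)) {
    shift <- sample.int(19L, length(hit), replace = TRUE)
    cur <- match(chars[hit], AA20)
    chars[hit] <- AA20[((cur - 1L + shift) %% 20L) + 1L]
  }
  chars
}

#' Generate diverged single-copy ortholog families with planted asymmetry
#'
#' Ancestral sequences are mutated independently down a reference
#' (piezosensitive) and a target (piezophile) lineage with a symmetric
#' uniform substitution kernel; `planted_asym` adds directed excess
#' substitutions on the target lineage only. The truth record carries the
#' realized directed substitution counts, recountable from the emitted
#' sequences when `indel_prob = 0`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `ref` and `tgt` [proteome] objects (genomes `REF`,
#'   `TGT`), `clusters` ([cluster_table] of the true pairing), and
#'   `truth` (pooled `substitution_counts` plus a `per_family` list).
#' @export
gen_ortholog_families <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$divergence >= 0.5) {
    warning("divergence >= 0.5: ortholog pairing recovery degrades")
  }
  set.seed(spec$seed + 1L)
  planted_src <- if (length(spec$planted_asym)) {
    split(data.frame(
      to = vapply(strsplit(names(spec$planted_asym), "->", fixed = TRUE),
                  `[`, character(1L), 2L),
      e = unname(spec$planted_asym), stringsAsFactors = FALSE),
      vapply(strsplit(names(spec$planted_asym), "->", fixed = TRUE),
             `[`, character(1L), 1L))
  } else list()

  n <- spec$n_ortholog_families
  lens <- sample_lengths(n, spec$length_mean, spec$length_sd)
  ref_seqs <- tgt_seqs <- character(n)
  per_family <- vector("list", n)
  C_true <- matrix(0L, 20L, 20L, dimnames = list(AA20, AA20))
  n_conserved <- 0L
  n_sites <- 0L
  for (i in seq_len(n)) {
    anc <- sample(AA20, lens[i], replace = TRUE, prob = BASE_AA_FREQ)
    ref <- mutate_symmetric(anc, spec$divergence)
    # target lineage: planted directed excess first, then the symmetric
    # background on the remaining sites
    tgt <- anc
    planted <- rep(FALSE, lens[i])
    for (src in names(planted_src)) {
      tab <- planted_src[[src]]
      at <- which(anc == src)
      if (!length(at)) next
      u <- stats::runif(length(at))
      cum <- cumsum(tab$e)
      slot <- findInterval(u, c(0, cum))
      hit <- u < cum[nrow(tab)]
      tgt[at[hit]] <- tab$to[slot[hit]]
      planted[at[hit]] <- TRUE
    }
    free <- which(!planted)
    tgt[free] <- mutate_symmetric(tgt[free], spec$divergence)
    keep <- rep(TRUE, lens[i])
    if (spec$indel_prob > 0) keep <- stats::runif(lens[i]) >= spec$indel_prob
    rk <- ref[keep]
    tk <- tgt[keep]
    tab2 <- table(factor(rk, AA20), factor(tk, AA20))
    Ci <- matrix(as.integer(tab2), 20L, 20L, dimnames = list(AA20, AA20))
    cons <- sum(diag(Ci))
    diag(Ci) <- 0L
    per_family[[i]] <- substitution_counts(Ci, cons, length(rk), length(rk))
    C_true <- C_true + Ci
    n_conserved <- n_conserved + cons
    n_sites <- n_sites + length(rk)
    ref_seqs[i] <- paste(ref, collapse = "")
    tgt_seqs[i] <- paste(tgt[keep], collapse = "")
  }
  ids <- sprintf("p%04d", seq_len(n))
  names(per_family) <- sprintf("fam_%04d", seq_len(n))
  clusters <- lapply(ids, function(p) list(REF = p, TGT = p))
  names(clusters) <- names(per_family)
  list(
    ref = proteome("REF", "piezosensitive",
                   data.frame(protein_id = ids, description = "",
                              sequence = ref_seqs, stringsAsFactors = FALSE)),
    tgt = proteome("TGT", "piezophile",
                   data.frame(protein_id = ids, description = "",
                              sequence = tgt_seqs, stringsAsFactors = FALSE)),
    clusters = cluster_table(clusters),
    truth = list(counts = substitution_counts(C_true, n_conserved, n_sites,
                                              n_sites),
                 per_family = per_family))
}

# base COG category frequencies for the generator (common categories of a
# heterotrophic gammaproteobacterium; normalized at use)
COG_BASE_FREQ <- c(J = 0.06, K = 0.08, L = 0.05, D = 0.01, V = 0.02,
                   T = 0.05, M = 0.07, N = 0.02, W = 0.005, U = 0.02,
                   O = 0.04, C = 0.06, G = 0.06, E = 0.09, F = 0.02,
                   H = 0.05, I = 0.03, P = 0.06, Q = 0.02, R = 0.10,
                   S = 0.08, X = 0.01)

#' Generate a COG category count table with planted group enrichments
#'
#' Per-genome counts are multinomial over a fixed base category frequency
#' vector, with the group's enrichment multipliers applied and
#' renormalized.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `cog` (a [cog_table]), `groups` (named vector) and
#'   `truth` (per-group realized probability vectors).
#' @export
gen_cog_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  groups <- synthetic_genome_ids(spec)
  probs <- lapply(stats::setNames(GROUP_LEVELS, GROUP_LEVELS), function(g) {
    p <- COG_BASE_FREQ
    mult <- spec$cog_enrichment[[g]]
    if (!is.null(mult)) p[names(mult)] <- p[names(mult)] * mult
    p / sum(p)
  })
  counts <- t(vapply(names(groups), function(g)
    as.integer(stats::rmultinom(1L, spec$cog_genes_per_genome,
                                probs[[groups[[g]]]])),
    integer(length(COG_BASE_FREQ))))
  colnames(counts) <- names(COG_BASE_FREQ)
  list(cog = cog_table(counts), groups = groups, truth = probs)
}

#' Write a complete synthetic study bundle to disk
#'
#' Emits per-genome proteome FASTA files plus a group config, the
#' ortholog REF/TGT FASTA pair with its cluster table, the COG count
#' table, and plain-text truth tables — everything [run_pipeline()]
#' consumes.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
gen_synthetic_bundle <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pz <- gen_proteomes(spec)
  orth <- gen_ortholog_families(spec)
  cogs <- gen_cog_table(spec)

  paths <- list()
  fasta <- character(0)
  for (g in names(pz$proteomes)) {
    f <- file.path(dir, paste0(g, ".faa"))
    write_proteome(pz$proteomes[[g]], f)
    fasta[g] <- basename(f)
  }
  groups <- synthetic_genome_ids(spec)
  cfg <- data.frame(genome_id = names(groups), group = unname(groups),
                    pressure_opt = NA_real_, fasta = unname(fasta),
                    stringsAsFactors = FALSE)
  paths$group_config <- file.path(dir, "groups.yaml")
  write_group_config(cfg, paths$group_config)

  paths$ref_fasta <- file.path(dir, "REF.faa")
  paths$tgt_fasta <- file.path(dir, "TGT.faa")
  write_proteome(orth$ref, paths$ref_fasta)
  write_proteome(orth$tgt, paths$tgt_fasta)
  paths$clusters <- file.path(dir, "clusters.tsv")
  write_cluster_table(orth$clusters, paths$clusters)
  paths$cog <- file.path(dir, "cog_counts.tsv")
  write_cog_table(cogs$cog, paths$cog)

  paths$truth_classes <- file.path(dir, "truth_protein_classes.tsv")
  utils::write.table(pz$truth, paths$truth_classes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$truth_substitutions <- file.path(dir, "truth_substitutions.tsv")
  Ct <- orth$truth$counts$C
  long <- data.frame(from = rep(AA20, times = 20L),
                     to = rep(AA20, each = 20L),
                     count = as.vector(Ct), stringsAsFactors = FALSE)
  utils::write.table(long[long$count > 0L, ], paths$truth_substitutions,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
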