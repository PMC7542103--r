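# Independent oracles and small fixture builders used across the suite.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_aa_seq <- function(len, alphabet = AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force pI: evaluate the charge model on a dense pH grid and return
# the grid point minimizing |Q|. Formula written out independently of the
# package internals.
grid_pi_oracle <- function(sequence, pka = pka_set("expasy"), step = 1e-5) {
  ch <- strsplit(sequence, "")[[1L]]
  pH <- seq(0, 14, by = step)
  q <- 1 / (1 + 10^(pH - pka$nterm)) - 1 / (1 + 10^(pka$cterm - pH))
  for (r in c("K", "R", "H")) {
    q <- q + sum(ch == r) / (1 + 10^(pH - pka$side[[r]]))
  }
  for (r in c("D", "E", "C", "Y")) {
    q <- q - sum(ch == r) / (1 + 10^(pka$side[[r]] - pH))
  }
  pH[which.min(abs(q))]
}

# Affine-gap score of a given gapped alignment: substitution score on
# residue columns, each gap run costs open + len * ext.
score_alignment <- function(ra, ta, mat, open = 11, ext = 1) {
  a <- strsplit(ra, "")[[1L]]
  b <- strsplit(ta, "")[[1L]]
  res <- a != "-" & b != "-"
  s <- sum(mat[cbind(a[res], b[res])])
  gap_cost <- function(g) {
    runs <- rle(g)
    sum(vapply(which(runs$values), function(i) open + ext * runs$lengths[i],
               numeric(1L)), 0)
  }
  s - gap_cost(a == "-") - gap_cost(b == "-")
}

# Exhaustive enumeration of all global alignments (paths over match /
# gap-up / gap-left moves with affine costs); returns the optimal score.
# Feasible for sequences of length <= 6-8.
enum_align_max <- function(a, b, mat, open = 11, ext = 1) {
  va <- strsplit(a, "")[[1L]]
  vb <- strsplit(b, "")[[1L]]
  n <- length(va)
  m <- length(vb)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, mat[va[i], vb[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= n) {
      best <- max(best,
                  -(ext + if (prev == "U") 0 else open) + rec(i + 1L, j, "U"))
    }
    if (j <= m) {
      best <- max(best,
                  -(ext + if (prev == "L") 0 else open) + rec(i, j + 1L, "L"))
    }
    best
  }
  rec(1L, 1L, "M")
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# Deterministic strongly basic / strongly acidic designed sequences.
basic_seq <- function(i = 1L) paste0("M", strrep("KR", 8L + i %% 3))
acidic_seq <- function(i = 1L) paste0("M", strrep("DE", 8L + i %% 3))

designed_proteome <- function(genome_id, group, n_basic, n_acidic) {
  n <- n_basic + n_acidic
  seqs <- c(vapply(seq_len(n_basic), basic_seq, character(1L)),
            vapply(seq_len(n_acidic), acidic_seq, character(1L)))
  proteome(genome_id, group,
           data.frame(protein_id = sprintf("p%03d", seq_len(n)),
                      sequence = seqs, stringsAsFactors = FALSE))
}

# Minimal stand-in asymmetry result carrying only per_pair, for consensus
# rule tests.
fake_asym_result <- function(pairs_df) {
  pt <- piezocomp:::pair_index_table()
  pp <- data.frame(a = pt$a, b = pt$b, index = NA_real_,
                   significant = FALSE, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs_df))) {
    i <- which(pp$a == pairs_df$a[k] & pp$b == pairs_df$b[k])
    pp$index[i] <- pairs_df$index[k]
    pp$significant[i] <- pairs_df$significant[k]
  }
  structure(list(per_pair = pp), class = "asymmetry_result")
}

fake_profile <- function(genome_id, group, bias, n = 100L) {
  nb <- round(n * (1 + bias / 100) / 2)
  structure(list(genome_id = genome_id, group = group,
                 pressure_opt = NA_real_, pi = numeric(0), bins = integer(0),
                 n_acidic = n - nb, n_basic = nb, bias_pct = bias,
                 pka = "expasy"),
            class = "pi_profile")
}

# Random gapped alignment over the plain alphabet, for mask properties.
rand_gapped_alignment <- function(len = 40L, gap_p = 0.1) {
  mk <- function() {
    ch <- sample(AA, len, replace = TRUE)
    ch[runif(len) < gap_p] <- "-"
    ch
  }
  a <- mk()
  b <- mk()
  both <- a == "-" & b == "-"   # drop all-gap columns (not valid alignments)
  pairwise_alignment(paste(a[!both], collapse = ""),
                     paste(b[!both], collapse = ""))
}
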