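test_that("single-copy filtering keeps exactly-one-member clusters only", {
  ct <- cluster_table(list(
    multi = list(G1 = c("a", "b"), G2 = "c"),
    absent = list(G1 = "d"),
    good = list(G1 = "e", G2 = "f")))
  out <- single_copy_clusters(ct, c("G1", "G2"))
  expect_equal(names(out$clusters), "good")
})

test_that("ambiguity mask excludes gap neighborhoods and ambiguous residues", {
  # every column within 2 of the gap column -> all 4 masked
  m <- ambiguity_mask(pairwise_alignment("A-EE", "AAEK"), window = 2)
  expect_equal(m$keep, rep(FALSE, 4))
  # gapless, unambiguous -> all kept
  m2 <- ambiguity_mask(pairwise_alignment("MKVL", "MKVI"), window = 2)
  expect_equal(m2$keep, rep(TRUE, 4))
  # window 0: only the ambiguous column masked
  m3 <- ambiguity_mask(pairwise_alignment("AXKK", "AAKK"), window = 0)
  expect_equal(m3$keep, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("masking is monotone: larger windows never keep more sites", {
  set.seed(41)
  for (i in 1:20) {
    aln <- rand_gapped_alignment()
    kept <- vapply(0:4, function(w) sum(ambiguity_mask(aln, w)$keep),
                   numeric(1L))
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("substitution counting obeys its conservation invariant", {
  aln <- pairwise_alignment("AAEE", "AAKK")
  cnt <- count_substitutions(aln, ambiguity_mask(aln))
  expect_equal(cnt$C["E", "K"], 2L)
  expect_equal(cnt$n_conserved, 2L)
  expect_equal(cnt$n_sites, 4L)
  expect_equal(sum(cnt$C) + cnt$n_conserved, cnt$n_sites)
  # self-comparison: everything conserved
  self <- pairwise_alignment("MKVLIDE", "MKVLIDE")
  cs <- count_substitutions(self, ambiguity_mask(self))
  expect_equal(sum(cs$C), 0L)
  expect_equal(cs$n_conserved, cs$n_sites)
})

test_that("swapping ref and tgt transposes counts and negates residue indices", {
  set.seed(43)
  for (i in 1:10) {
    aln <- rand_gapped_alignment(len = 60, gap_p = 0.05)
    swp <- pairwise_alignment(aln$tgt_aligned, aln$ref_aligned)
    c1 <- count_substitutions(aln, ambiguity_mask(aln))
    c2 <- count_substitutions(swp, ambiguity_mask(swp))
    expect_identical(c2$C, t(c1$C))
    expect_equal(c2$n_conserved, c1$n_conserved)
  }
})

test_that("pooling counts is an elementwise sum verified by recount", {
  a1 <- pairwise_alignment("AAEE", "AAKK")
  a2 <- pairwise_alignment("MKVLIDEDE", "MKVLIDEDD")
  cnts <- lapply(list(a1, a2), function(a)
    count_substitutions(a, ambiguity_mask(a)))
  pooled <- pool_counts(cnts)
  expect_equal(pooled$n_sites, 13L)
  # recount oracle: concatenated alignment gives the same pooled counts
  cat_aln <- pairwise_alignment(paste0(a1$ref_aligned, a2$ref_aligned),
                                paste0(a1$tgt_aligned, a2$tgt_aligned))
  recount <- count_substitutions(cat_aln, ambiguity_mask(cat_aln))
  expect_identical(pooled$C, recount$C)
  expect_equal(pooled$n_conserved, recount$n_conserved)
  # pool of one is the identity
  expect_identical(pool_counts(cnts[1])$C, cnts[[1]]$C)
})

test_that("asymmetry indices follow the count imbalance and report NA when empty", {
  C <- matrix(0L, 20, 20, dimnames = list(AA, AA))
  C["E", "K"] <- 2L
  C["A", "G"] <- 7L
  C["G", "A"] <- 7L
  one <- substitution_counts(C, 10L, 26L)
  res <- asymmetry(list(one, one), n_replicates = 50, seed = 5)
  pp <- res$per_pair
  expect_equal(pp$index[pp$a == "E" & pp$b == "K"], 1)
  expect_equal(pp$index[pp$a == "A" & pp$b == "G"], 0)
  # unobserved pair is missing, never zero
  expect_true(is.na(pp$index[pp$a == "C" & pp$b == "W"]))
  # per-residue gains/losses bookkeeping
  pr <- res$per_residue
  expect_equal(pr$gains[pr$residue == "K"], 4)
  expect_equal(pr$losses[pr$residue == "E"], 4)
  expect_equal(pr$index[pr$residue == "K"], 1)
})

test_that("planted directional excess is recovered with the right sign", {
  hits <- 0L
  for (s in 1:5) {
    sp <- synthetic_spec(seed = 100 + s, planted_asym = c("E->K" = 0.02))
    orth <- gen_ortholog_families(sp)
    expect_gte(orth$truth$counts$n_sites, 1e4)
    res <- asymmetry(orth$truth$per_family, seed = 200 + s)
    pp <- res$per_pair
    row <- pp[pp$a == "E" & pp$b == "K", ]
    pr <- res$per_residue
    if (row$index > 0 && row$z > 1.96 &&
        pr$index[pr$residue == "K"] > 0) hits <- hits + 1L
  }
  expect_equal(hits, 5L)
})

test_that("the pooled substitution ratio matches the planted rates", {
  # planted E->A 0.02 vs background A->E; expect a strong directed excess
  sp <- synthetic_spec(seed = 301, n_ortholog_families = 150,
                       planted_asym = c("E->A" = 0.02))
  orth <- gen_ortholog_families(sp)
  C <- orth$truth$counts$C
  expect_gt(C["E", "A"], C["A", "E"])
  # background A->E stays near divergence/19 per A site; E->A gains ~0.02
  expect_gt(C["E", "A"] / max(C["A", "E"], 1), 2)
})

test_that("pair_asymmetry filters low-identity pairings", {
  set.seed(47)
  mk <- function(g, grp) proteome(g, grp, data.frame(
    protein_id = sprintf("r%02d", 1:6),
    sequence = vapply(rep(80, 6), rand_aa_seq, character(1L)),
    stringsAsFactors = FALSE))
  # two unrelated random proteomes: every RBH pair fails the 30% identity
  # or 50-site floor and the run aborts rather than reporting noise
  expect_error(pair_asymmetry(mk("R", "piezosensitive"),
                              mk("T", "piezophile"), seed = 7),
               "identity/site filters")
})

test_that("consensus requires same-sign significance in every comparison", {
  r1 <- fake_asym_result(data.frame(a = c("E", "A", "D"), b = c("K", "G", "N"),
                                    index = c(0.5, 0.4, 0.6),
                                    significant = c(TRUE, TRUE, TRUE)))
  r2 <- fake_asym_result(data.frame(a = c("E", "A", "D"), b = c("K", "G", "N"),
                                    index = c(0.3, 0.2, -0.5),
                                    significant = c(TRUE, FALSE, TRUE)))
  cons <- consensus_substitutions(list(r1, r2), c("cmp1", "cmp2"))
  expect_true(cons$conserved[cons$a == "E" & cons$b == "K"])     # both sig +
  expect_false(cons$conserved[cons$a == "A" & cons$b == "G"])    # one not sig
  expect_false(cons$conserved[cons$a == "D" & cons$b == "N"])    # sign flip
  expect_equal(cons$direction[cons$a == "E" & cons$b == "K"], "a->b")
})
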