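#!/usr/bin/env Rscript
# Directed amino-acid substitution asymmetry between the piezosensitive
# reference lineage and the piezophile target lineage, in two independent
# synthetic comparisons, plus the cross-comparison consensus of directed
# substitutions (significant with the same direction in both).

library(piezocomp)

run_one <- function(dir, seed) {
  ref <- read_proteome(file.path(dir, "REF.faa"), "REF", "piezosensitive")
  tgt <- read_proteome(file.path(dir, "TGT.faa"), "TGT", "piezophile")
  clusters <- read_cluster_table(file.path(dir, "clusters.tsv"))
  pair_asymmetry(ref, tgt, clusters = clusters, window = 2,
                 n_replicates = 100, seed = seed)
}

cmp1 <- run_one("results/sim", seed = 11)
cmp2 <- run_one("results/sim_rep2", seed = 12)

for (nm in c("cmp1", "cmp2")) {
  res <- get(nm)$result
  pp <- res$per_pair
  sig <- pp[!is.na(pp$index) & pp$significant, ]
  sig <- sig[order(-abs(sig$z)), ]
  cat(sprintf("\n%s: %d kept sites, %d/%d pairs used, top significant pairs:\n",
              nm, res$counts$n_sites, get(nm)$n_pairs_used,
              get(nm)$n_pairs_total))
  print(head(sig[, c("a", "b", "c_ab", "c_ba", "index", "z")], 5),
        row.names = FALSE)
  write.table(pp, sprintf("results/asymmetry_pairs_%s.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$per_residue, sprintf("results/asymmetry_residues_%s.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cons <- consensus_substitutions(list(cmp1$result, cmp2$result),
                                c("cmp1", "cmp2"))
conserved <- cons[cons$conserved, ]
cat("\nDirected substitutions conserved across both comparisons:\n")
print(conserved[, c("a", "b", "index_cmp1", "index_cmp2", "direction")],
      row.names = FALSE)
write.table(cons, "results/asymmetry_consensus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
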