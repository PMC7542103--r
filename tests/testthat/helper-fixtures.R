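# A hand-built seven-genome study: 4 piezophiles (P1-P4), 3 piezosensitive
# (S1-S3), with clusters planted in each pan-genome compartment.
toy_seven_genome <- function() {
  groups <- c(P1 = "piezophile", P2 = "piezophile", P3 = "piezophile",
              P4 = "piezophile", S1 = "piezosensitive", S2 = "piezosensitive",
              S3 = "piezosensitive")
  one <- function(genomes) {
    m <- lapply(genomes, function(g) paste0(g, "_x"))
    names(m) <- genomes
    m
  }
  clusters <- list(
    core1 = one(names(groups)),                       # all 7 -> core
    core2 = one(names(groups)),
    core3 = one(names(groups)),
    shell1 = one(c("P1", "P2", "S1")),                # 3 genomes -> shell
    shell2 = one(c("P1", "P2", "P3", "P4", "S1", "S2")),  # 6 -> shell
    pz_only1 = one(c("P1", "P2", "P3", "P4")),        # piezophile-exclusive
    pz_only2 = one(c("P1", "P2", "P3", "P4")),
    ps_only = one(c("S1", "S2", "S3")),               # piezosensitive-excl.
    cloud1 = one("P3"),                               # singletons -> cloud
    cloud2 = one("S2"))
  list(matrix = gene_content_matrix(cluster_table(clusters), groups),
       groups = groups)
}

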