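test_that("FASTA parsing yields one record per entry with cleaned sequences", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 hypothetical protein", "MKR", ">p2", "DD", "E",
               ">p3", "mkr*"), f)
  p <- read_proteome(f, "G1", "piezophile")
  expect_equal(nrow(p$records), 3L)
  expect_equal(p$records$protein_id, c("p1", "p2", "p3"))
  # wrapped lines joined, lowercase uppercased, terminal stop stripped
  expect_equal(p$records$sequence, c("MKR", "DDE", "MKR"))
  expect_equal(p$records$description[1L], "hypothetical protein")
  # parser never drops records: header count == record count
  expect_equal(sum(startsWith(readLines(f), ">")), nrow(p$records))
})

test_that("FASTA validation rejects empty files and illegal characters", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(character(0), f)
  expect_error(read_proteome(f, "G1", "piezophile"), "no FASTA records")
  writeLines(c(">p1", "M1K"), f)
  expect_error(read_proteome(f, "G1", "piezophile"), "'1'.*p1")
  writeLines(c(">pa", "MKR", ">pa", "MKR"), f)
  expect_error(read_proteome(f, "G1", "piezophile"), "duplicate protein_id")
})

test_that("proteome FASTA round-trips identically", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:20, 1)
    recs <- data.frame(
      protein_id = sprintf("prot%02d", seq_len(n)),
      description = sample(c("", "desc text"), n, replace = TRUE),
      sequence = vapply(sample(20:200, n, replace = TRUE), rand_aa_seq,
                        character(1L), alphabet = c(AA, "X", "U")),
      stringsAsFactors = FALSE)
    p <- proteome("G1", "piezosensitive", recs)
    f <- withr::local_tempfile(fileext = ".faa")
    write_proteome(p, f)
    p2 <- read_proteome(f, "G1", "piezosensitive")
    expect_identical(p2$records, p$records)
  }
})

test_that("cluster tables parse, reject duplicates and malformed tokens", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\tG1:p1\tG2:p9", "c2\tG1:p1\tG1:p2"), f)
  ct <- read_cluster_table(f)
  expect_equal(ct$clusters$c1, list(G1 = "p1", G2 = "p9"))
  expect_equal(ct$clusters$c2, list(G1 = c("p1", "p2")))  # multi-copy kept
  writeLines(c("c1\tG1:p1", "c1\tG2:p2"), f)
  expect_error(read_cluster_table(f), "duplicate cluster_id 'c1'")
  writeLines(c("c1\tG1:p1", "c2\tG1p2"), f)
  expect_error(read_cluster_table(f), "line 2")
})

test_that("cluster tables round-trip and validate against proteomes", {
  ct <- cluster_table(list(c1 = list(G1 = "p1", G2 = "p2"),
                           c2 = list(G1 = c("p3", "p4"))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(ct, f)
  expect_equal(read_cluster_table(f)$clusters, ct$clusters)
  g1 <- proteome("G1", "piezophile",
                 data.frame(protein_id = c("p1", "p3", "p4"),
                            sequence = rep("MKL", 3)))
  expect_true(validate_cluster_table(ct, list(g1)))
  ct_bad <- cluster_table(list(c1 = list(G1 = "p9")))
  expect_error(validate_cluster_table(ct_bad, list(g1)), "unknown protein 'p9'")
})

test_that("COG tables load in both count and per-protein form", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\tJ\t10", "G1\tK\t5", "G2\tJ\t7"), f)
  ct <- read_cog_table(f)
  expect_equal(ct$counts["G1", c("J", "K")], c(J = 10L, K = 5L))
  expect_equal(ct$counts["G2", "J"], 7L)
  writeLines(c("G1\tp1\tL", "G1\tp2\tL", "G1\tp3\tL"), f)
  expect_equal(read_cog_table(f)$counts["G1", "L"], 3L)
  writeLines(c("G1\t9\t10"), f)
  expect_error(read_cog_table(f), "unknown COG category '9'")
})

test_that("group config round-trips", {
  df <- data.frame(genome_id = c("A", "B"),
                   group = c("piezophile", "piezosensitive"),
                   pressure_opt = c(60, NA), fasta = c("a.faa", "b.faa"),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_group_config(df, f)
  expect_equal(read_group_config(f), df)
})
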