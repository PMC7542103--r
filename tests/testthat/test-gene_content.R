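test_that("the toy seven-genome matrix partitions exactly by construction", {
  toy <- toy_seven_genome()
  part <- pan_partition(toy$matrix)
  expect_equal(part$n_core, 3L)
  expect_equal(part$n_shell, 5L)   # shell1, shell2, pz_only1/2, ps_only
  expect_equal(part$n_cloud, 2L)
  expect_equal(part$n_total, 10L)
  expect_equal(part$n_core + part$n_shell + part$n_cloud, part$n_total)
  expect_setequal(part$group_exclusive$piezophile, c("pz_only1", "pz_only2"))
  expect_setequal(part$group_exclusive$piezosensitive, "ps_only")
})

test_that("partitioning is invariant under genome reordering", {
  toy <- toy_seven_genome()
  part1 <- pan_partition(toy$matrix)
  set.seed(51)
  perm <- sample(names(toy$groups))
  mat2 <- toy$matrix
  mat2$presence <- mat2$presence[, perm]
  mat2$groups <- toy$groups[perm]
  part2 <- pan_partition(mat2)
  expect_equal(part2$n_core, part1$n_core)
  expect_equal(part2$n_shell, part1$n_shell)
  expect_equal(part2$n_cloud, part1$n_cloud)
  expect_setequal(part2$group_exclusive$piezophile,
                  part1$group_exclusive$piezophile)
})

test_that("adding genomes never increases the core", {
  toy <- toy_seven_genome()
  genomes <- names(toy$groups)
  cores <- vapply(2:7, function(k) {
    sub <- toy$matrix
    sub$presence <- sub$presence[, genomes[1:k], drop = FALSE]
    sub$groups <- toy$groups[genomes[1:k]]
    keep <- rowSums(sub$presence) > 0
    sub$presence <- sub$presence[keep, , drop = FALSE]
    pan_partition(sub)$n_core
  }, numeric(1L))
  expect_true(all(diff(cores) <= 0))
})

test_that("COG comparison degenerates to t = 0 on identical groups", {
  counts <- rbind(A1 = c(J = 10L, K = 20L, L = 30L),
                  A2 = c(J = 10L, K = 20L, L = 30L),
                  B1 = c(J = 10L, K = 20L, L = 30L),
                  B2 = c(J = 10L, K = 20L, L = 30L))
  groups <- c(A1 = "piezophile", A2 = "piezophile",
              B1 = "piezosensitive", B2 = "piezosensitive")
  res <- cog_compare(cog_table(counts), groups)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
})

test_that("COG comparison rejects undersized groups and empty genomes", {
  counts <- rbind(A1 = c(J = 10L), A2 = c(J = 10L), B1 = c(J = 10L))
  groups3 <- c(A1 = "piezophile", A2 = "piezophile", B1 = "piezosensitive")
  expect_error(cog_compare(cog_table(counts), groups3), "at least 2")
  counts0 <- rbind(A1 = c(J = 10L, K = 2L), A2 = c(J = 0L, K = 0L),
                   B1 = c(J = 10L, K = 1L), B2 = c(J = 9L, K = 2L))
  groups4 <- c(A1 = "piezophile", A2 = "piezophile",
               B1 = "piezosensitive", B2 = "piezosensitive")
  expect_error(cog_compare(cog_table(counts0), groups4), "zero annotated")
})

test_that("a planted 1.5x category-L enrichment is ranked first", {
  hits <- 0L
  for (s in 1:50) {
    sp <- synthetic_spec(seed = 400 + s, n_piezophile = 5,
                         n_piezosensitive = 5, cog_genes_per_genome = 3000,
                         cog_enrichment = list(piezophile = c(L = 1.5)))
    cogs <- gen_cog_table(sp)
    res <- cog_compare(cogs$cog, cogs$groups)
    if (res$category[1L] == "L") hits <- hits + 1L
  }
  expect_gte(hits, 45L)  # >= 90% of 50 seeded replicates
})

test_that("without enrichment the per-category type-I error is near nominal", {
  n_sig <- 0L
  n_tot <- 0L
  for (s in 1:100) {
    sp <- synthetic_spec(seed = 600 + s, n_piezophile = 5,
                         n_piezosensitive = 5, cog_enrichment = list())
    cogs <- gen_cog_table(sp)
    res <- cog_compare(cogs$cog, cogs$groups)
    n_sig <- n_sig + sum(res$p < 0.05)
    n_tot <- n_tot + nrow(res)
  }
  rate <- n_sig / n_tot
  # binomial 99% bound around 0.05 over ~2200 tests, plus slack for the
  # multinomial coupling between categories
  expect_lt(abs(rate - 0.05), 2.58 * sqrt(0.05 * 0.95 / n_tot) + 0.015)
})

test_that("marker grids extract the requested presence patterns", {
  toy <- toy_seven_genome()
  grid <- marker_table(toy$matrix, c("core1", "pz_only1", "ps_only"))
  expect_true(all(grid[, "core1"]))
  pz <- names(toy$groups)[toy$groups == "piezophile"]
  expect_true(all(grid[pz, "pz_only1"]))
  expect_true(all(!grid[setdiff(rownames(grid), pz), "pz_only1"]))
  expect_error(marker_table(toy$matrix, "nope"), "unknown marker")
})
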