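test_that("net charge shows the correct titration limits and closed form", {
  # at pH 0 everything protonated: net ~ +1 (C-terminus residually ~ -3e-4)
  expect_equal(net_charge("GG", 0), 1, tolerance = 5e-4)
  expect_gt(net_charge("GG", 0), 0.999)
  # at pH 14 everything deprotonated: net ~ -1
  expect_equal(net_charge("GG", 14), -1, tolerance = 1e-6)
  # independent hand evaluation of the charge model for KDE at pH 7
  pk <- pka_set("expasy")
  expected <- 1 / (1 + 10^(7 - 7.5)) +      # N-terminus
    1 / (1 + 10^(7 - 10.0)) -               # K
    1 / (1 + 10^(3.55 - 7)) -               # C-terminus
    1 / (1 + 10^(4.05 - 7)) -               # D
    1 / (1 + 10^(4.45 - 7))                 # E
  expect_equal(net_charge("KDE", 7, pk), expected, tolerance = 1e-12)
  # ambiguity codes carry no charge
  expect_equal(net_charge("KDEXXUU", 7, pk), expected, tolerance = 1e-12)
})

test_that("net charge is strictly decreasing in pH", {
  set.seed(11)
  for (i in 1:20) {
    s <- rand_aa_seq(sample(10:100, 1))
    pH <- seq(0.5, 13.5, by = 0.5)
    q <- vapply(pH, function(x) net_charge(s, x), numeric(1L))
    expect_true(all(diff(q) < 0))
  }
})

test_that("bisection pI behaves like the composition it summarizes", {
  expect_gt(compute_pi(strrep("K", 10)), compute_pi(strrep("D", 10)))
  # order invariance: pI depends on composition only
  expect_equal(compute_pi("MKR"), compute_pi("RKM"), tolerance = 1e-10)
  # glycine dipeptide against the dense-grid oracle
  expect_equal(compute_pi("GG"), grid_pi_oracle("GG"), tolerance = 1e-3)
  # appending a basic residue never decreases pI
  set.seed(12)
  for (i in 1:10) {
    s <- rand_aa_seq(sample(20:80, 1))
    expect_gte(compute_pi(paste0(s, "K")), compute_pi(s) - 1e-6)
  }
})

test_that("bisection pI agrees with the grid-search oracle", {
  set.seed(13)
  for (i in 1:10) {
    s <- rand_aa_seq(sample(20:120, 1))
    expect_equal(compute_pi(s), grid_pi_oracle(s), tolerance = 1e-3)
  }
})

test_that("pI profiles bin at 0.1 resolution and split acid/base strictly", {
  p <- designed_proteome("G1", "piezophile", n_basic = 1, n_acidic = 2)
  pr <- pi_profile(p)
  expect_equal(sum(pr$bins), 3L)           # every protein lands in a bin
  expect_equal(pr$n_acidic, 2L)
  expect_equal(pr$n_basic, 1L)
  expect_equal(pr$bias_pct, 100 * (1 - 2) / 3)
  # all-basic proteome
  pb <- pi_profile(designed_proteome("G2", "piezophile", 4, 0))
  expect_equal(pb$n_acidic, 0L)
  expect_equal(pb$n_basic, 4L)
})

test_that("synthetic basic fraction is recovered within binomial bounds", {
  sp <- synthetic_spec(seed = 21, n_piezophile = 1, n_piezosensitive = 1,
                       proteome_size = 2000,
                       basic_fraction = c(piezophile = 0.6,
                                          piezosensitive = 0.5))
  gp <- gen_proteomes(sp)
  pr <- pi_profile(gp$proteomes$PZ01)
  frac <- pr$n_basic / (pr$n_acidic + pr$n_basic)
  ci <- 1.96 * sqrt(0.6 * 0.4 / 2000)
  expect_lt(abs(frac - 0.6), ci + 0.01)
})

test_that("pI bias hits its boundary and midpoint values", {
  expect_equal(pi_bias(pi_profile(designed_proteome("G", "piezophile", 10, 0))),
               100)
  expect_equal(pi_bias(pi_profile(designed_proteome("G", "piezophile", 5, 5))),
               0)
  expect_equal(pi_bias(pi_profile(designed_proteome("G", "piezophile", 1, 3))),
               -50)
})

test_that("group bias comparison: degenerate and error cases", {
  profs <- list(fake_profile("A1", "piezophile", 10),
                fake_profile("A2", "piezophile", 10),
                fake_profile("B1", "piezosensitive", 10),
                fake_profile("B2", "piezosensitive", 10))
  cmp <- compare_bias(profs)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  expect_error(compare_bias(profs[c(1, 3, 4)]), "at least 2 genomes")
})

test_that("a +30-point bias shift with sd-5 noise is detected at p < .01", {
  set.seed(31)
  hits <- 0L
  for (rep in 1:100) {
    profs <- c(
      lapply(1:5, function(i)
        fake_profile(paste0("A", i), "piezophile", rnorm(1, 10, 5))),
      lapply(1:5, function(i)
        fake_profile(paste0("B", i), "piezosensitive", rnorm(1, -20, 5))))
    if (compare_bias(profs)$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
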