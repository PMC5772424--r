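test_that("hand-worked single-locus example is reproduced exactly", {
  # individuals (100/102) and (102/104): K=3, R=4, M=0.6, H=(4/3)(1-0.375)
  g <- array(c(100L, 102L, 102L, 104L), c(2L, 1L, 2L))
  dat <- genotype_data(g, pop = c("a", "a"))
  s <- microsat_sumstats(dat, grouping = "pooled")
  expect_equal(unname(s["K_mean"]), 3)
  expect_equal(unname(s["R_mean"]), 4)
  expect_equal(unname(s["M_mean"]), 0.6)
  expect_equal(unname(s["H_mean"]), (4 / 3) * (1 - 0.375))
})

test_that("a monomorphic locus gives K=1, H=0, R=0, M=1", {
  g <- array(150L, c(4L, 1L, 2L))
  s <- microsat_sumstats(genotype_data(g, pop = rep("a", 4)),
                         grouping = "pooled")
  expect_equal(unname(s[c("K_mean", "H_mean", "R_mean", "M_mean")]),
               c(1, 0, 0, 1))
})

test_that("statistics agree with the brute-force oracle on random data", {
  set.seed(21)
  for (rep in 1:100) {
    n_pops <- sample(2:4, 1)
    dat <- random_genotype_data(n_ind = sample(4:10, 1),
                                n_loci = sample(1:3, 1), n_pops = n_pops,
                                miss_rate = sample(c(0, 0.15), 1))
    s <- microsat_sumstats(dat, grouping = "demes")
    o <- naive_microsat_sumstats(dat)
    common <- intersect(names(o), names(s))
    expect_equal(unname(s[common]), unname(o[common]), tolerance = 1e-10)
  }
})

test_that("fast simulation path and public statistics agree", {
  specs <- default_model_specs()
  set.seed(22)
  p <- draw_params(specs$ACS, 1)[1, ]
  smp <- sample_config(rep(20L, 4), n_loci = 5L)
  set.seed(77)
  fast <- demabc:::sim_panel_stats("ACS", as.list(p), smp)
  set.seed(77)
  dat <- simulate_dataset("ACS", p, smp)
  slow <- stat_panel(microsat_sumstats(dat, grouping = "demes"))
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("duplicated demes give non-positive multi-locus FST", {
  set.seed(23)
  one <- random_genotype_data(6, 3, 1)
  g2 <- array(NA_integer_, c(12L, 3L, 2L))
  g2[1:6, , ] <- one$genotypes
  g2[7:12, , ] <- one$genotypes
  dup <- genotype_data(g2, pop = rep(c("a", "b"), each = 6))
  s <- microsat_sumstats(dup, grouping = "demes")
  expect_lte(unname(s["fst_global"]), 1e-12)
  o <- naive_fst(demabc:::genotype_copies(dup)$copies,
                 demabc:::genotype_copies(dup)$group)
  expect_equal(unname(s["fst_global"]), o, tolerance = 1e-10)
})

test_that("statistics are invariant to individual and locus permutation", {
  set.seed(24)
  dat <- random_genotype_data(8, 3, 2)
  s1 <- microsat_sumstats(dat, grouping = "demes")
  perm_ind <- sample(8)
  perm_loc <- sample(3)
  dat2 <- genotype_data(dat$genotypes[perm_ind, perm_loc, , drop = FALSE],
                        pop = dat$pop[perm_ind])
  s2 <- microsat_sumstats(dat2, grouping = "demes")
  expect_equal(unname(s1), unname(s2), tolerance = 1e-12)
})

test_that("empty/small groups raise errors naming the group", {
  g <- array(100L, c(3L, 2L, 2L))
  dat <- genotype_data(g, pop = c("a", "a", "b"))
  dat$pop <- factor(dat$pop, levels = c("a", "b", "ghost"))
  expect_error(microsat_sumstats(dat, grouping = "demes"), "ghost")
})

test_that("mtDNA statistics match hand computation and brute force", {
  mono <- haplotype_data(seqs = rep(strrep("A", 630), 60))
  expect_equal(mtdna_sumstats(mono), c(H = 1, S = 0, pi = 0))
  expect_true(is_zero_diversity(mono))

  tri <- haplotype_data(seqs = c("AAA", "AAT", "AAT"))
  expect_equal(mtdna_sumstats(tri), c(H = 2, S = 1, pi = 2 / 3))
  expect_false(is_zero_diversity(tri))

  set.seed(25)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C"), 6, replace = TRUE), collapse = ""),
      character(1))
    hd <- haplotype_data(seqs = seqs)
    expect_equal(mtdna_sumstats(hd), naive_mtdna(seqs), tolerance = 1e-12)
    # permutation invariance
    hd2 <- haplotype_data(seqs = sample(seqs))
    expect_equal(mtdna_sumstats(hd2), mtdna_sumstats(hd))
  }
  expect_error(haplotype_data(seqs = c("AAA", "AA")), "ragged")
})

test_that("zero diversity coincides with H == 1 on simulated data", {
  d <- const_demography(200)
  smp <- sample_config(10L, ploidy = "mito")
  set.seed(26)
  agree <- replicate(300, {
    g <- simulate_genealogy(d, smp)
    sites <- mutate_sequence(g, mutation_config(2e-3))
    hd <- haplotype_data(sites = sites)
    is_zero_diversity(hd) == (mtdna_sumstats(hd)[["H"]] == 1)
  })
  expect_true(all(agree))
  # and H=1 <=> S=0 <=> pi=0
  set.seed(27)
  for (rep in 1:50) {
    g <- simulate_genealogy(d, smp)
    sites <- mutate_sequence(g, mutation_config(1e-3))
    st <- mtdna_sumstats(haplotype_data(sites = sites))
    expect_equal(st[["H"]] == 1, st[["S"]] == 0)
    expect_equal(st[["S"]] == 0, st[["pi"]] == 0)
  }
})
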