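# Monte-Carlo checks of the coalescent engine against closed-form
# expectations; each within 3 standard errors at a fixed seed.

test_that("pairwise TMRCA matches the Kingman expectation E[T2] = 2N", {
  d <- const_demography(1000)
  smp <- sample_config(2L)
  set.seed(11)
  tm <- replicate(10000, tmrca(simulate_genealogy(d, smp)))
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2000), 3 * se)
})

test_that("single lineage gives a zero-depth tree", {
  d <- const_demography(1000)
  g <- simulate_genealogy(d, sample_config(1L, ploidy = "mito"))
  expect_equal(g$n, 1L)
  expect_equal(max(g$time), 0)
})

test_that("haploid total branch length matches 2*G*sum(1/i)", {
  # mito sampling with female_scale 0.25: G = N/2 = 500 copies
  d <- const_demography(1000)
  smp <- sample_config(10L, ploidy = "mito", female_scale = 0.25)
  set.seed(12)
  len <- replicate(10000, total_branch_length(simulate_genealogy(d, smp)))
  expected <- 2 * 500 * sum(1 / (1:9))
  se <- stats::sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - expected), 3 * se)
})

test_that("genealogies satisfy structural invariants", {
  specs <- default_model_specs()
  set.seed(13)
  for (m in c("AC", "ACS", "TI")) {
    p <- draw_params(specs[[m]], 1)[1, ]
    d <- build_demography(m, p)
    smp <- sample_config(rep(6L, if (m == "ACS") 4L else 1L) * 2L)
    g <- simulate_genealogy(d, smp)
    n <- g$n
    expect_equal(sum(is.na(g$parent)), 1L)   # one root
    expect_equal(length(g$parent), 2L * n - 1L)
    ok <- !is.na(g$parent)
    expect_true(all(g$time[g$parent[ok]] >= g$time[ok]))
    expect_true(all(diff(g$time[(n + 1):(2 * n - 1)]) >= 0))
  }
})

test_that("lineages stranded in never-merging demes raise an error", {
  segs <- rbind(c(0, 0, Inf, 100, 0), c(1, 0, Inf, 100, 0))
  merges <- matrix(numeric(0), 0, 3)
  expect_error(
    demabc:::rcpp_sim_genealogy(segs, merges, c(0L, 0L, 1L, 1L), 2),
    "non-coalescing")
})

test_that("GSM mutation respects its degenerate limits", {
  d <- const_demography(1000)
  smp <- sample_config(10L)
  set.seed(14)
  g <- simulate_genealogy(d, smp)
  expect_equal(mutate_microsat(g, mutation_config(0)), rep(0L, 10L))
  sites <- mutate_sequence(g, mutation_config(0))
  expect_equal(ncol(sites), 0L)
  expect_error(mutation_config(1e-3, p_gsm = 1))
})

test_that("SMM equilibrium heterozygosity matches Ohta-Kimura (theta = 4)", {
  # N = 1000, mu = 1e-3: expected het 1 - 1/sqrt(1 + 2*theta) = 2/3
  d <- const_demography(1000)
  smp <- sample_config(50L)
  cfg <- mutation_config(1e-3, p_gsm = 0)
  set.seed(15)
  het <- replicate(2000, {
    g <- simulate_genealogy(d, smp)
    naive_het(mutate_microsat(g, cfg))
  })
  se <- stats::sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - 2 / 3), 3 * se)
})

test_that("infinite-sites S and pi match Watterson and Tajima", {
  # G = 500 copies, theta = 2*G*mu_seq = 0.2
  d <- const_demography(1000)
  smp <- sample_config(10L, ploidy = "mito", female_scale = 0.25)
  cfg <- mutation_config(0.2 / (2 * 500))
  set.seed(16)
  res <- replicate(10000, {
    g <- simulate_genealogy(d, smp)
    sites <- mutate_sequence(g, cfg)
    S <- ncol(sites)
    pi <- if (S == 0) 0 else {
      cnt <- colSums(sites)
      sum(cnt * (10 - cnt)) / choose(10, 2)
    }
    c(S, pi, nrow(unique(sites)))
  })
  a9 <- sum(1 / (1:9))
  se_S <- stats::sd(res[1, ]) / sqrt(ncol(res))
  se_pi <- stats::sd(res[2, ]) / sqrt(ncol(res))
  expect_lt(abs(mean(res[1, ]) - 0.2 * a9), 3 * se_S)
  expect_lt(abs(mean(res[2, ]) - 0.2), 3 * se_pi)
  # infinite sites: haplotype count bounded by S + 1
  expect_true(all(res[3, ] <= res[1, ] + 1))
})

test_that("simulate_dataset is deterministic and has the right shape", {
  specs <- default_model_specs()
  set.seed(17)
  p <- draw_params(specs$AC, 1)[1, ]
  smp <- sample_config(rep(112L, 4), n_loci = 18L)
  d1 <- simulate_dataset("AC", p, smp, seed = 99)
  d2 <- simulate_dataset("AC", p, smp, seed = 99)
  expect_identical(d1, d2)
  expect_equal(dim(d1$genotypes), c(224L, 18L, 2L))
  expect_equal(nlevels(d1$pop), 4L)
  # 224 individuals = 448 gene copies per locus
  expect_equal(sum(table(d1$pop)) * 2L, 448L)
})

test_that("longer small-population epochs depress heterozygosity (AC)", {
  base <- list(N_Anc = 3e4, N_Cur = 500, N_shrink = 10, mu = 5e-4,
               p_gsm = 0.1)
  smp <- sample_config(40L, n_loci = 2L)
  set.seed(18)
  het_at <- function(T_shrink) {
    p <- c(base, list(T_shrink = T_shrink))
    mean(replicate(500,
      demabc:::sim_panel_stats("AC", p, smp)[["H_mean"]]))
  }
  h_short <- het_at(100)
  h_long <- het_at(1400)
  expect_gt(h_short, h_long)
})
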