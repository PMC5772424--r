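test_that("cross-validation separates separable models perfectly", {
  set.seed(71)
  stats <- cbind(s1 = c(rnorm(300, -5, 0.5), rnorm(300, 5, 0.5)),
                 s2 = rnorm(600))
  tab <- fake_table(stats, factor(rep(c("A", "B"), each = 300)))
  cv <- cross_validate_models(tab, n_pseudo_per_model = 40, tolerance = 0.1,
                              method = "rejection", seed = 1)
  expect_equal(sum(cv$confusion) - sum(diag(cv$confusion)), 0)
  expect_equal(unname(rowSums(cv$confusion)), c(40, 40))
  cvl <- cross_validate_models(tab, 40, 0.1, method = "logistic", seed = 1)
  expect_equal(sum(diag(cvl$confusion)), 80)
})

test_that("identically simulated models are classified at chance level", {
  set.seed(72)
  stats <- cbind(s1 = rnorm(1200), s2 = rnorm(1200))
  tab <- fake_table(stats, factor(rep(c("A", "B"), each = 600)))
  cv <- cross_validate_models(tab, 150, tolerance = 0.05,
                              method = "logistic", seed = 2)
  for (m in c("A", "B")) {
    prop <- cv$confusion[m, m] / 150
    se <- sqrt(0.5 * 0.5 / 150)
    expect_lt(abs(prop - 0.5), 3 * se)
  }
})

test_that("cross-validation is deterministic under a fixed seed", {
  set.seed(73)
  stats <- cbind(s1 = rnorm(200), s2 = rnorm(200))
  tab <- fake_table(stats, factor(rep(c("A", "B"), each = 100)))
  cv1 <- cross_validate_models(tab, 20, 0.2, method = "logistic", seed = 9)
  cv2 <- cross_validate_models(tab, 20, 0.2, method = "logistic", seed = 9)
  expect_identical(cv1$confusion, cv2$confusion)
  expect_error(cross_validate_models(tab, 500, 0.2, seed = 9), "exceeds")
})

test_that("zero-diversity proportion hits its analytic limits", {
  draws0 <- data.frame(N_Anc = 5000, N_Cur = 400, T_shrink = 1200,
                       N_shrink = 20, mu_seq = 0)
  z0 <- mtdna_zero_diversity("AC", draws0, n_sims = 50, seed = 3)
  expect_equal(z0$proportion, 1)
  # theta = G * mu_seq large: zero diversity almost never
  dl <- data.frame(N_Anc = 5e4, N_Cur = 4e4, T_shrink = 1200,
                   N_shrink = 45, mu_seq = 0.05)
  zl <- mtdna_zero_diversity("AC", dl, n_sims = 2000, seed = 4)
  expect_lt(zl$proportion, 0.01)
})

test_that("zero-diversity proportion decreases with the mtDNA rate", {
  grid <- c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1)
  base <- data.frame(N_Anc = 3e4, N_Cur = 485, T_shrink = 1220,
                     N_shrink = 28)
  props <- vapply(seq_along(grid), function(i) {
    draws <- cbind(base, mu_seq = grid[i])
    mtdna_zero_diversity("AC", draws, n_sims = 800, seed = 5)$proportion
  }, numeric(1))
  expect_true(all(diff(props) <= 0))
})

test_that("point priors are always covered; tolerance 1 without adjustment samples the prior", {
  spec <- const_spec(300, mu = 2e-4, p_gsm = 0, T_s = 50)
  smp <- sample_config(20L, n_loci = 3L)
  rec <- suppressWarnings( # point priors make several statistics constant
    recover_parameters(spec, n_trials = 6, sims_per_table = 60,
                       tolerance = 1, sample = smp, seed = 6,
                       method = "rejection"))
  cov <- rec$coverage
  expect_true(all(cov$coverage[cov$parameter %in%
                                 c("N_Anc", "N_Cur", "T_shrink")] == 1))
})

test_that("recent-founder scenarios carry fewer alleles than ancient growth", {
  # matched current sizes; the recent introduction keeps the bottleneck
  # signature in allelic richness
  smp <- sample_config(rep(56L, 4), n_loci = 6L)
  set.seed(74)
  n <- 500
  k_ri <- k_ac <- numeric(n)
  for (i in seq_len(n)) {
    mu <- 10^runif(1, -4, -3)
    ri <- list(N_Anc = 2000, N_Cur = 500, T_shrink = runif(1, 20, 70),
               N_shrink = runif(1, 2, 10), mu = mu, p_gsm = 0.1)
    ac <- list(N_Anc = 2000, N_Cur = 500, T_shrink = runif(1, 1000, 1500),
               N_shrink = runif(1, 4, 50), mu = mu, p_gsm = 0.1)
    k_ri[i] <- demabc:::sim_panel_stats("RI", ri, smp)[["K_mean"]]
    k_ac[i] <- demabc:::sim_panel_stats("AC", ac, smp)[["K_mean"]]
  }
  expect_lt(mean(k_ri), mean(k_ac))
})
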