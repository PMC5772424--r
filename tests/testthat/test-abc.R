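test_that("MAD standardization and Euclidean distance behave as specified", {
  set.seed(31)
  stats <- cbind(s1 = rnorm(50), s2 = runif(50))
  obs <- c(s1 = unname(stats[7, 1]), s2 = unname(stats[7, 2]))
  sd_ <- standardize_and_distance(stats, obs)
  expect_equal(sd_$distance[7], 0)
  # symmetry with a single statistic
  sym <- standardize_and_distance(cbind(s1 = c(1, 3)), c(s1 = 2))
  expect_equal(sym$distance[1], sym$distance[2])
  # MAD scaling makes distances invariant to a common rescaling
  stats10 <- stats
  stats10[, 1] <- stats10[, 1] * 10
  obs10 <- obs
  obs10["s1"] <- obs10["s1"] * 10
  expect_equal(standardize_and_distance(stats10, obs10)$distance,
               sd_$distance, tolerance = 1e-12)
  expect_error(standardize_and_distance(stats, c(s1 = 1, bogus = 2)),
               "bogus")
  expect_warning(
    standardize_and_distance(cbind(s1 = rnorm(20), s2 = rep(1, 20)),
                             c(s1 = 0, s2 = 1)), "MAD")
})

test_that("rejection retains exactly ceil(tolerance * N) closest rows", {
  tab <- fake_table(cbind(s1 = c(1.1, 1.2, 1.3, 1.4, 1.5)),
                    model = factor(rep("A", 5)))
  r <- abc_reject(tab, c(s1 = 1), tolerance = 0.4)
  expect_equal(sort(r$index), c(1L, 2L))
  expect_equal(length(abc_reject(tab, c(s1 = 1), 1)$index), 5L)
  expect_error(abc_reject(tab, c(s1 = 1), 0), "tolerance")
  set.seed(32)
  big <- fake_table(cbind(s1 = rnorm(10000)), factor(rep("A", 10000)))
  expect_equal(length(abc_reject(big, c(s1 = 0), 0.01)$index), 100L)
  # distances sorted non-decreasing
  expect_true(all(diff(abc_reject(big, c(s1 = 0), 0.05)$distance) >= 0))
})

test_that("rejection model probabilities are retained-label proportions", {
  tab <- suppressWarnings(
    fake_table(cbind(s1 = c(0.1, 0.2, 0.3, 0.4, 9, 9, 9, 9)),
               model = factor(c("A", "A", "A", "B", "B", "B", "B", "B"),
                              levels = c("A", "B", "C"))))
  p <- model_posterior_rejection(abc_reject(tab, c(s1 = 0), 0.5))
  expect_equal(unname(p), c(0.75, 0.25, 0))
  expect_equal(sum(p), 1)
  # oracle equivalence on random retained sets
  set.seed(33)
  for (rep in 1:20) {
    lab <- factor(sample(c("A", "B", "C"), 40, replace = TRUE))
    tab <- fake_table(cbind(s1 = rnorm(40)), lab)
    r <- abc_reject(tab, c(s1 = 0), 0.5)
    p <- model_posterior_rejection(r)
    counts <- vapply(levels(lab), function(m) sum(r$model == m), numeric(1))
    expect_equal(unname(p), unname(counts / sum(counts)))
  }
})

test_that("logistic model choice separates separable models and not exchangeable ones", {
  set.seed(34)
  stats <- cbind(s1 = c(rnorm(1000, -1, 0.3), rnorm(1000, 1, 0.3)))
  tab <- fake_table(stats, factor(rep(c("A", "B"), each = 1000)))
  p <- model_posterior_logistic(tab, c(s1 = -2), tolerance = 0.5)
  expect_gt(p[["A"]], 0.99)
  expect_equal(sum(p), 1, tolerance = 1e-9)

  # same generating distribution: probabilities hover around 1/2
  ps <- replicate(30, {
    stats <- cbind(s1 = rnorm(600), s2 = rnorm(600))
    tab <- fake_table(stats, factor(rep(c("A", "B"), each = 300)))
    model_posterior_logistic(tab, c(s1 = 0, s2 = 0), 0.2)[["A"]]
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)

  one <- fake_table(cbind(s1 = rnorm(50)), factor(rep("A", 50)))
  expect_equal(model_posterior_logistic(one, c(s1 = 0), 0.5)[["A"]], 1)
})

test_that("Bayes factors are probability ratios with Inf sentinels", {
  p <- c(A = 0.9, B = 0.1)
  bf <- bayes_factors(p)
  expect_equal(bf["A", "B"], 9)
  expect_equal(bayes_factors(c(A = 0.5, B = 0.5))["A", "B"], 1)
  set.seed(35)
  q <- runif(4)
  q <- q / sum(q)
  names(q) <- letters[1:4]
  bf <- bayes_factors(q)
  expect_equal(bf * t(bf), matrix(1, 4, 4, dimnames = dimnames(bf)))
  expect_equal(unname(bayes_factors(c(A = 1, B = 0))["A", "B"]), Inf)
  expect_error(bayes_factors(c(0.5, 0.4)), "sum to 1")
})

test_that("marginal-density p-value ranks typical and outlier observations", {
  set.seed(36)
  stats <- cbind(s1 = rnorm(1000), s2 = rnorm(1000))
  tab <- fake_table(stats, factor(rep("A", 1000)))
  at_mode <- abc_reject(tab, c(s1 = 0, s2 = 0), 1)
  expect_gt(marginal_density_pvalue(at_mode), 0.8)
  far <- abc_reject(tab, c(s1 = 30, s2 = 0), 1)
  expect_lt(marginal_density_pvalue(far), 0.01)
  set.seed(37)
  for (rep in 1:5) {
    r <- abc_reject(tab, c(s1 = rnorm(1), s2 = rnorm(1)), 0.5)
    p <- marginal_density_pvalue(r)
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

make_linear_table <- function(n, noise_sd, seed) {
  set.seed(seed)
  theta <- runif(n, 10, 20)
  s1 <- theta + rnorm(n, 0, noise_sd)
  s2 <- rnorm(n)
  reference_table(model = factor(rep("ID", n)),
                  params = data.frame(
                    N_Anc = rep(500, n), N_Cur = rep(500, n),
                    T_shrink = theta, mu = rep(1e-4, n),
                    p_gsm = rep(0, n)),
                  stats = cbind(s1 = s1, s2 = s2))
}

linear_spec <- model_spec("ID", list(
  N_Anc = prior_spec("uniform", 500, 500),
  N_Cur = prior_spec("uniform", 500, 500),
  T_shrink = prior_spec("uniform", 10, 20),
  mu = prior_spec("uniform", 1e-4, 1e-4),
  p_gsm = prior_spec("uniform", 0, 0)))

test_that("local-linear adjustment collapses onto a noise-free linear truth", {
  tab <- make_linear_table(2000, noise_sd = 0, seed = 38)
  retained <- abc_reject(tab, c(s1 = 15, s2 = 0), 0.5)
  post <- loclinear_adjust(retained, linear_spec, hcorr = FALSE)
  prior_var <- stats::var(tab$params$T_shrink)
  expect_lt(stats::var(post$sample$T_shrink), 1e-10 * prior_var)
  expect_equal(mean(post$sample$T_shrink), 15, tolerance = 1e-6)
  # heteroscedasticity-corrected version collapses too
  post2 <- loclinear_adjust(retained, linear_spec, hcorr = TRUE)
  expect_lt(stats::var(post2$sample$T_shrink), 1e-8 * prior_var)
})

test_that("adjustment leaves signal-free parameters distributionally alone", {
  set.seed(39)
  n <- 3000
  theta <- runif(n, 10, 20) # independent of every statistic
  tab <- reference_table(model = factor(rep("ID", n)),
                         params = data.frame(
                           N_Anc = rep(500, n), N_Cur = rep(500, n),
                           T_shrink = theta, mu = rep(1e-4, n),
                           p_gsm = rep(0, n)),
                         stats = cbind(s1 = rnorm(n), s2 = rnorm(n)))
  retained <- abc_reject(tab, c(s1 = 0, s2 = 0), 0.4)
  post <- loclinear_adjust(retained, linear_spec)
  ks <- suppressWarnings(
    stats::ks.test(post$sample$T_shrink,
                   tab$params$T_shrink[retained$index]))
  expect_lt(unname(ks$statistic), ks_crit(length(retained$index), 0.01))
  # constant parameters come back unchanged
  expect_equal(unique(round(post$sample$N_Cur, 9)), 500)
})

test_that("posterior summaries match closed forms", {
  eq <- list(sample = data.frame(x = c(1, 2, 3)), weights = rep(1 / 3, 3))
  sm <- posterior_summaries(eq)
  expect_equal(sm$mean, 2)
  expect_equal(sm$median, 2)
  set.seed(40)
  z <- list(sample = data.frame(x = rnorm(1e5)), weights = rep(1e-5, 1e5))
  sm <- posterior_summaries(z)
  expect_lt(abs(sm$hpd_lower - (-1.96)), 0.05)
  expect_lt(abs(sm$hpd_upper - 1.96), 0.05)
  expect_lt(abs(sm$mode), 0.08)
  pt <- list(sample = data.frame(x = rep(7, 50)), weights = rep(0.02, 50))
  sm <- posterior_summaries(pt)
  expect_true(all(abs(unlist(sm[-1]) - 7) < 1e-9))
  expect_equal(sm$hpd_upper - sm$hpd_lower, 0)
})
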