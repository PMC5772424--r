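ac_example <- list(N_Anc = 33000, N_Cur = 485, T_shrink = 1220,
                   N_shrink = 28)

test_that("AC builds an exponential founder-growth trajectory", {
  d <- build_demography("AC", ac_example)
  expect_equal(deme_size(d, 0), 485)
  expect_equal(deme_size(d, 1500), 33000)
  expect_equal(deme_size(d, 1219.9999), 28, tolerance = 1e-4)
  # exponential interpolation: geometric mean halfway
  expect_equal(deme_size(d, 610), sqrt(485 * 28), tolerance = 1e-8)
})

test_that("ID with equal sizes is a constant demography", {
  d <- build_demography("ID", list(N_Anc = 700, N_Cur = 700, T_shrink = 100))
  expect_equal(deme_size(d, c(0, 50, 99.9, 100, 1e6)), rep(700, 5))
})

test_that("fragmented models have 4 demes summing to the pooled trajectory", {
  p <- c(ac_example, list(T_split = 100))
  d <- build_demography("ACS", p)
  expect_equal(d$n_demes, 4L)
  for (t in c(0, 50, 99.9)) {
    sizes <- vapply(1:4, function(k) deme_size(d, t, k), numeric(1))
    expect_equal(sum(sizes), deme_size(build_demography("AC", ac_example), t),
                 tolerance = 1e-9)
  }
  # beyond the split a single deme carries the full trajectory
  expect_equal(deme_size(d, 100, 1),
               deme_size(build_demography("AC", ac_example), 100),
               tolerance = 1e-9)
  expect_true(is.na(deme_size(d, 150, 2)))
  expect_equal(nrow(d$merges), 3L)
})

test_that("AC and RI share the demography shape; priors are the difference", {
  a <- build_demography("AC", ac_example)
  r <- build_demography("RI", ac_example)
  expect_equal(a$segments, r$segments)
  expect_equal(a$events$time, r$events$time)
})

test_that("every model collapses to a constant ancestral population", {
  params <- list(
    ID = list(N_Anc = 2e4, N_Cur = 500, T_shrink = 800),
    ED = list(N_Anc = 2e4, N_Cur = 500, T_shrink = 800),
    AC = c(ac_example),
    RI = list(N_Anc = 3000, N_Cur = 500, T_shrink = 50, N_shrink = 10),
    TI = list(N_Anc = 2e4, N_Sulu = 1500, N_Cur = 500, T_shrink = 45,
              N_shrink = 8, T_first = 60, N_shrink1 = 5),
    ACS = c(ac_example, list(T_split = 300)),
    RIS = list(N_Anc = 3000, N_Cur = 500, T_shrink = 50, N_shrink = 10,
               T_split = 20))
  expected_events <- c(ID = 1L, ED = 1L, AC = 1L, RI = 1L, TI = 2L,
                       ACS = 2L, RIS = 2L)
  for (m in names(params)) {
    d <- build_demography(m, params[[m]])
    oldest <- max(d$events$time)
    expect_equal(deme_size(d, oldest * 1000), params[[m]]$N_Anc,
                 info = m)
    expect_equal(nrow(d$events), expected_events[[m]], info = m)
    expect_true(all(diff(d$events$time) >= 0), info = m)
    # N(t) >= 1 along a time grid
    grid <- seq(0, oldest * 2, length.out = 64)
    expect_true(all(deme_size(d, grid) >= 1, na.rm = TRUE), info = m)
  }
})

test_that("invalid structures are rejected", {
  expect_error(build_demography("XX", ac_example))
  expect_error(build_demography("ACS", c(ac_example, list(T_split = 2000))),
               "T_split")
  expect_error(build_demography("TI",
    list(N_Anc = 2e4, N_Sulu = 1500, N_Cur = 500, T_shrink = 65,
         N_shrink = 8, T_first = 50, N_shrink1 = 5)), "T_first")
  expect_error(build_demography("AC", list(N_Anc = 33000, N_Cur = 485)),
               "missing parameter")
  expect_error(build_demography("AC", c(ac_example[-4], list(N_shrink = 0.5))),
               "sizes")
})
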