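# Independent brute-force oracles used to cross-check the package's
# statistics and ABC machinery.  Deliberately naive (explicit loops, no
# shared code with the implementation).

# Nei's unbiased expected heterozygosity from a vector of allele copies
naive_het <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  p <- as.numeric(table(alleles)) / n
  (n / (n - 1)) * (1 - sum(p^2))
}

naive_khrm <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  if (!length(alleles)) return(c(K = NA, H = NA, R = NA, M = NA))
  K <- length(unique(alleles))
  R <- max(alleles) - min(alleles)
  c(K = K, H = naive_het(alleles), R = R, M = K / (R + 1))
}

# One-way ANOVA F_ST on allele indicator variables, ratio of sums across
# loci and alleles; copies is a (gene copies x loci) matrix, group a vector
# of group indices per copy.
naive_fst <- function(copies, group, which_groups = sort(unique(group))) {
  num <- 0; den <- 0
  for (l in seq_len(ncol(copies))) {
    a <- copies[, l]
    keep <- !is.na(a) & group %in% which_groups
    a <- a[keep]; g <- group[keep]
    sizes <- table(g)
    sizes <- sizes[sizes > 0]
    r <- length(sizes)
    if (r < 2) next
    N <- sum(sizes)
    if (N <= r) next
    n_c <- (N - sum(sizes^2) / N) / (r - 1)
    for (al in unique(a)) {
      ybar <- mean(a == al)
      ssa <- 0; ssw <- 0
      for (gg in names(sizes)) {
        y <- (a == al)[g == gg]
        ssa <- ssa + length(y) * (mean(y) - ybar)^2
        ssw <- ssw + sum((y - mean(y))^2)
      }
      msa <- ssa / (r - 1)
      msw <- ssw / (N - r)
      s2a <- (msa - msw) / n_c
      num <- num + s2a
      den <- den + s2a + msw
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# full naive replica of the microsat_sumstats vector for grouped data
naive_microsat_sumstats <- function(data) {
  fl <- demabc:::genotype_copies(data)
  copies <- fl$copies; group <- fl$group
  r <- nlevels(data$pop)
  L <- ncol(copies)
  per_locus <- t(vapply(seq_len(L), function(l) naive_khrm(copies[, l]),
                        numeric(4)))
  sdn <- function(x) stats::sd(x[!is.na(x)])
  mn <- function(x) mean(x, na.rm = TRUE)
  out <- c(K_mean = mn(per_locus[, 1]), K_sd = sdn(per_locus[, 1]),
           H_mean = mn(per_locus[, 2]), H_sd = sdn(per_locus[, 2]),
           R_mean = mn(per_locus[, 3]), R_sd = sdn(per_locus[, 3]),
           M_mean = mn(per_locus[, 4]), M_sd = sdn(per_locus[, 4]))
  if (r > 1) {
    for (g in seq_len(r)) {
      pg <- t(vapply(seq_len(L), function(l)
        naive_khrm(copies[group == g, l]), numeric(4)))
      v <- c(mn(pg[, 1]), mn(pg[, 2]), mn(pg[, 3]), mn(pg[, 4]))
      names(v) <- paste(c("K_mean", "H_mean", "R_mean", "M_mean"),
                        paste0("d", g), sep = "_")
      out <- c(out, v)
    }
    out <- c(out, fst_global = naive_fst(copies, group))
    for (pr in utils::combn(r, 2, simplify = FALSE)) {
      v <- naive_fst(copies, group, pr)
      names(v) <- sprintf("fst_d%d_d%d", pr[1], pr[2])
      out <- c(out, v)
    }
  }
  out
}

# pairwise-difference mtDNA statistics by explicit double loop
naive_mtdna <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  diffs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diffs <- diffs + sum(m[i, ] != m[j, ])
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  H <- length(unique(seqs))
  c(H = H, S = S, pi = diffs / choose(n, 2))
}

# random small genotype dataset (optionally with missing data)
random_genotype_data <- function(n_ind, n_loci, n_pops, miss_rate = 0,
                                 n_alleles = 4) {
  g <- array(sample(100:(99 + n_alleles), n_ind * n_loci * 2, replace = TRUE),
             c(n_ind, n_loci, 2))
  if (miss_rate > 0) {
    drop <- runif(n_ind * n_loci) < miss_rate
    for (k in which(drop)) {
      i <- ((k - 1) %% n_ind) + 1
      l <- ((k - 1) %/% n_ind) + 1
      g[i, l, ] <- NA_integer_
    }
  }
  pop <- sort(rep_len(seq_len(n_pops), n_ind))
  genotype_data(g, pop = paste0("p", pop))
}

# P(S = k | theta) for a sample of n lineages (haploid scale: theta = 2*G*mu
# with G gene copies), by the standard alternating-sum formula
prob_S_given_theta <- function(k, n, theta) {
  i <- 2:n
  terms <- (-1)^i * choose(n - 1, i - 1) * ((i - 1) / (theta + i - 1)) *
    (theta / (theta + i - 1))^k
  sum(terms)
}

watterson_grid_posterior <- function(S_obs, n, theta_grid) {
  lik <- vapply(theta_grid, function(th) prob_S_given_theta(S_obs, n, th),
                numeric(1))
  w <- lik / sum(lik)
  list(theta = theta_grid, weight = w,
       mean = sum(w * theta_grid),
       sd = sqrt(sum(w * theta_grid^2) - sum(w * theta_grid)^2))
}

# constant-size single-deme model spec with point priors (test scaffolding)
const_spec <- function(N, mu = 0, p_gsm = 0, T_s = 5) {
  model_spec("ID", list(
    N_Anc = prior_spec("uniform", N, N),
    N_Cur = prior_spec("uniform", N, N),
    T_shrink = prior_spec("uniform", T_s, T_s),
    mu = prior_spec("uniform", mu, mu),
    p_gsm = prior_spec("uniform", p_gsm, p_gsm)))
}

const_demography <- function(N) {
  build_demography("ID", list(N_Anc = N, N_Cur = N, T_shrink = 5))
}

# KS critical value at level alpha (large-sample)
ks_crit <- function(n, alpha = 0.01) sqrt(-log(alpha / 2) / (2 * n))

# build a reference table directly from synthetic stats (ABC unit tests)
fake_table <- function(stats, model, params = NULL) {
  stats <- as.matrix(stats)
  if (is.null(colnames(stats)))
    colnames(stats) <- paste0("s", seq_len(ncol(stats)))
  if (is.null(params))
    params <- data.frame(theta = rep(NA_real_, nrow(stats)))
  reference_table(model = model, params = params, stats = stats)
}
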