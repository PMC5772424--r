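#' Microsatellite summary statistics
#'
#' Per-locus statistics averaged (mean and SD) across loci: number of
#' alleles `K`, Nei's unbiased expected heterozygosity
#' `H = n/(n-1) (1 - sum p_i^2)` with `n` the non-missing gene copies,
#' allelic size range `R`, and the Garza-Williamson ratio `M = K/(R+1)`
#' (depressed by bottlenecks).  With `grouping = "demes"` the vector
#' additionally carries per-deme means of K/H/R/M, their across-deme
#' averages, the multi-locus global F_ST and all pairwise F_ST values
#' (one-way variance-components estimator, ratio-of-sums across loci and
#' alleles; negative estimates are reported as computed).
#'
#' @param data a [genotype_data()].
#' @param grouping `"demes"` (use population labels) or `"pooled"`.
#' @return named numeric summary vector with attribute `"panel"`, the
#'   default subset used for ABC distances (pooled moments, across-deme
#'   averages, global and mean pairwise F_ST).
#' @export
microsat_sumstats <- function(data, grouping = c("demes", "pooled")) {
  stopifnot(inherits(data, "genotype_data"))
  grouping <- match.arg(grouping)
  fl <- genotype_copies(data)
  if (grouping == "pooled") {
    group <- rep(1L, nrow(fl$copies))
    r <- 1L
  } else {
    group <- fl$group
    r <- nlevels(data$pop)
  }
  # preconditions: every group needs >= 2 copies somewhere per locus
  for (g in seq_len(r)) {
    ng <- sum(group == g)
    if (ng == 0L)
      stop(sprintf("empty group '%s'", levels(data$pop)[g]))
    if (ng < 2L)
      stop(sprintf("group '%s' has fewer than 2 gene copies",
                   levels(data$pop)[g]))
  }
  raw <- rcpp_microsat_stats(fl$copies, group - 1L, r)
  nm <- c("K_mean", "K_sd", "H_mean", "H_sd", "R_mean", "R_sd",
          "M_mean", "M_sd")
  if (r > 1L) {
    dn <- paste0("d", seq_len(r))
    nm <- c(nm,
            as.vector(t(outer(dn, c("K_mean", "H_mean", "R_mean", "M_mean"),
                              function(a, b) paste(b, a, sep = "_")))),
            "fst_global",
            apply(utils::combn(r, 2), 2,
                  function(p) sprintf("fst_d%d_d%d", p[1], p[2])))
  }
  names(raw) <- nm
  out <- raw
  if (r > 1L) {
    for (s in c("K_mean", "H_mean", "R_mean", "M_mean"))
      out[paste0(s, "_deme_avg")] <-
        mean(raw[paste(s, paste0("d", seq_len(r)), sep = "_")])
    out["fst_pair_mean"] <- mean(raw[grep("^fst_d", names(raw))])
  }
  panel <- c("K_mean", "K_sd", "H_mean", "H_sd", "R_mean", "R_sd",
             "M_mean", "M_sd")
  if (r > 1L)
    panel <- c(panel, "K_mean_deme_avg", "H_mean_deme_avg",
               "R_mean_deme_avg", "M_mean_deme_avg", "fst_global",
               "fst_pair_mean")
  attr(out, "panel") <- panel
  out
}

# raw C++ stat vector -> named panel vector (must agree with
# microsat_sumstats() + stat_panel(); asserted in the test suite)
panel_from_raw <- function(raw, r) {
  pooled <- raw[1:8]
  names(pooled) <- c("K_mean", "K_sd", "H_mean", "H_sd", "R_mean", "R_sd",
                     "M_mean", "M_sd")
  if (r == 1L) return(pooled)
  per_group <- matrix(raw[8L + seq_len(4L * r)], nrow = 4L) # K,H,R,M x group
  deme_avg <- rowMeans(per_group)
  names(deme_avg) <- c("K_mean_deme_avg", "H_mean_deme_avg",
                       "R_mean_deme_avg", "M_mean_deme_avg")
  fst_global <- raw[8L + 4L * r + 1L]
  pair <- raw[(8L + 4L * r + 2L):length(raw)]
  c(pooled, deme_avg, fst_global = unname(fst_global),
    fst_pair_mean = mean(pair))
}

# simulate one microsatellite dataset and return its ABC panel directly
# (hot path: skips the genotype_data round trip)
sim_panel_stats <- function(model_id, p, sample) {
  core <- demography_core(model_id, p)
  ng <- length(sample$copies_per_group)
  group_deme <- if (core$n_demes == 1L) rep(0L, ng) else seq_len(ng) - 1L
  ld <- rep(group_deme, sample$copies_per_group)
  x <- rcpp_sim_microsat_matrix(core$segments, core$merges, ld, 2,
                                sample$n_loci, rep(p$mu, sample$n_loci),
                                p$p_gsm)
  raw <- rcpp_microsat_stats(x, rep(seq_len(ng) - 1L,
                                    sample$copies_per_group), ng)
  panel_from_raw(raw, ng)
}

#' Default ABC statistic panel
#'
#' Subsets a summary vector to the statistics used for ABC distances.
#' @param stats a vector from [microsat_sumstats()].
#' @return the panel sub-vector.
#' @export
stat_panel <- function(stats) {
  panel <- attr(stats, "panel")
  if (is.null(panel)) return(stats)
  out <- stats[panel]
  attributes(out)$panel <- NULL
  names(out) <- panel
  out
}

#' mtDNA summary statistics
#'
#' Number of distinct haplotypes `H`, segregating sites `S`, and the mean
#' number of pairwise differences `pi` over all unordered sequence pairs.
#'
#' @param data a [haplotype_data()].
#' @return named numeric vector `c(H, S, pi)`.
#' @export
mtdna_sumstats <- function(data) {
  stopifnot(inherits(data, "haplotype_data"))
  if (data$n < 2L) stop("mtDNA summary statistics need >= 2 sequences")
  if (!is.null(data$sites)) {
    cs <- colSums(data$sites)
    poly <- which(cs > 0L & cs < nrow(data$sites))
    m <- data$sites[, poly, drop = FALSE]
  } else {
    m <- hap_char_matrix(data)
    poly <- which(apply(m, 2, function(col) length(unique(col)) > 1L))
    m <- m[, poly, drop = FALSE]
  }
  n <- data$n
  S <- length(poly)
  H <- if (S == 0L) 1L else
    length(unique(apply(m, 1, paste, collapse = "\r")))
  if (S == 0L) {
    pi <- 0
  } else {
    # per-site pair differences: sum over alleles c_a * (n - c_a) / 2
    pi <- sum(apply(m, 2, function(col) {
      cnt <- table(col)
      (n^2 - sum(cnt^2)) / 2
    })) / choose(n, 2)
  }
  c(H = as.numeric(H), S = as.numeric(S), pi = pi)
}

#' Is an mtDNA sample monomorphic?
#'
#' `TRUE` iff the sample contains a single haplotype (equivalently `S = 0`
#' and `pi = 0`) — the "zero diversity" pattern.
#'
#' @param data a [haplotype_data()].
#' @return logical.
#' @export
is_zero_diversity <- function(data) {
  unname(mtdna_sumstats(data)["H"] == 1)
}
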