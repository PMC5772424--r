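#' Sampling configuration
#'
#' Describes the sample drawn from the present-day population(s): gene-copy
#' counts per sampling group, locus count, and ploidy.  For
#' `ploidy = "diploid"` copies are autosomal (a deme of `N` diploid
#' individuals holds `2N` copies and the coalescence rate with k lineages is
#' `k(k-1)/(4N)`); for `ploidy = "mito"` copies are maternally inherited
#' haploids and the deme size is rescaled by `female_scale` relative to the
#' autosomal copy number (default 0.25, i.e. `N/2` mtDNA copies).
#'
#' Sampling groups correspond to the four field localities; under an
#' unstructured scenario all groups live in the single deme, under ACS/RIS
#' group i is sampled from deme i.
#'
#' @param copies_per_group integer vector of gene copies per group.
#' @param n_loci number of independent loci.
#' @param ploidy `"diploid"` or `"mito"`.
#' @param female_scale mtDNA effective copy number relative to `2N`.
#' @return an object of class `"sample_config"`.
#' @export
sample_config <- function(copies_per_group, n_loci = 1L,
                          ploidy = c("diploid", "mito"),
                          female_scale = 0.25) {
  ploidy <- match.arg(ploidy)
  copies_per_group <- as.integer(copies_per_group)
  if (any(copies_per_group < 1L)) stop("all group sample counts must be >= 1")
  if (ploidy == "diploid" && any(copies_per_group %% 2L != 0L))
    stop("diploid sampling requires an even number of gene copies per group")
  stopifnot(n_loci >= 1L, female_scale > 0)
  structure(list(copies_per_group = copies_per_group,
                 n_loci = as.integer(n_loci), ploidy = ploidy,
                 female_scale = female_scale),
            class = "sample_config")
}

copy_scale <- function(sample) {
  if (sample$ploidy == "diploid") 2 else 2 * sample$female_scale
}

# map sampling groups onto demes and build the per-leaf deme vector (0-based)
leaf_demes <- function(demog, sample) {
  ng <- length(sample$copies_per_group)
  if (demog$n_demes == 1L) {
    group_deme <- rep(0L, ng)
  } else {
    if (ng != demog$n_demes)
      stop(sprintf("demography has %d demes but sample has %d groups",
                   demog$n_demes, ng))
    group_deme <- seq_len(ng) - 1L
  }
  rep(group_deme, sample$copies_per_group)
}

demog_matrices <- function(demog) {
  list(segments = as.matrix(demog$segments[c("deme", "t0", "t1", "N0", "g")]),
       merges = as.matrix(demog$merges[c("time", "from", "to")]))
}

#' Simulate a coalescent genealogy
#'
#' Continuous-time coalescent under a piecewise-exponential demography,
#' possibly structured until demes merge.  Waiting times within
#' exponential-size epochs use closed-form time rescaling.
#'
#' @param demog a [build_demography()] result.
#' @param sample a [sample_config()] (its `n_loci` is ignored here).
#' @return an object of class `"genealogy"`: leaves `1..n`, internal nodes
#'   `n+1..2n-1` in coalescence order (root last), `parent` (`NA` at the
#'   root) and `time` in generations.
#' @export
simulate_genealogy <- function(demog, sample) {
  stopifnot(inherits(demog, "demography"), inherits(sample, "sample_config"))
  ld <- leaf_demes(demog, sample)
  m <- demog_matrices(demog)
  res <- rcpp_sim_genealogy(m$segments, m$merges, ld, copy_scale(sample))
  parent <- res$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(list(parent = parent, time = res$time, n = res$n,
                 leaf_group = rep(seq_along(sample$copies_per_group),
                                  sample$copies_per_group)),
            class = "genealogy")
}

#' Total branch length of a genealogy
#' @param tree a `"genealogy"`.
#' @return sum of branch lengths in generations.
#' @export
total_branch_length <- function(tree) {
  ok <- !is.na(tree$parent)
  sum(tree$time[tree$parent[ok]] - tree$time[ok])
}

#' Time to the most recent common ancestor
#' @param tree a `"genealogy"`.
#' @return root time in generations (0 for a single-lineage sample).
#' @export
tmrca <- function(tree) max(tree$time)

#' Mutation configuration
#'
#' @param mu mutation rate per generation: per locus for microsatellites,
#'   per sequence for mtDNA.
#' @param p_gsm multistep proportion of the generalized stepwise model;
#'   mutation step magnitudes are geometric, `P(k) = (1-p) p^(k-1)`, so
#'   `p_gsm = 0` is the strict stepwise model.
#' @param seq_length sequence length in bp (bookkeeping for FASTA output
#'   only; mutation placement is infinite-sites).
#' @return an object of class `"mutation_config"`.
#' @export
mutation_config <- function(mu, p_gsm = 0, seq_length = 630L) {
  stopifnot(mu >= 0, p_gsm >= 0, p_gsm < 1, seq_length >= 1)
  structure(list(mu = mu, p_gsm = p_gsm, seq_length = as.integer(seq_length)),
            class = "mutation_config")
}

#' Superimpose generalized stepwise mutations on a genealogy
#'
#' Mutation counts per branch are Poisson(`mu` x branch length); each
#' mutation changes the repeat number by a geometric magnitude with
#' equiprobable sign.  No allele-range constraint is applied.
#'
#' @param tree a `"genealogy"`.
#' @param cfg a [mutation_config()].
#' @return integer vector of tip allele sizes as offsets from the ancestral
#'   repeat number (ancestral = 0).
#' @export
mutate_microsat <- function(tree, cfg) {
  stopifnot(inherits(tree, "genealogy"), inherits(cfg, "mutation_config"))
  parent0 <- tree$parent - 1L
  parent0[is.na(parent0)] <- -1L
  rcpp_mutate_microsat(parent0, tree$time, tree$n, cfg$mu, cfg$p_gsm)
}

#' Superimpose infinite-sites mutations on a genealogy
#'
#' @param tree a `"genealogy"`.
#' @param cfg a [mutation_config()]; `cfg$mu` is the per-sequence rate.
#' @return binary matrix (tips x segregating sites) of derived alleles.
#' @export
mutate_sequence <- function(tree, cfg) {
  stopifnot(inherits(tree, "genealogy"), inherits(cfg, "mutation_config"))
  parent0 <- tree$parent - 1L
  parent0[is.na(parent0)] <- -1L
  rcpp_mutate_sites(parent0, tree$time, tree$n, cfg$mu)
}

#' Simulate a complete dataset under a demographic scenario
#'
#' One independent genealogy per locus.  For diploid microsatellite data the
#' two gene copies of each individual are consecutive rows of the simulated
#' copies, paired into genotypes; every locus shares the drawn mean mutation
#' rate `mu`.  For mtDNA a single haploid locus is simulated under the
#' infinite-sites model with per-sequence rate `mu_seq`.
#'
#' @param model_id scenario identifier.
#' @param params named parameter draw (needs `mu` and `p_gsm` for
#'   microsatellites, `mu_seq` for mtDNA).
#' @param sample a [sample_config()].
#' @param seed optional integer seed (applied with [set.seed()]).
#' @param locus_rate_shape optional gamma shape for per-locus rate scatter
#'   around the mean `mu` (mean-preserving; `NULL`, the default, gives
#'   every locus the drawn mean rate).
#' @return a `"genotype_data"` (diploid) or `"haplotype_data"` (mito)
#'   object.
#' @export
simulate_dataset <- function(model_id, params, sample, seed = NULL,
                             locus_rate_shape = NULL) {
  stopifnot(inherits(sample, "sample_config"))
  if (!is.null(seed)) set.seed(seed)
  p <- as.list(params)
  demog <- build_demography(model_id, p)
  ld <- leaf_demes(demog, sample)
  m <- demog_matrices(demog)
  if (sample$ploidy == "diploid") {
    if (is.null(p$mu) || is.null(p$p_gsm))
      stop("microsatellite simulation needs 'mu' and 'p_gsm'")
    rates <- if (is.null(locus_rate_shape)) rep(p$mu, sample$n_loci)
      else p$mu * stats::rgamma(sample$n_loci, shape = locus_rate_shape,
                                rate = locus_rate_shape)
    copies <- rcpp_sim_microsat_matrix(m$segments, m$merges, ld,
                                       copy_scale(sample), sample$n_loci,
                                       rates, p$p_gsm)
    genotype_data_from_copies(copies,
                              rep(seq_along(sample$copies_per_group),
                                  sample$copies_per_group))
  } else {
    if (is.null(p$mu_seq)) stop("mtDNA simulation needs 'mu_seq'")
    tree <- simulate_genealogy(demog, sample)
    sites <- mutate_sequence(tree, mutation_config(p$mu_seq))
    haplotype_data(sites = sites,
                   group = rep(seq_along(sample$copies_per_group),
                               sample$copies_per_group))
  }
}
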