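#' Shape of a pseudo-observed dataset
#'
#' Defaults emulate the motivating dataset: 224 genotyped individuals over
#' four Sabah localities, 18 microsatellite loci, and 630 bp of mtDNA
#' sequence from a 60-individual subset.  The true per-locality sample
#' sizes are not published, so the default split is equal.
#'
#' @param ind_per_deme individuals per deme.
#' @param n_loci microsatellite locus count.
#' @param mtdna_n mtDNA sample size.
#' @param seq_length mtDNA alignment length (bp).
#' @param deme_names locality names.
#' @return an object of class `"dataset_shape"`.
#' @export
dataset_shape <- function(ind_per_deme = c(56L, 56L, 56L, 56L),
                          n_loci = 18L, mtdna_n = 60L, seq_length = 630L,
                          deme_names = c("Lower Kinabatangan",
                                         "North Kinabatangan",
                                         "Central Forest", "Tabin")) {
  stopifnot(all(ind_per_deme >= 1L), n_loci >= 1L, mtdna_n >= 2L,
            seq_length >= 1L,
            length(deme_names) == length(ind_per_deme),
            mtdna_n <= sum(ind_per_deme))
  structure(list(ind_per_deme = as.integer(ind_per_deme),
                 n_loci = as.integer(n_loci), mtdna_n = as.integer(mtdna_n),
                 seq_length = as.integer(seq_length),
                 deme_names = deme_names),
            class = "dataset_shape")
}

shape_sample_config <- function(shape, ploidy = "diploid",
                                female_scale = 0.25) {
  if (ploidy == "diploid")
    sample_config(2L * shape$ind_per_deme, n_loci = shape$n_loci,
                  ploidy = "diploid")
  else stop("use generate_observed_like() for the mtDNA subsample")
}

#' Generate a pseudo-observed dataset with the motivating data's shape
#'
#' Simulates a full microsatellite + mtDNA dataset under one scenario,
#' optionally writes Genepop and FASTA files plus a truth sidecar (model,
#' parameters, seed, shape) sufficient to re-simulate the identical data.
#' The mtDNA individuals are a random subset of the genotyped ones, so the
#' mtDNA per-deme counts follow the subsample.  Microsatellite allele
#' offsets are shifted by +100 repeat units for 3-digit Genepop codes.
#'
#' @param model_id scenario identifier.
#' @param params named parameter vector; `NULL` draws from `spec`'s priors.
#'   Needs `mu`, `p_gsm` and `mu_seq` (a missing `mu_seq` is drawn
#'   log-uniformly from 1e-7..1e-5 per site and scaled to the sequence
#'   length).
#' @param shape a [dataset_shape()].
#' @param seed integer seed (required; the truth sidecar records it).
#' @param dir optional output directory; when given, writes
#'   `genotypes.genepop.txt`, `mtdna.fasta` and `truth.json`.
#' @param spec a [model_spec()] used when `params` is `NULL`.
#' @param female_scale mtDNA copy-number scale.
#' @return list with `genotypes` ([genotype_data()]), `mtdna`
#'   ([haplotype_data()] sequences), `truth`, and `files` (if written).
#' @export
generate_observed_like <- function(model_id, params = NULL,
                                   shape = dataset_shape(), seed,
                                   dir = NULL, spec = NULL,
                                   female_scale = 0.25) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  set.seed(seed)
  if (is.null(params)) {
    if (is.null(spec)) spec <- default_model_specs(model_id)[[1]]
    params <- as.list(draw_params(spec, 1L))
  } else params <- as.list(params)
  if (is.null(params$mu_seq))
    params$mu_seq <- 10^stats::runif(1, -7, -5) * shape$seq_length
  smp <- shape_sample_config(shape)
  geno <- simulate_dataset(model_id, params, smp)
  levels(geno$pop) <- shape$deme_names
  geno$genotypes <- geno$genotypes + 100L
  # mtDNA subsample of the genotyped individuals
  chosen <- sort(sample.int(sum(shape$ind_per_deme), shape$mtdna_n))
  per_deme <- tabulate(as.integer(geno$pop)[chosen],
                       nbins = length(shape$ind_per_deme))
  keep <- per_deme > 0L
  mt_smp <- sample_config(per_deme[keep], ploidy = "mito",
                          female_scale = female_scale)
  demog <- build_demography(model_id, params)
  if (demog$n_demes > 1L && sum(keep) != demog$n_demes)
    stop("mtDNA subsample left a deme empty; increase mtdna_n")
  tree <- simulate_genealogy(demog, mt_smp)
  sites <- mutate_sequence(tree, mutation_config(params$mu_seq,
                                                 seq_length = shape$seq_length))
  hap <- haplotype_data(sites = sites, group = tree$leaf_group,
                        seq_length = shape$seq_length)
  mt <- haplotypes_to_sequences(hap, names = geno$ind[chosen])
  truth <- list(model = model_id, params = params, seed = seed,
                shape = unclass(shape), female_scale = female_scale)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(genepop = file.path(dir, "genotypes.genepop.txt"),
                  fasta = file.path(dir, "mtdna.fasta"),
                  truth = file.path(dir, "truth.json"))
    write_genepop(geno, files$genepop,
                  title = sprintf("simulated %s dataset (seed %d)",
                                  model_id, seed))
    write_fasta(mt, files$fasta)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  list(genotypes = geno, mtdna = mt, truth = truth, files = files)
}

#' Build a suite of tiny plain-text fixtures for unit testing
#'
#' Writes small datasets (at most 10 individuals, 3 loci) covering the edge
#' cases the statistics modules must handle — a monomorphic locus, missing
#' genotypes, a single-deme sample — plus a manifest with md5 checksums.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return the manifest as a data.frame (also written to `manifest.json`).
#' @export
make_fixture_suite <- function(dir, seed) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  # two-deme fixture with a monomorphic locus and some missing genotypes
  g <- array(NA_integer_, c(6L, 3L, 2L))
  g[, 1, 1] <- c(101L, 102L, 101L, 103L, 102L, 101L)
  g[, 1, 2] <- c(102L, 102L, 103L, 103L, 101L, 101L)
  g[, 2, 1] <- rep(150L, 6L) # monomorphic
  g[, 2, 2] <- rep(150L, 6L)
  g[, 3, 1] <- c(200L, 202L, NA, 204L, 202L, 200L)
  g[, 3, 2] <- c(202L, 204L, NA, 204L, 200L, 202L)
  two <- genotype_data(g, pop = rep(c("a", "b"), each = 3L),
                       loci = c("locA", "locB", "locC"))
  f <- file.path(dir, "two_deme.genepop.txt")
  write_genepop(two, f, title = "fixture: two demes, monomorphic + missing")
  files <- c(files, f)
  # single-deme fixture
  one <- genotype_data(g[1:4, , , drop = FALSE], pop = rep("a", 4L),
                       loci = c("locA", "locB", "locC"))
  f <- file.path(dir, "one_deme.genepop.txt")
  write_genepop(one, f, title = "fixture: single deme")
  files <- c(files, f)
  # small mtDNA alignment with two haplotypes
  seqs <- c(rep("ACGTACGTAC", 4L), rep("ACGTACGTAT", 2L))
  names(seqs) <- sprintf("seq_%02d", 1:6)
  f <- file.path(dir, "mtdna_small.fasta")
  write_fasta(haplotype_data(seqs = seqs), f)
  files <- c(files, f)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       pretty = TRUE)
  manifest
}
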