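#' Diploid microsatellite dataset
#'
#' @param genotypes integer array `c(n_ind, n_loci, 2)` of allele sizes
#'   (repeat units or arbitrary integer codes); `NA` = missing.
#' @param pop factor (or character) of deme/population labels per
#'   individual.
#' @param loci optional locus names.
#' @param ind optional individual names.
#' @return an object of class `"genotype_data"`.
#' @export
genotype_data <- function(genotypes, pop, loci = NULL, ind = NULL) {
  stopifnot(is.array(genotypes), length(dim(genotypes)) == 3L,
            dim(genotypes)[3] == 2L)
  n <- dim(genotypes)[1]
  L <- dim(genotypes)[2]
  if (length(pop) != n) stop("'pop' must have one label per individual")
  pop <- as.factor(pop)
  if (is.null(loci)) loci <- sprintf("locus_%02d", seq_len(L))
  if (is.null(ind)) ind <- sprintf("ind_%04d", seq_len(n))
  storage.mode(genotypes) <- "integer"
  structure(list(genotypes = genotypes, pop = pop, loci = loci, ind = ind),
            class = "genotype_data")
}

# build from a (2*n_ind x L) gene-copy matrix, copies of an individual in
# consecutive rows
genotype_data_from_copies <- function(copies, copy_group) {
  n2 <- nrow(copies)
  stopifnot(n2 %% 2L == 0L)
  n <- n2 %/% 2L
  L <- ncol(copies)
  g <- array(NA_integer_, c(n, L, 2L))
  g[, , 1L] <- copies[seq(1L, n2, by = 2L), , drop = FALSE]
  g[, , 2L] <- copies[seq(2L, n2, by = 2L), , drop = FALSE]
  pop <- copy_group[seq(1L, n2, by = 2L)]
  genotype_data(g, pop = paste0("pop_", pop))
}

# flatten to a gene-copy matrix plus per-copy group index
genotype_copies <- function(data) {
  n <- dim(data$genotypes)[1]
  L <- dim(data$genotypes)[2]
  copies <- matrix(NA_integer_, 2L * n, L)
  copies[seq(1L, 2L * n, by = 2L), ] <- data$genotypes[, , 1L]
  copies[seq(2L, 2L * n, by = 2L), ] <- data$genotypes[, , 2L]
  list(copies = copies, group = rep(as.integer(data$pop), each = 2L))
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d individuals x %d loci, %d population(s)\n",
              dim(x$genotypes)[1], dim(x$genotypes)[2], nlevels(x$pop)))
  print(table(x$pop))
  invisible(x)
}

#' Haploid mtDNA haplotype dataset
#'
#' Either aligned sequences (equal-length character strings) or a binary
#' derived-allele site matrix from an infinite-sites simulation.
#'
#' @param seqs character vector of aligned sequences (all the same length).
#' @param sites binary matrix (sequences x segregating sites).
#' @param group optional sampling-group index per sequence.
#' @param seq_length declared alignment length (for site matrices).
#' @return an object of class `"haplotype_data"`.
#' @export
haplotype_data <- function(seqs = NULL, sites = NULL, group = NULL,
                           seq_length = 630L) {
  if (is.null(seqs) == is.null(sites))
    stop("provide exactly one of 'seqs' or 'sites'")
  if (!is.null(seqs)) {
    seqs <- toupper(as.character(seqs))
    if (length(unique(nchar(seqs))) != 1L)
      stop("ragged alignment: sequences differ in length")
    n <- length(seqs)
    seq_length <- nchar(seqs[1])
  } else {
    stopifnot(is.matrix(sites))
    n <- nrow(sites)
  }
  if (is.null(group)) group <- rep(1L, n)
  structure(list(seqs = seqs, sites = sites, n = n, group = group,
                 seq_length = as.integer(seq_length)),
            class = "haplotype_data")
}

# site x sequence character matrix view (for sequence input)
hap_char_matrix <- function(data) {
  do.call(rbind, strsplit(data$seqs, ""))
}

#' @export
print.haplotype_data <- function(x, ...) {
  cat(sprintf("haplotype_data: %d sequences, alignment length %d (%s)\n",
              x$n, x$seq_length,
              if (is.null(x$sites)) "sequences" else
                sprintf("site matrix, S = %d", ncol(x$sites))))
  invisible(x)
}
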