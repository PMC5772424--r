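#' Read a Genepop file
#'
#' Supports the 2-digit and 3-digit diploid allele dialects (4 or 6 digits
#' per locus), locus names on separate lines or comma-separated on one
#' line, and `pop`/`Pop`/`POP` block separators.  Allele code 0 is treated
#' as missing.
#'
#' @param path file path.
#' @return a [genotype_data()] with populations `pop_1 ... pop_k`.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed Genepop file: too few lines")
  lines <- trimws(lines, which = "right")
  body <- lines[-1L] # first line is the title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("malformed Genepop file: no 'pop' line")
  locus_lines <- body[seq_len(first_pop - 1L)]
  loci <- unlist(strsplit(locus_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("malformed Genepop file: no locus names")
  L <- length(loci)
  pop_starts <- which(is_pop)
  pop_of_line <- findInterval(seq_along(body), pop_starts)
  inds <- list()
  pops <- integer(0)
  names_ind <- character(0)
  for (i in seq_along(body)) {
    if (i < first_pop || is_pop[i]) next
    line <- body[i]
    if (!nzchar(trimws(line))) next
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L)
      stop(sprintf("malformed Genepop line %d: missing ',' separator",
                   i + 1L))
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                     "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop(sprintf("malformed Genepop line %d: %d genotype field(s), expected %d",
                   i + 1L, length(toks), L))
    width <- unique(nchar(toks))
    if (length(width) != 1L || !width %in% c(4L, 6L))
      stop(sprintf("malformed Genepop line %d: genotype fields must be 4 or 6 digits",
                   i + 1L))
    half <- width %/% 2L
    a1 <- as.integer(substr(toks, 1L, half))
    a2 <- as.integer(substr(toks, half + 1L, width))
    if (anyNA(a1) || anyNA(a2))
      stop(sprintf("malformed Genepop line %d: non-numeric allele code",
                   i + 1L))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    inds[[length(inds) + 1L]] <- cbind(a1, a2)
    pops <- c(pops, pop_of_line[i])
    names_ind <- c(names_ind, id)
  }
  if (!length(inds)) stop("malformed Genepop file: no individuals")
  empty <- setdiff(seq_along(pop_starts), unique(pops))
  if (length(empty))
    stop(sprintf("empty pop block(s): %s",
                 paste(paste0("pop_", empty), collapse = ", ")))
  n <- length(inds)
  g <- array(NA_integer_, c(n, L, 2L))
  for (i in seq_len(n)) {
    g[i, , 1L] <- inds[[i]][, 1L]
    g[i, , 2L] <- inds[[i]][, 2L]
  }
  genotype_data(g, pop = paste0("pop_", pops), loci = loci, ind = names_ind)
}

#' Write a Genepop file
#'
#' Emits the 3-digit diploid dialect (6 digits per locus, `000000` for
#' missing), one locus name per line, individuals grouped into `pop` blocks
#' by their population label.
#'
#' @param data a [genotype_data()]; allele codes must lie in 1..999.
#' @param path output path.
#' @param title first (title) line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(data, path, title = "demabc simulated dataset") {
  stopifnot(inherits(data, "genotype_data"))
  g <- data$genotypes
  rng <- range(g, na.rm = TRUE)
  if (rng[1] < 1L || rng[2] > 999L)
    stop("allele codes must be in 1..999 for 3-digit Genepop output")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(data$loci, con)
  fmt <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a))
  for (p in levels(data$pop)) {
    writeLines("pop", con)
    for (i in which(data$pop == p)) {
      geno <- paste0(fmt(g[i, , 1L]), fmt(g[i, , 2L]))
      writeLines(paste0(data$ind[i], " ,  ", paste(geno, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read an aligned FASTA file
#' @param path file path.
#' @return a [haplotype_data()] (sequences must share one length).
#' @export
read_fasta <- function(path) {
  seqs <- as.character(Biostrings::readDNAStringSet(path))
  haplotype_data(seqs = seqs)
}

#' Write an aligned FASTA file
#' @param data a [haplotype_data()] holding sequences (see
#'   [haplotypes_to_sequences()] for site-matrix data).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path) {
  stopifnot(inherits(data, "haplotype_data"))
  if (is.null(data$seqs))
    stop("haplotype_data holds a site matrix; convert with haplotypes_to_sequences()")
  nm <- names(data$seqs)
  if (is.null(nm)) nm <- sprintf("seq_%03d", seq_along(data$seqs))
  x <- Biostrings::DNAStringSet(stats::setNames(data$seqs, nm))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Render an infinite-sites site matrix as DNA sequences
#'
#' Places the segregating sites at distinct random positions of a random
#' ancestral sequence of the declared length and substitutes a different
#' base on the derived background.  Uses the current RNG stream.
#'
#' @param data a [haplotype_data()] with a site matrix.
#' @param names sequence names.
#' @return a [haplotype_data()] holding sequences.
#' @export
haplotypes_to_sequences <- function(data, names = NULL) {
  stopifnot(inherits(data, "haplotype_data"))
  if (is.null(data$sites)) return(data)
  S <- ncol(data$sites)
  L <- data$seq_length
  if (S > L) stop("more segregating sites than sequence positions")
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  pos <- sort(sample.int(L, S))
  derived <- vapply(pos, function(p) sample(setdiff(bases, anc[p]), 1L),
                    character(1))
  seqs <- vapply(seq_len(data$n), function(i) {
    s <- anc
    hit <- which(data$sites[i, ] == 1L)
    s[pos[hit]] <- derived[hit]
    paste(s, collapse = "")
  }, character(1))
  if (is.null(names)) names <- sprintf("seq_%03d", seq_len(data$n))
  names(seqs) <- names
  haplotype_data(seqs = seqs, group = data$group)
}
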