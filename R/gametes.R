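#' Sample a recombinant gamete from a parental haplotype pair
#'
#' Models meiosis per chromosome: the crossover count is Poisson with mean
#' equal to the chromosome's map length in Morgans, crossover positions are
#' uniform along the chromosome, parental origin alternates at each
#' crossover, and the starting strand is chosen by a fair coin. A zero-length
#' chromosome recombines never and yields an unrecombined copy of one
#' parental strand.
#'
#' @param haplotypes a 2 x L integer matrix (rows = the parent's two
#'   haplotypes, columns = loci in genome order, alleles coded 0/1) covering
#'   all marker + QTL loci of `genome`.
#' @param genome a [build_genome()] map.
#' @param mutation_rate per-locus recurrent mutation probability applied to
#'   the gamete (default 0); see [mutate_gamete()].
#' @return integer vector of length L with attribute `crossovers`, the
#'   genome-wide crossover count.
#' @seealso [mutate_gamete()]
#' @export
sample_gamete <- function(haplotypes, genome, mutation_rate = 0) {
  info <- genome_loci(genome)
  L <- nrow(info$loci)
  if (!is.matrix(haplotypes) || nrow(haplotypes) != 2 || ncol(haplotypes) != L)
    stop(sprintf("`haplotypes` must be a 2 x %d matrix covering all loci", L),
         call. = FALSE)
  check_mutation_rate(mutation_rate)
  res <- cpp_sample_gamete(as.integer(haplotypes[1, ]),
                           as.integer(haplotypes[2, ]),
                           info$loci$pos_cM,
                           info$chr_first, info$chr_last, info$chr_len,
                           mutation_rate)
  structure(res$gamete, crossovers = res$crossovers)
}

#' Apply recurrent mutation to a haplotype
#'
#' Each locus flips its allele state independently with probability
#' `mutation_rate`. Mutation is recurrent: an allele toggles between the two
#' existing variants and no new alleles arise.
#'
#' @param haplotype integer vector of 0/1 alleles.
#' @param mutation_rate per-locus flip probability in `[0, 1)`.
#' @return the mutated haplotype (same length, 0/1).
#' @export
mutate_gamete <- function(haplotype, mutation_rate) {
  check_mutation_rate(mutation_rate)
  if (mutation_rate == 0) return(haplotype)
  flip <- runif(length(haplotype)) < mutation_rate
  haplotype[flip] <- 1L - haplotype[flip]
  haplotype
}

check_mutation_rate <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
    stop("mutation rate must lie in [0, 1)", call. = FALSE)
  invisible(rate)
}
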