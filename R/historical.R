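# Historical (drift) phase of the forward simulator.

# A cohort is the minimal genetic state carried between phases: the two
# haplotype matrices (rows = individuals, columns = all loci in genome
# storage order), sexes, and the genome they live on.
new_cohort <- function(genome, H1, H2, sex) {
  structure(list(genome = genome, H1 = H1, H2 = H2, sex = sex),
            class = "sim_cohort")
}

#' @export
#' @method print sim_cohort
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d individuals (%d M / %d F), %d loci\n",
              nrow(x$H1), sum(x$sex == "M"), sum(x$sex == "F"), ncol(x$H1)))
  invisible(x)
}

# Founder haplotypes: every locus starts at allele frequency 0.5 and drift +
# recurrent mutation shape the spectrum from there.
init_founders <- function(genome, n) {
  L <- nrow(genome_loci(genome)$loci)
  H1 <- matrix(as.integer(runif(n * L) < 0.5), n, L)
  H2 <- matrix(as.integer(runif(n * L) < 0.5), n, L)
  new_cohort(genome, H1, H2, rep_len(c("M", "F"), n))
}

#' Run the historical (drift) phase of the simulation
#'
#' Random mating with an equal sex ratio, no selection and no migration.
#' Each phase interpolates the population size linearly from its start to
#' its end size, so bottlenecks and expansions shape the amount of linkage
#' disequilibrium the cohort carries into the recent phase. Generation 0
#' founders start every locus at allele frequency 0.5.
#'
#' @param genome a [build_genome()] map.
#' @param phases list of phases, each `c(n_generations, start_size,
#'   end_size)`; an empty list returns the initialised founders unchanged.
#' @param mutation_rate per-locus recurrent mutation rate per generation.
#' @param seed optional integer seed.
#' @param founders optional `sim_cohort` to start from instead of a fresh
#'   frequency-0.5 initialisation. Passing the same base cohort to several
#'   populations makes them diverge from common ancestors (shared LD
#'   phase), the situation of related livestock breeds; the cohort is
#'   subsampled to the first phase's start size if larger.
#' @return a cohort (class `sim_cohort`) of the final generation, with
#'   attribute `monomorphic`: logical flag per marker (monomorphic markers
#'   are retained but flagged).
#' @export
run_historical <- function(genome, phases, mutation_rate = 2.5e-5,
                           seed = NULL, founders = NULL) {
  local_seed(seed)
  check_mutation_rate(mutation_rate)
  sizes0 <- if (length(phases)) phases[[1]][2] else 100
  cohort <- if (is.null(founders)) init_founders(genome, sizes0)
            else subsample_cohort(founders, sizes0)
  info <- genome_loci(genome)
  for (ph in phases) {
    stopifnot(length(ph) == 3, ph[1] >= 0, ph[2] >= 2, ph[3] >= 2)
    gens <- ph[1]
    if (gens == 0) next
    sizes <- round(ph[2] + (ph[3] - ph[2]) * seq_len(gens) / gens)
    for (n_next in sizes)
      cohort <- random_mating_generation(cohort, n_next, info, mutation_rate)
  }
  mono <- marker_monomorphic(cohort, info)
  attr(cohort, "monomorphic") <- mono
  cohort
}

# Draw a sex-balanced subsample of a base cohort (used when several
# populations branch off one shared base).
subsample_cohort <- function(base, n) {
  if (nrow(base$H1) <= n) return(base)  # sizes ramp up through mating
  males <- which(base$sex == "M"); females <- which(base$sex == "F")
  nm <- min(length(males), ceiling(n / 2))
  keep <- c(males[sample.int(length(males), nm)],
            females[sample.int(length(females), n - nm)])
  new_cohort(base$genome, base$H1[keep, , drop = FALSE],
             base$H2[keep, , drop = FALSE], base$sex[keep])
}

random_mating_generation <- function(cohort, n_next, info, mutation_rate) {
  males <- which(cohort$sex == "M")
  females <- which(cohort$sex == "F")
  if (!length(males) || !length(females))
    stop("cannot mate: a sex is missing from the cohort", call. = FALSE)
  sire <- males[sample.int(length(males), n_next, replace = TRUE)]
  dam <- females[sample.int(length(females), n_next, replace = TRUE)]
  off <- cpp_drop_offspring(cohort$H1, cohort$H2, sire, dam,
                            info$loci$pos_cM, info$chr_first, info$chr_last,
                            info$chr_len, mutation_rate)
  new_cohort(cohort$genome, off$H1, off$H2, rep_len(c("M", "F"), n_next))
}

marker_monomorphic <- function(cohort, info = genome_loci(cohort$genome)) {
  counts <- colSums(cohort$H1[, info$marker_cols, drop = FALSE]) +
    colSums(cohort$H2[, info$marker_cols, drop = FALSE])
  counts == 0 | counts == 2L * nrow(cohort$H1)
}

# Allele-count (dosage) matrices for the marker and QTL subsets.
cohort_dosage <- function(H1, H2, info) {
  D <- H1 + H2
  list(markers = D[, info$marker_cols, drop = FALSE],
       qtl = D[, info$qtl_cols, drop = FALSE])
}
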