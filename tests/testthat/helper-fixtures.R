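# Shared fixtures. Expensive simulations are cached per session so several
# test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# A miniature configuration that exercises every stage in well under a
# second: 3 chromosomes, 60 cM, 120 markers, 30 QTL, two short historical
# phases, 3 selected generations.
tiny_config <- function(pop = "A") {
  cfg <- pop_config(pop, "desk")
  cfg$genome_args <- list(n_chromosomes = 3, total_length = 60,
                          n_markers = 120, n_qtl = 30)
  cfg$demography$common_phases <- list(c(10, 40, 40))
  cfg$demography$hp_phases <- list(c(5, 30, 120))
  cfg$demography$recent <- modifyList(
    cfg$demography$recent,
    list(n_sires = 5, n_dams = 40, n_generations = 3))
  cfg
}

tiny_study <- function(seed = 42, pop = "A", config = tiny_config(pop),
                       ...) {
  simulate_population(pop, "desk", seed = seed, config = config, ...)
}

# Full desk-scale PopA study, simulated once per test run.
desk_study_A <- function() {
  cached("desk_A", simulate_population("A", "desk", seed = 101))
}

# Desk-scale three-population bundle on a shared genome.
desk_bundle <- function() {
  cached("desk_bundle", simulate_populations(202, "desk"))
}

# Small genotype fixture in Hardy-Weinberg proportions.
hwe_genotypes <- function(n, m, p = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  G <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(G) <- paste0("id", seq_len(n))
  G
}
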