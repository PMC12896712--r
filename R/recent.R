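# Recent generations: truncation selection on pedigree-BLUP EBVs.

#' Run the recent selected generations of the simulation
#'
#' Starting from a founder cohort, `n_sires` males and `n_dams` females are
#' drawn as the initial breeders. Each generation every dam produces
#' `offspring_per_dam` offspring by random sire-dam pairing; EBVs are then
#' estimated for all recorded animals by pedigree BLUP (mixed-model
#' equations with the sparse `A` inverse and the true variance ratio); a
#' fraction `sire_replacement` of the sires (resp. `dam_replacement` of the
#' dams) with the lowest EBV is culled and replaced by the highest-EBV
#' same-sex offspring of the current generation. Phenotypes carry the
#' configured missingness, and breeding values, pedigree, phenotypes and
#' genotypes are recorded for every generation.
#'
#' @param founders a `sim_cohort` from [run_historical()].
#' @param demography a [demography_config()]; its `recent` block drives this
#'   phase.
#' @param architecture a [assign_trait()] trait architecture (scaled on the
#'   founder cohort).
#' @param genome the shared [build_genome()] map.
#' @param seed optional integer seed.
#' @param population_label label used as the id prefix ("A", "B", "C").
#' @param selection `"ebv"` (truncation on pedigree-BLUP EBV, the default)
#'   or `"random"` (replacements drawn at random; for comparison).
#' @return an object of class `sim_study`; see [simulate_population()].
#' @export
run_recent <- function(founders, demography, architecture, genome,
                       seed = NULL, population_label = "A",
                       selection = c("ebv", "random")) {
  local_seed(seed)
  selection <- match.arg(selection)
  rc <- demography$recent
  info <- genome_loci(genome)
  mut <- demography$mutation_rate
  miss <- demography$missing_phenotype_rate

  males <- which(founders$sex == "M")
  females <- which(founders$sex == "F")
  if (length(males) < rc$n_sires || length(females) < rc$n_dams)
    stop(sprintf(
      "founder cohort too small: need %d sires / %d dams, have %d M / %d F",
      rc$n_sires, rc$n_dams, length(males), length(females)), call. = FALSE)

  keep <- c(males[sample.int(length(males), rc$n_sires)],
            females[sample.int(length(females), rc$n_dams)])
  n_founders <- length(keep)
  n_total <- n_founders +
    rc$n_generations * rc$n_dams * rc$offspring_per_dam
  L <- ncol(founders$H1)

  H1 <- matrix(NA_integer_, n_total, L)
  H2 <- matrix(NA_integer_, n_total, L)
  H1[seq_len(n_founders), ] <- founders$H1[keep, ]
  H2[seq_len(n_founders), ] <- founders$H2[keep, ]
  id <- paste0(population_label, "_", seq_len(n_total))
  sex <- c(rep("M", rc$n_sires), rep("F", rc$n_dams),
           rep(NA_character_, n_total - n_founders))
  sire_of <- dam_of <- rep(NA_integer_, n_total)
  generation <- c(rep(0L, n_founders), rep(NA_integer_, n_total - n_founders))

  qtl_dose <- function(rows)
    H1[rows, info$qtl_cols, drop = FALSE] + H2[rows, info$qtl_cols, drop = FALSE]
  tbv <- rep(NA_real_, n_total)
  tbv[seq_len(n_founders)] <- compute_tbv(qtl_dose(seq_len(n_founders)),
                                          architecture$beta)
  y <- rep(NA_real_, n_total)
  y[seq_len(n_founders)] <- simulate_phenotypes(tbv[seq_len(n_founders)],
                                                architecture, miss)

  sires <- seq_len(rc$n_sires)
  dams <- rc$n_sires + seq_len(rc$n_dams)
  n_rep_s <- as.integer(round(rc$sire_replacement * rc$n_sires))
  n_rep_d <- as.integer(round(rc$dam_replacement * rc$n_dams))
  lambda <- architecture$sigma_e2 / architecture$sigma_a2
  filled <- n_founders
  ebv <- rep(NA_real_, n_total)
  breeder_log <- vector("list", rc$n_generations)

  for (g in seq_len(rc$n_generations)) {
    dam_vec <- rep(dams, each = rc$offspring_per_dam)
    sire_vec <- sires[sample.int(length(sires), length(dam_vec),
                                 replace = TRUE)]
    off <- cpp_drop_offspring(H1[seq_len(filled), , drop = FALSE],
                              H2[seq_len(filled), , drop = FALSE],
                              sire_vec, dam_vec,
                              info$loci$pos_cM, info$chr_first,
                              info$chr_last, info$chr_len, mut)
    rows <- filled + seq_along(dam_vec)
    H1[rows, ] <- off$H1
    H2[rows, ] <- off$H2
    sire_of[rows] <- sire_vec
    dam_of[rows] <- dam_vec
    sex[rows] <- sample(c("M", "F"), length(rows), replace = TRUE)
    generation[rows] <- g
    tbv[rows] <- compute_tbv(qtl_dose(rows), architecture$beta)
    y[rows] <- simulate_phenotypes(tbv[rows], architecture, miss)
    filled <- filled + length(rows)

    cur <- seq_len(filled)
    if (selection == "ebv") {
      ebv[cur] <- pedigree_ebv(y[cur], sire_of[cur], dam_of[cur], lambda)
    } else {
      ebv[cur] <- runif(filled)  # random ranking
    }
    cand_m <- rows[sex[rows] == "M"]
    cand_f <- rows[sex[rows] == "F"]
    if (length(cand_m) < n_rep_s || length(cand_f) < n_rep_d)
      stop(sprintf(
        "generation %d: %d male / %d female candidates cannot fill the %d/%d replacement quota",
        g, length(cand_m), length(cand_f), n_rep_s, n_rep_d), call. = FALSE)
    if (n_rep_s > 0) {
      cull <- sires[order(ebv[sires])[seq_len(n_rep_s)]]
      new <- cand_m[order(ebv[cand_m], decreasing = TRUE)[seq_len(n_rep_s)]]
      sires <- c(setdiff(sires, cull), new)
    }
    if (n_rep_d > 0) {
      cull <- dams[order(ebv[dams])[seq_len(n_rep_d)]]
      new <- cand_f[order(ebv[cand_f], decreasing = TRUE)[seq_len(n_rep_d)]]
      dams <- c(setdiff(dams, cull), new)
    }
    breeder_log[[g]] <- list(sires = id[sires], dams = id[dams])
  }

  pedigree <- data.frame(
    id = id, sire = ifelse(is.na(sire_of), NA, id[sire_of]),
    dam = ifelse(is.na(dam_of), NA, id[dam_of]),
    sex = sex, generation = generation, stringsAsFactors = FALSE)
  dose <- cohort_dosage(H1, H2, info)
  rownames(dose$markers) <- rownames(dose$qtl) <- id
  names(y) <- names(tbv) <- names(ebv) <- id
  # The final generation is the validation set; the four generations
  # preceding it (fewer when the phase is shorter) are the genotyped,
  # phenotyped reference block, mirroring the multi-generation reference
  # of the full design.
  gen_last <- rc$n_generations
  ref_gens <- if (gen_last >= 2) max(1L, gen_last - 4L):(gen_last - 1L)
              else integer()
  genotyped_gen <- c(ref_gens, gen_last)

  structure(list(
    genome = genome, architecture = architecture,
    population = population_label,
    pedigree = pedigree,
    genotypes = dose$markers, qtl_genotypes = dose$qtl,
    phenotype = y, tbv = tbv, ebv = ebv,
    genotyped_generations = genotyped_gen,
    reference_generations = ref_gens,
    reference_ids = id[generation %in% ref_gens],
    validation_ids = id[generation == gen_last],
    breeders = breeder_log,
    demography = demography, selection = selection),
    class = "sim_study")
}

# Pedigree BLUP used for within-simulation selection: intercept-only fixed
# effect, sparse A inverse, records with missing phenotypes excluded.
pedigree_ebv <- function(y, sire_idx, dam_idx, lambda) {
  n <- length(y)
  ped <- data.frame(id = seq_len(n),
                    sire = ifelse(is.na(sire_idx), 0L, sire_idx),
                    dam = ifelse(is.na(dam_idx), 0L, dam_idx))
  Ainv <- ainverse(ped)
  obs <- which(!is.na(y))
  Z <- Matrix::sparseMatrix(i = seq_along(obs), j = obs, x = 1,
                            dims = c(length(obs), n))
  sol <- solve_mme(y[obs], matrix(1, length(obs), 1), Z, Ainv, lambda,
                   tag = "PBLUP")
  unname(sol$u)
}

#' @export
#' @method print sim_study
print.sim_study <- function(x, ...) {
  gen <- x$pedigree$generation
  cat(sprintf(paste0("sim_study Pop%s: %d animals over %d generations, ",
                     "%d markers, %d QTL\n"),
              x$population, nrow(x$pedigree), max(gen),
              ncol(x$genotypes), ncol(x$qtl_genotypes)))
  cat(sprintf("  reference (gens %s): %d, validation (gen %d): %d, missing y: %.1f%%\n",
              paste(range(x$reference_generations), collapse = "-"),
              length(x$reference_ids), max(gen),
              length(x$validation_ids), 100 * mean(is.na(x$phenotype))))
  invisible(x)
}
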