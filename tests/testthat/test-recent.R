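test_that("each generation adds one offspring per dam and replaces the exact quota", {
  st <- tiny_study(seed = 11)
  ped <- st$pedigree
  rc <- st$demography$recent
  for (g in seq_len(rc$n_generations))
    expect_equal(sum(ped$generation == g), rc$n_dams * rc$offspring_per_dam)
  # exactly round(rate * n) breeders are swapped out each generation
  n_rep_s <- round(rc$sire_replacement * rc$n_sires)
  n_rep_d <- round(rc$dam_replacement * rc$n_dams)
  for (g in 2:rc$n_generations) {
    expect_equal(length(setdiff(st$breeders[[g]]$sires,
                                st$breeders[[g - 1]]$sires)), n_rep_s)
    expect_equal(length(setdiff(st$breeders[[g]]$dams,
                                st$breeders[[g - 1]]$dams)), n_rep_d)
    expect_equal(length(st$breeders[[g]]$sires), rc$n_sires)
    expect_equal(length(st$breeders[[g]]$dams), rc$n_dams)
  }
})

test_that("pedigree is topologically ordered with founders unrelated", {
  st <- tiny_study(seed = 11)
  ped <- st$pedigree
  idx <- seq_len(nrow(ped))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  expect_true(all(is.na(si) | si < idx))
  expect_true(all(is.na(di) | di < idx))
  A <- numerator_relationship(ped)
  founders <- which(ped$generation == 0)
  expect_equal(unname(diag(A)[founders]), rep(1, length(founders)))
})

test_that("stored TBV is conserved with respect to QTL genotypes and effects", {
  st <- tiny_study(seed = 11)
  again <- compute_tbv(st$qtl_genotypes, st$architecture$beta)
  expect_lt(max(abs(again - st$tbv)), 1e-10)
})

test_that("phenotype missingness matches the configured rate", {
  st <- desk_study_A()
  rate <- st$demography$missing_phenotype_rate
  n <- length(st$phenotype)
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(mean(is.na(st$phenotype)) - rate), 3 * se)
})

test_that("EBV truncation selection raises mean TBV relative to random selection", {
  cfg <- tiny_config()
  cfg$demography$recent$n_generations <- 4
  g <- build_genome(3, 60, 120, 30, seed = 21)
  base <- run_historical(g, cfg$demography$common_phases, seed = 22)
  mk <- function(sel) {
    fo <- run_historical(g, cfg$demography$hp_phases, seed = 23,
                         founders = base)
    set.seed(24)
    info <- crosspopgs:::genome_loci(g)
    arch <- assign_trait(fo$H1[, info$qtl_cols] + fo$H2[, info$qtl_cols])
    run_recent(fo, cfg$demography, arch, g, seed = 25, selection = sel)
  }
  sel <- mk("ebv")
  rnd <- mk("random")
  last <- function(st) mean(st$tbv[st$validation_ids])
  expect_gt(last(sel), last(rnd))
})

test_that("an impossible replacement quota is rejected", {
  cfg <- tiny_config()
  cfg$demography$recent$n_dams <- 6
  cfg$demography$recent$n_sires <- 5
  # ~3 offspring per generation cannot supply 3 new sires + 2 new dams
  expect_error(tiny_study(seed = 31, config = cfg),
               "replacement quota|too small")
})

test_that("identical seeds reproduce the full study", {
  a <- tiny_study(seed = 12)
  b <- tiny_study(seed = 12)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$ebv, b$ebv)
})
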