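# Independent transcription of the Weir & Cockerham (1984) two-population
# variance components, used as the oracle for fst_per_snp.
wc_fst_oracle <- function(ga, gb) {
  na <- nrow(ga); nb <- nrow(gb); r <- 2
  sapply(seq_len(ncol(ga)), function(j) {
    p1 <- mean(ga[, j]) / 2; p2 <- mean(gb[, j]) / 2
    h1 <- mean(ga[, j] == 1); h2 <- mean(gb[, j] == 1)
    nbar <- (na + nb) / 2
    nc <- (r * nbar - (na^2 + nb^2) / (r * nbar)) / (r - 1)
    pbar <- (na * p1 + nb * p2) / (r * nbar)
    s2 <- (na * (p1 - pbar)^2 + nb * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (na * h1 + nb * h2) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a / (a + b + cc)
  })
}

test_that("Weir-Cockerham Fst matches a literal transcription of the formulas", {
  set.seed(1)
  ga <- hwe_genotypes(10, 50, p = runif(50, 0.2, 0.8), seed = 1)
  gb <- hwe_genotypes(10, 50, p = runif(50, 0.2, 0.8), seed = 2)
  res <- fst_per_snp(ga, gb)
  oracle <- wc_fst_oracle(ga, gb)
  keep <- !res$undefined
  expect_lt(max(abs(res$fst[keep] - oracle[keep])), 1e-12)
})

test_that("fixed differences give Fst exactly 1", {
  ga <- matrix(2L, 10, 3)
  gb <- matrix(0L, 10, 3)
  res <- fst_per_snp(ga, gb)
  expect_equal(res$fst, rep(1, 3))
  res_h <- fst_per_snp(ga, gb, estimator = "hudson")
  expect_equal(res_h$fst, rep(1, 3))
})

test_that("a population against itself shows no differentiation", {
  g <- hwe_genotypes(60, 300, seed = 3)
  res <- fst_per_snp(g, g)
  expect_true(all(res$fst[!res$undefined] <= 0))
  expect_lt(abs(mean(res$fst)), 0.01)
})

test_that("Fst is invariant to allele-label swaps", {
  ga <- hwe_genotypes(15, 40, seed = 4)
  gb <- hwe_genotypes(15, 40, p = runif(40, 0.2, 0.8), seed = 5)
  swap <- sample(40, 10)
  ga2 <- ga; gb2 <- gb
  ga2[, swap] <- 2L - ga2[, swap]
  gb2[, swap] <- 2L - gb2[, swap]
  expect_equal(fst_per_snp(ga, gb)$fst, fst_per_snp(ga2, gb2)$fst,
               tolerance = 1e-12)
})

test_that("monomorphic-in-both loci are flagged and reported as zero", {
  ga <- cbind(rep(0L, 8), rbinom(8, 2, 0.5))
  gb <- cbind(rep(0L, 8), rbinom(8, 2, 0.5))
  res <- fst_per_snp(ga, gb)
  expect_true(res$undefined[1])
  expect_equal(res$fst[1], 0)
  expect_error(fst_per_snp(ga, gb[, 1, drop = FALSE]), "marker sets")
  expect_error(fst_per_snp(ga[1, , drop = FALSE], gb), "2 individuals")
})

test_that("screening uses a strict threshold and is monotone", {
  expect_equal(screen_snps(c(0.05, 0.15, 0.10), 0.1), 2L)
  expect_equal(screen_snps(c(0.05, 0.15, 0.10), -Inf), 1:3)
  set.seed(6)
  fst <- runif(100, -0.05, 0.6)
  for (i in 1:5) {
    t1 <- runif(1, 0, 0.3); t2 <- t1 + runif(1, 0, 0.3)
    expect_true(all(screen_snps(fst, t2) %in% screen_snps(fst, t1)))
  }
  expect_warning(screen_snps(c(0.01, 0.02), 0.5), "no markers")
})

test_that("LD decay declines with distance and handles degenerate pairs", {
  g <- build_genome(1, 10, 50, 2, seed = 7)
  # duplicated marker columns give r2 = 1 in their bin
  set.seed(8)
  X <- hwe_genotypes(100, 50, seed = 8)
  X[, 2] <- X[, 1]
  prof <- ld_decay(X, g, max_distance_kb = 10000, n_bins = 5)
  expect_true(all(prof$mean_r2 >= 0 & prof$mean_r2 <= 1, na.rm = TRUE))
  # independent equal-frequency markers: mean r2 near the 1/n null
  Xind <- hwe_genotypes(500, 50, p = rep(0.5, 50), seed = 9)
  prof2 <- ld_decay(Xind, g, max_distance_kb = 10000, n_bins = 2)
  expect_lt(sum(prof2$mean_r2 * prof2$n_pairs) / sum(prof2$n_pairs), 0.01)
  # simulated population: near pairs in stronger LD than far pairs
  st <- desk_study_A()
  prof3 <- ld_decay(st$genotypes[st$validation_ids, ], st$genome)
  expect_gt(prof3$mean_r2[1], prof3$mean_r2[nrow(prof3)])
})

test_that("PCA scores are orthogonal and separate populations", {
  X <- hwe_genotypes(40, 200, seed = 10)
  sc <- pca_coords(X, 3)
  cp <- crossprod(sc)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  # identical individuals collapse to the origin
  same <- matrix(rep(rbinom(50, 2, 0.5), each = 6), 6)
  expect_equal(unname(pca_coords(same, 2)), matrix(0, 6, 2),
               ignore_attr = TRUE)
  # between-population spread exceeds within-population spread
  b <- desk_bundle()
  ids <- lapply(b[c("A", "B", "C")], function(s) s$validation_ids)
  X3 <- rbind(b$A$genotypes[ids$A, ], b$B$genotypes[ids$B, ],
              b$C$genotypes[ids$C, ])
  lab <- rep(c("A", "B", "C"), times = lengths(ids))
  sc3 <- pca_coords(X3, 2)
  cent <- apply(sc3, 2, tapply, lab, mean)
  within <- mean(sqrt(rowSums((sc3 - cent[lab, ])^2)))
  between <- mean(dist(cent))
  expect_gt(between, within)
})

test_that("PopC is more differentiated from PopA than PopB is", {
  b <- desk_bundle()
  fab <- fst_per_snp(b$A$genotypes[b$A$reference_ids, ],
                     b$B$genotypes[b$B$reference_ids, ])
  fac <- fst_per_snp(b$A$genotypes[b$A$reference_ids, ],
                     b$C$genotypes[b$C$reference_ids, ])
  expect_gt(mean(fac$fst), mean(fab$fst))
})
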