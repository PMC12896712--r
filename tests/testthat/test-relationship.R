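test_that("tabular A reproduces path-counting coefficients", {
  two <- data.frame(id = c("x", "y"), sire = NA, dam = NA)
  expect_equal(unname(numerator_relationship(two)), diag(2),
               ignore_attr = TRUE)
  trio <- data.frame(id = c("s", "d", "o"),
                     sire = c(NA, NA, "s"), dam = c(NA, NA, "d"))
  A <- numerator_relationship(trio)
  expect_equal(A["o", "o"], 1.0)
  expect_equal(A["s", "o"], 0.5)
  # full sibs related 0.5; their offspring inbred with diagonal 1.25
  ped <- data.frame(
    id = c("s", "d", "k1", "k2", "o"),
    sire = c(NA, NA, "s", "s", "k1"),
    dam = c(NA, NA, "d", "d", "k2"))
  A <- numerator_relationship(ped)
  expect_equal(A["k1", "k2"], 0.5)
  expect_equal(A["o", "o"], 1.25)
})

test_that("cycles and disordered pedigrees are rejected", {
  bad <- data.frame(id = c("a", "b"), sire = c("b", NA), dam = NA)
  expect_error(numerator_relationship(bad), "ordered|ancestor")
})

test_that("Henderson's sparse inverse actually inverts A", {
  ped <- data.frame(
    id = c("s", "d", "k1", "k2", "o", "p"),
    sire = c(NA, NA, "s", "s", "k1", NA),
    dam = c(NA, NA, "d", "d", "k2", NA))
  A <- numerator_relationship(ped)
  Ainv <- as.matrix(crosspopgs:::ainverse(ped))
  expect_lt(max(abs(Ainv %*% A - diag(nrow(A)))), 1e-10)
  st <- tiny_study(seed = 13)
  A2 <- numerator_relationship(st$pedigree)
  Ainv2 <- as.matrix(crosspopgs:::ainverse(st$pedigree))
  expect_lt(max(abs(Ainv2 %*% A2 - diag(nrow(A2)))), 1e-8)
})

test_that("VanRaden G matches hand calculations and blending", {
  # everyone heterozygous at p = 0.5: Z = 0, G* = blend * I
  M <- matrix(1, 4, 6, dimnames = list(paste0("i", 1:4), NULL))
  G <- vanraden_grm(M, p = rep(0.5, 6), blend = 0.05)
  expect_equal(unname(G), 0.05 * diag(4), ignore_attr = TRUE)
  # two individuals, two SNPs, counts [[0,2],[2,0]] at p = 0.5:
  # Z = [[-1,1],[1,-1]], sum 2p(1-p) = 1, so G = Z Z' = [[2,-2],[-2,2]]
  M2 <- matrix(c(0, 2, 2, 0), 2, 2,
               dimnames = list(c("a", "b"), NULL))
  G2 <- vanraden_grm(M2, p = c(0.5, 0.5), blend = 0)
  expect_equal(unname(G2), matrix(c(2, -2, -2, 2), 2),
               ignore_attr = TRUE)
  expect_error(vanraden_grm(matrix(2, 3, 4)), "monomorphic")
})

test_that("G diagonal averages near 1 in a Hardy-Weinberg population", {
  M <- hwe_genotypes(300, 2000, seed = 5)
  G <- vanraden_grm(M, blend = 0)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
  expect_lt(max(abs(G - t(G))), 1e-10)
})

test_that("H inverse reduces to A inverse in the degenerate cases", {
  ped <- data.frame(
    id = c("s", "d", "k1", "k2"),
    sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"))
  A <- numerator_relationship(ped)
  Hinv0 <- h_inverse(A, matrix(0, 0, 0), character())
  expect_equal(Hinv0, solve(A), tolerance = 1e-10, ignore_attr = TRUE)
  # G* equal to A22 cancels the genomic block exactly
  gset <- c("k1", "k2")
  Hinv1 <- h_inverse(A, A[gset, gset], gset)
  expect_equal(Hinv1, solve(A), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("assembled H inverse matches the dense oracle", {
  set.seed(6)
  ped <- data.frame(
    id = c("s", "d", "k1", "k2"),
    sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"))
  A <- numerator_relationship(ped)
  g <- 3:4
  R <- matrix(rnorm(4), 2)
  Gs <- crossprod(R) + diag(2) * 0.5
  dimnames(Gs) <- list(c("k1", "k2"), c("k1", "k2"))
  Hinv <- h_inverse(A, Gs, c("k1", "k2"))
  # oracle: invert A, add the block difference by direct dense arithmetic
  oracle <- solve(A)
  oracle[g, g] <- oracle[g, g] + solve(Gs) - solve(A[g, g])
  expect_lt(max(abs(Hinv - oracle)), 1e-8)
  # H^-1 times the dense H (joint pedigree-genomic covariance) is identity
  A11 <- A[1:2, 1:2]; A12 <- A[1:2, g]; A22 <- A[g, g]
  H <- A
  H[g, g] <- Gs
  H[1:2, g] <- A12 %*% solve(A22) %*% Gs
  H[g, 1:2] <- t(H[1:2, g])
  H[1:2, 1:2] <- A11 + A12 %*% solve(A22) %*% (Gs - A22) %*%
    solve(A22) %*% t(A12)
  expect_lt(max(abs(Hinv %*% H - diag(4))), 1e-6)
  # sparse pedigree-based assembly agrees with the dense route
  Hinv_ped <- as.matrix(crosspopgs:::h_inverse_ped(ped, Gs, c("k1", "k2")))
  expect_lt(max(abs(Hinv_ped - oracle)), 1e-8)
})

test_that("singular genomic matrices are reported by name", {
  ped <- data.frame(id = c("a", "b"), sire = NA, dam = NA)
  A <- numerator_relationship(ped)
  Gs <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(h_inverse(A, Gs, c("a", "b")), "G\\*")
})
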