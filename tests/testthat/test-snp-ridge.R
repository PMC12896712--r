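test_that("orthogonal responses give zero SNP effects", {
  Z <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  y <- rep(2, 4)  # orthogonal to both columns
  fit <- snp_ridge(y, matrix(1, 4, 1), Z, sigma_alpha2 = 1, sigma_e2 = 1)
  expect_lt(max(abs(fit$alpha)), 1e-12)
})

test_that("a single SNP reproduces the scalar closed form", {
  set.seed(1)
  z <- rnorm(20)
  z <- z - mean(z)
  y <- 0.3 * z + rnorm(20, 0, 0.5)
  # with an exactly centred z the intercept block decouples, so the
  # textbook scalar form holds
  fit <- snp_ridge(y, matrix(1, 20, 1), matrix(z, 20, 1),
                   sigma_alpha2 = 0.09, sigma_e2 = 0.25)
  oracle <- sum(z * y) / (sum(z^2) + 0.25 / 0.09)
  expect_equal(unname(fit$alpha), oracle, tolerance = 1e-10)
})

test_that("SNP-ridge with unit weights is the equivalent model of GBLUP", {
  set.seed(2)
  n <- 200; m <- 500
  M <- hwe_genotypes(n, m, seed = 2)
  p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  Zc <- sweep(M[, keep], 2, 2 * p[keep])
  k <- sum(2 * p[keep] * (1 - p[keep]))
  u_true <- drop(Zc %*% rnorm(sum(keep), 0, 0.05))
  y <- 1 + u_true + rnorm(n, 0, sd(u_true))
  sigma_a2 <- var(u_true); sigma_e2 <- var(u_true)
  # route 1: SNP-space ridge, GEBV = Z alpha
  rid <- snp_ridge(y, matrix(1, n, 1), Zc,
                   sigma_alpha2 = sigma_a2 / k, sigma_e2 = sigma_e2)
  # route 2 (independent oracle): GBLUP in its V-matrix form, which never
  # inverts the (singular) unblended G
  G <- tcrossprod(Zc) / k
  V <- sigma_a2 * G + sigma_e2 * diag(n)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  bh <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  gebv <- drop(sigma_a2 * G %*% Vi %*% (y - drop(X %*% bh)))
  expect_gt(cor(rid$gebv_train, gebv), 0.9999)
  expect_lt(max(abs(rid$gebv_train - gebv)), 1e-6)
})

test_that("degenerate weight vectors are rejected or handled", {
  Z <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  expect_error(snp_ridge(y, matrix(1, 10, 1), Z, weights = c(0, 0, 0),
                         sigma_alpha2 = 1, sigma_e2 = 1), "zero")
  fit <- snp_ridge(y, matrix(1, 10, 1), Z, weights = c(1, 0, 1),
                   sigma_alpha2 = 1, sigma_e2 = 1)
  expect_equal(fit$alpha[2], 0, ignore_attr = TRUE)
})

test_that("window weights average truncated windows and normalise to mean 1", {
  # S = 0: weights proportional to squared effects
  a <- c(1, 2, 3)
  w0 <- window_weights(a, S = 0)
  expect_equal(unname(w0), a^2 / mean(a^2), ignore_attr = TRUE)
  expect_equal(mean(w0), 1, tolerance = 1e-10)
  # constant effects: all weights 1 for any S
  for (S in 0:3) expect_equal(unname(window_weights(rep(1, 5), S)),
                              rep(1, 5), ignore_attr = TRUE)
  # hand-computed truncated windows for (0,1,0,0,2), S = 1:
  # squared (0,1,0,0,4); means (1/2, 1/3, 1/3, 4/3, 2); grand mean 0.9
  w <- window_weights(c(0, 1, 0, 0, 2), S = 1)
  expect_equal(unname(w),
               c(1/2, 1/3, 1/3, 4/3, 2) / 0.9, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(mean(w), 1, tolerance = 1e-10)
})

test_that("weight windows never span chromosome boundaries", {
  a <- c(1, 1, 10, 10)
  chrom <- c(1, 1, 2, 2)
  w <- window_weights(a, S = 5, chrom = chrom)
  # within each chromosome the window mean is constant
  expect_equal(w[1], w[2], ignore_attr = TRUE)
  expect_equal(w[3], w[4], ignore_attr = TRUE)
  expect_gt(w[3], w[1])
  expect_warning(wz <- window_weights(rep(0, 4), S = 1), "zero")
  expect_equal(unname(wz), rep(1, 4), ignore_attr = TRUE)
})
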