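test_that("raw QTL effect magnitudes follow the configured gamma shape", {
  set.seed(1)
  x <- rqtl_effects(20000, shape = 0.4)
  fit <- MASS::fitdistr(x, "gamma", lower = c(1e-3, 1e-3))
  expect_lt(abs(fit$estimate[["shape"]] - 0.4) / 0.4, 0.10)
})

test_that("trait scaling pins founder TBV variance to h2 * Vp", {
  set.seed(2)
  Q <- matrix(rbinom(400 * 60, 2, 0.4), 400, 60)
  arch <- assign_trait(Q, gamma_shape = 0.4, h2 = 0.42,
                       phenotypic_variance = 1.0)
  expect_lt(abs(var(drop(Q %*% arch$beta)) - 0.42), 1e-8)
  expect_equal(arch$sigma_a2 + arch$sigma_e2, 1.0)
  expect_error(assign_trait(matrix(1, 10, 4)), "monomorphic")
  expect_error(assign_trait(Q, h2 = 1.2), "h2")
})

test_that("TBV is the exact sum of QTL effects", {
  expect_equal(compute_tbv(matrix(c(0, 1, 2), 1), c(1, 1, 1)),
               3)
  expect_equal(compute_tbv(matrix(rbinom(20, 2, 0.5), 5), rep(0, 4)),
               rep(0, 5))
  set.seed(3)
  Q <- matrix(sample(0:2, 20, replace = TRUE), 5, 4)
  beta <- rnorm(4)
  loop <- sapply(1:5, function(k) {
    s <- 0
    for (j in 1:4) s <- s + beta[j] * Q[k, j]
    s
  })
  expect_equal(compute_tbv(Q, beta), loop, tolerance = 1e-12)
  expect_error(compute_tbv(Q, beta[1:3]), "mismatch")
  # single-QTL genotypes map to 0, beta, 2 beta
  expect_equal(compute_tbv(matrix(0:2, 3, 1), 1.7), c(0, 1.7, 3.4))
})

test_that("phenotypes follow y = mu + tbv + e with configured missingness", {
  arch0 <- structure(list(mu = 2, sigma_e2 = 0, sigma_a2 = 1),
                     class = "trait_architecture")
  tbv <- rnorm(50)
  expect_equal(simulate_phenotypes(tbv, arch0, missing_rate = 0),
               2 + tbv, ignore_attr = TRUE)
  set.seed(4)
  arch <- structure(list(mu = 0, sigma_e2 = 0.58, sigma_a2 = 0.42),
                    class = "trait_architecture")
  y <- simulate_phenotypes(rnorm(20000, 0, sqrt(0.42)), arch,
                           missing_rate = 0)
  se_var <- sqrt(2 / (20000 - 1))  # SE of unit-variance sample variance
  expect_lt(abs(var(y) - 1.0), 3 * se_var)
  ym <- simulate_phenotypes(rnorm(10000), arch, missing_rate = 0.05)
  se_miss <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(mean(is.na(ym)) - 0.05), 3 * se_miss)
})
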