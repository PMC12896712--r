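fit_fixture <- function(method = "gblup", seed = 1, n = 120, m = 300, ...) {
  set.seed(seed)
  M <- hwe_genotypes(n, m, seed = seed)
  p <- colMeans(M) / 2
  Zc <- sweep(M, 2, 2 * p)
  u <- drop(Zc %*% rnorm(m, 0, 0.04))
  y <- 0.5 + u + rnorm(n, 0, sd(u) * sqrt(0.58 / 0.42))
  dat <- data.frame(id = rownames(M), y = y)
  list(fit = gsblup(y ~ 1, dat, genotypes = M, method = method,
                    varcomp = varcomp_true(var(u), var(y - u)), ...),
       M = M, y = y, u = u, dat = dat)
}

test_that("the gsblup object supports the standard modelling verbs", {
  fx <- fit_fixture()
  fit <- fx$fit
  expect_s3_class(fit, "gsblup")
  expect_output(print(fit), "gsblup fit \\[gblup\\]")
  expect_output(print(summary(fit)), "breeding values")
  expect_named(coef(fit), "(Intercept)")
  expect_length(predict(fit), nrow(fx$M))
  expect_equal(fitted(fit) + residuals(fit), fx$y, ignore_attr = TRUE)
  expect_error(predict(fit, "nope"), "absent")
  sim <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sim), c(length(fx$y), 3))
  expect_lt(abs(var(sim[[1]]) / var(fx$y) - 1), 0.6)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_lt(fit$mme_residual, 1e-8)
  expect_gt(cor(predict(fit), fx$u), 0.5)
})

test_that("wGBLUP with forced unit weights reproduces GBLUP exactly", {
  fx <- fit_fixture("gblup")
  fxw <- fit_fixture("wgblup", snp_weights = rep(1, 300))
  expect_gt(cor(fxw$fit$u, fx$fit$u), 0.9999)
  expect_lt(max(abs(fxw$fit$u - fx$fit$u)), 1e-6)
})

test_that("two-step wGBLUP produces mean-1 weights and reasonable GEBVs", {
  fx <- fit_fixture("wgblup", window = 5)
  expect_equal(mean(fx$fit$snp_weights), 1, tolerance = 1e-10)
  expect_true(all(fx$fit$snp_weights >= 0))
  expect_length(fx$fit$alpha, 300)
  expect_gt(cor(predict(fx$fit), fx$u), 0.5)
})

test_that("ssGBLUP with every animal genotyped and G* = A22 equals PBLUP", {
  st <- tiny_study(seed = 14)
  ped <- st$pedigree
  obs <- names(st$phenotype)[!is.na(st$phenotype)]
  y <- st$phenotype[obs]
  X <- matrix(1, length(y), 1)
  n <- nrow(ped)
  Z <- Matrix::sparseMatrix(i = seq_along(obs), j = match(obs, ped$id),
                            x = 1, dims = c(length(obs), n))
  A <- numerator_relationship(ped)
  lam <- 0.58 / 0.42
  pb <- solve_mme(y, X, Z, crosspopgs:::ainverse(ped), lam)
  Hinv <- crosspopgs:::h_inverse_ped(ped, A, ped$id)  # G* := A22 = A
  ss <- solve_mme(y, X, Z, Hinv, lam)
  expect_lt(max(abs(pb$u - ss$u)), 1e-8)
})

test_that("ssGBLUP uses ungenotyped relatives and beats nothing-at-stake PBLUP on genotyped accuracy", {
  st <- tiny_study(seed = 15)
  obs <- st$reference_ids[!is.na(st$phenotype[st$reference_ids])]
  dat <- data.frame(id = obs, y = st$phenotype[obs])
  gen_ids <- c(st$reference_ids, st$validation_ids)
  fit <- gsblup(y ~ 1, dat, genotypes = st$genotypes[gen_ids, ],
                pedigree = st$pedigree, method = "ssgblup",
                varcomp = varcomp_true(0.42, 0.58))
  expect_length(predict(fit), nrow(st$pedigree))
  expect_gt(accuracy(predict(fit, st$validation_ids),
                     st$tbv[st$validation_ids]), 0)
})

test_that("validation GEBV variance shrinks monotonically in lambda", {
  set.seed(4)
  M <- hwe_genotypes(80, 150, seed = 4)
  y <- rnorm(80)
  obs <- rownames(M)[1:60]
  G <- vanraden_grm(M)
  Z <- matrix(0, 60, 80); Z[cbind(1:60, 1:60)] <- 1
  vars <- sapply(c(0.1, 1, 10, 100), function(lam)
    var(solve_mme(y[1:60], matrix(1, 60, 1), Z, chol2inv(chol(G)),
                  lam)$u[61:80]))
  expect_true(all(diff(vars) < 0))
})

test_that("missing inputs are reported per method", {
  dat <- data.frame(id = c("a", "b", "c"), y = rnorm(3))
  expect_error(gsblup(y ~ 1, dat, method = "gblup"), "genotypes")
  expect_error(gsblup(y ~ 1, dat, method = "pblup"), "pedigree")
  M <- matrix(rbinom(30, 2, 0.5), 3, dimnames = list(c("a", "b", "x"), NULL))
  expect_error(gsblup(y ~ 1, dat, genotypes = M),
               "missing from the relationship")
  expect_error(gsblup(y ~ 1, dat[1:2, ], genotypes = M[1:2, ]),
               "fewer than 3")
})
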