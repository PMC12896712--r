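test_that("distances to the target centroid match a brute-force norm", {
  set.seed(1)
  cand <- matrix(sample(0:2, 12, replace = TRUE), 3, 4,
                 dimnames = list(c("c1", "c2", "c3"), NULL))
  tgt <- matrix(sample(0:2, 20, replace = TRUE), 5, 4)
  rk <- distance_to_target(cand, tgt, snp_subset = 1:4)
  centroid <- colMeans(tgt)
  oracle <- sapply(1:3, function(i) sqrt(sum((cand[i, ] - centroid)^2)))
  names(oracle) <- rownames(cand)
  expect_equal(rk$distance, unname(sort(oracle)), tolerance = 1e-12)
  expect_equal(rk$id, names(sort(oracle)))
})

test_that("degenerate distance cases behave", {
  tgt <- matrix(2, 4, 1)
  cand <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), NULL))
  rk <- distance_to_target(cand, tgt, 1)
  expect_equal(rk$distance[rk$id == "b"], 0)
  expect_equal(rk$distance[rk$id == "a"], 2)
  expect_error(distance_to_target(cand, tgt, integer()), "empty")
})

test_that("alternative aggregation modes rank sensibly", {
  set.seed(2)
  cand <- matrix(rbinom(40, 2, 0.5), 10, 4,
                 dimnames = list(paste0("c", 1:10), NULL))
  tgt <- matrix(rbinom(24, 2, 0.5), 6, 4)
  for (m in c("mean_pair", "min_pair")) {
    rk <- distance_to_target(cand, tgt, 1:4, aggregate = m)
    expect_equal(sort(rk$id), sort(rownames(cand)))
    expect_true(all(diff(rk$distance) >= 0))
  }
})

test_that("similarity selection floors k, keeps a minimum of one, and nests", {
  set.seed(3)
  rk <- distance_to_target(
    matrix(rbinom(100, 2, 0.5), 20, 5,
           dimnames = list(sprintf("c%02d", 1:20), NULL)),
    matrix(rbinom(25, 2, 0.5), 5, 5), 1:5)
  expect_length(select_similar(rk, 0.10), 2)
  expect_length(select_similar(rk, 0.01), 1)
  s10 <- select_similar(rk, 0.10)
  s15 <- select_similar(rk, 0.15)
  s20 <- select_similar(rk, 0.20)
  expect_true(all(s10 %in% s15) && all(s15 %in% s20))
  expect_error(select_similar(rk, 0), "fraction")
  # all-tied distances resolve by ascending id
  tied <- structure(data.frame(id = sprintf("c%02d", c(3, 1, 2)),
                               distance = c(1, 1, 1)),
                    class = c("distance_ranking", "data.frame"))
  tied <- tied[order(tied$distance, tied$id), ]
  expect_equal(select_similar(tied, 0.67), c("c01", "c02"))
})

test_that("scenario construction yields the stratified designs without leakage", {
  b <- desk_bundle()
  scen <- build_scenarios(b$A, b$B, b$C)
  expect_length(scen, 13)  # baseline + (cross + signal) x 2 donors x 3 fractions
  nm <- vapply(scen, `[[`, "", "name")
  expect_setequal(nm[vapply(scen, `[[`, "", "group") == "cross"],
                  c("A+10%B", "A+15%B", "A+20%B",
                    "A+10%C", "A+15%C", "A+20%C"))
  for (sc in scen) {
    expect_length(intersect(sc$reference_ids, sc$validation_ids), 0)
    expect_setequal(sc$validation_ids, b$A$validation_ids)
    if (sc$group == "cross")
      expect_true(all(b$A$reference_ids %in% sc$reference_ids))
  }
  # cross reference size = |A reference| + floor(fraction * donor candidates)
  sc10B <- scen[[which(nm == "A+10%B")]]
  expect_length(sc10B$reference_ids,
                length(b$A$reference_ids) +
                  floor(0.10 * length(b$B$reference_ids)))
  # selected donors are closer than every unselected donor
  rkB <- distance_to_target(b$B$genotypes[b$B$reference_ids, ],
                            b$A$genotypes[b$A$reference_ids, ],
                            sc10B$snp_subset)
  sel <- setdiff(sc10B$reference_ids, b$A$reference_ids)
  dmax_sel <- max(rkB$distance[rkB$id %in% sel])
  dmin_un <- min(rkB$distance[!rkB$id %in% sel])
  expect_lte(dmax_sel, dmin_un)
  # rebuilding gives identical id sets
  scen2 <- build_scenarios(b$A, b$B, b$C)
  expect_identical(lapply(scen, `[[`, "reference_ids"),
                   lapply(scen2, `[[`, "reference_ids"))
})

test_that("a full donor fraction takes the whole donor reference generation", {
  b <- desk_bundle()
  scen <- build_scenarios(b$A, b$B, fractions = 1.0, baseline = FALSE)
  cross <- scen[[which(vapply(scen, `[[`, "", "group") == "cross")]]
  expect_setequal(cross$reference_ids,
                  c(b$A$reference_ids, b$B$reference_ids))
})
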