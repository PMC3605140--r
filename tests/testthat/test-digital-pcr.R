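# Hypergeometric zero-well model: copy accounting, P0, tabulation,
# exact binomial CIs, pooling and rate comparison.

test_that("mass-to-copies conversion matches the assay design", {
  del <- copiesFromMass(50)
  expect_equal(del$perWell, 16667)
  expect_equal(del$perPlate / 1.6e6, 1, tolerance = 1e-4)
  dup <- copiesFromMass(100)
  expect_equal(dup$perPlate / 3.2e6, 1, tolerance = 1e-4)
  expect_equal(copiesFromMass(0.003, wellsPerPlate = 1)$perWell, 1)
  expect_error(copiesFromMass(-1), "positive")
})

test_that("pZero is exact on enumerable instances and near the closed form", {
  # tiny instance: enumerate all C(10, 2) two-slot draws
  expect_equal(pZero(3, N = 10, W = 2), enumeratePZero(10, 2, 3))
  expect_equal(pZero(3, N = 10, W = 2), choose(7, 2) / choose(10, 2))
  for (R in 0:7)
    expect_equal(pZero(R, N = 9, W = 3), enumeratePZero(9, 3, R))
  # boundary behaviour
  expect_identical(pZero(0, N = 1e6, W = 100), 1)
  expect_equal(pZero(8, N = 10, W = 2), 1 / choose(10, 2))  # R = N - W
  expect_equal(pZero(9, N = 10, W = 2), 0)                  # R > N - W
  expect_error(pZero(-1, N = 10, W = 2), "non-negative")
  # plate-scale value against the (1 - W/N)^R first-order form
  N <- 1.6e6; W <- N / 96
  expect_equal(pZero(30, N = N, W = W), (1 - 1 / 96)^30, tolerance = 1e-4)
})

test_that("pZero is strictly decreasing in R", {
  p <- pZero(0:500, N = 1.6e6, W = 1.6e6 / 96)
  expect_true(all(diff(p) < 0))
})

test_that("P0 matches the with-replacement form at plate scale and the Poisson limit", {
  # sampling without replacement is indistinguishable from the
  # with-replacement closed form (1 - W/N)^R at plate scale
  N <- 1.6e6; W <- N / 96
  R <- 1:200
  closedForm <- (1 - W / N)^R
  expect_true(all(abs(pZero(R, N = N, W = W) - closedForm) /
                    closedForm < 1e-3))
  # Poisson limit: at fixed per-well load R*W/N = 1 and fixed W, the
  # deviation from exp(-R W / N) vanishes as the pool N grows
  poisErr <- function(wells) {
    W <- 16667; N <- W * wells; R <- wells
    abs(pZero(R, N = N, W = W) - exp(-1)) / exp(-1)
  }
  errs <- vapply(c(96, 960, 9600), poisErr, 0.0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("tabulation reproduces all per-donor and pooled recombinant counts", {
  # deletion assay: 50 ng/well, N = 1.6e6 per plate
  delPlates <- lapply(c(26, 25, 23), PlateResult,
                      wellsTotal = 96, copiesTotal = 1.6e6)
  expect_equal(vapply(delPlates,
                      function(p) recombinants(estimateRecombinants(p)), 0L),
               c(30L, 29L, 26L))
  # duplication assay: 100 ng/well, N = 3.2e6 per plate
  dupPlates <- lapply(c(23, 20, 22), PlateResult,
                      wellsTotal = 96, copiesTotal = 3.2e6)
  expect_equal(vapply(dupPlates,
                      function(p) recombinants(estimateRecombinants(p)), 0L),
               c(26L, 22L, 25L))
  # pooling re-tabulates on the pooled negative fraction; for the
  # duplication assay this gives 74, one more than the per-donor sum 73
  delPool <- poolPlates(delPlates)
  expect_equal(wellsPositive(delPool), 74L)
  expect_equal(copiesTotal(delPool), 4.8e6)
  expect_equal(recombinants(estimateRecombinants(delPool)), 85L)
  dupPool <- poolPlates(dupPlates)
  rPooled <- recombinants(estimateRecombinants(dupPool))
  expect_equal(rPooled, 74L)
  expect_equal(rPooled - sum(26L, 22L, 25L), 1L)  # exceeds per-plate sum
})

test_that("tabulation handles edge plates and rejects saturation", {
  expect_equal(recombinants(estimateRecombinants(PlateResult(96, 0, 1.6e6))),
               0L)
  expect_error(estimateRecombinants(PlateResult(96, 96, 1.6e6)),
               "saturated")
})

test_that("estimated R is monotone non-decreasing in positive wells", {
  r <- vapply(0:95, function(wp)
    recombinants(estimateRecombinants(PlateResult(96, wp, 1.6e6))), 0L)
  expect_true(all(diff(r) >= 0))
})

test_that("tabulation equals brute-force enumeration on small plates", {
  # N = 12, three wells of W = 4: P0 by explicit draw enumeration
  N <- 12; wt <- 3; W <- N / wt
  p0 <- vapply(0:(N - W), function(R) enumeratePZero(N, W, R), 0.0)
  for (wp in 0:(wt - 1)) {
    brute <- which.min(abs(p0 - (wt - wp) / wt)) - 1L
    est <- recombinants(estimateRecombinants(PlateResult(wt, wp, N)))
    expect_equal(est, brute)
  }
})

test_that("rate CIs match the printed table and the beta-quantile oracle", {
  est <- rateCI(estimateRecombinants(PlateResult(96, 26, 1.6e6)))
  expect_equal(rateValue(est), 30 / 1.6e6)
  expect_equal(unname(signif(rateCIBounds(est), 2)), c(1.3e-5, 2.7e-5))
  # independent Clopper-Pearson route
  ci <- rateCI(85, N = 4.8e6)
  expect_equal(unname(rateCIBounds(ci)), betaCI(85, 4.8e6),
               tolerance = 1e-3)
  # zero count: one-sided at zero
  z <- rateCI(0, N = 1e6)
  expect_equal(unname(rateCIBounds(z))[1], 0)
  expect_error(rateCI(est, level = 1.5), "level")
})

test_that("pooling requires a shared per-well copy number", {
  expect_error(poolPlates(list(PlateResult(96, 10, 1.6e6),
                               PlateResult(96, 10, 3.2e6))),
               "different copies-per-well")
  # identity on a single plate
  p <- PlateResult(96, 10, 1.6e6)
  expect_equal(poolPlates(list(p)), p)
})

test_that("rate comparison recovers the deletion/duplication enrichment", {
  del <- rateCI(estimateRecombinants(PlateResult(288, 74, 4.8e6)))
  dup <- rateCI(estimateRecombinants(PlateResult(288, 65, 9.6e6)))
  cmp <- compareRates(del, dup)
  expect_equal(cmp$ratio, (85 / 4.8e6) / (74 / 9.6e6))
  expect_equal(round(cmp$ratio, 1), 2.3)
  expect_lt(cmp$pValue, 0.05)
  # identical estimates: ratio 1, no signal
  same <- compareRates(del, del)
  expect_equal(same$ratio, 1)
  expect_gt(same$pValue, 0.9)
  # zero denominator rate is reported as undefined
  z <- rateCI(0, N = 1e6)
  expect_true(is.na(compareRates(del, z)$ratio))
})

test_that("rate comparison holds its nominal type-I error on equal-rate plates", {
  cfg <- simConfig(seed = 7)
  rej <- vapply(1:400, function(i) {
    a <- estimateRecombinants(simulatePlate(cfg, "deletion",
                                            replicate = i)$plate)
    b <- estimateRecombinants(simulatePlate(cfg, "deletion",
                                            replicate = 10000 + i)$plate)
    compareRates(a, b)$pValue < 0.05
  }, TRUE)
  expect_lt(mean(rej), 0.09)  # ~0.05 nominal; exact test is discrete
  expect_gt(mean(rej), 0.01)
})

test_that("plate summaries round-trip through TSV", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("plate_id\tassay\twells_total\twells_positive\tmass_per_well_ng",
               "A\tdeletion\t96\t26\t50",
               "A\tduplication\t96\t23\t100"), tsv)
  d <- readPlateSummary(tsv)
  plates <- attr(d, "plates")
  expect_equal(d$copies_total / c(1.6e6, 3.2e6), c(1, 1), tolerance = 1e-4)
  expect_equal(recombinants(estimateRecombinants(plates[[1]])), 30L)
  unlink(tsv)
})
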