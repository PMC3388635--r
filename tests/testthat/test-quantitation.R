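test_that("voxel volume converts spacing products to millilitres", {
  expect_equal(voxelVolumeMl(c(1, 1, 1)), 0.001)
  expect_equal(voxelVolumeMl(c(0.5, 0.5, 10)), 0.0025)
  expect_equal(voxelVolumeMl(c(0.7, 0.7, 5)), 0.00245)
  expect_error(voxelVolumeMl(c(0, 1, 1)), "positive")
  expect_error(voxelVolumeMl(c(1, 1)), "positive")
})

test_that("compartment classification follows the integer HU bands", {
  expect_equal(as.character(compartmentOf(c(-950, -500, -100, 0))),
               c("hyper", "poor", "non", "non"))
  # closed-range boundaries on both sides of every band edge
  expect_equal(as.character(compartmentOf(c(-1000, -901, -900, -501,
                                            -500, -101, -100, 100))),
               c("hyper", "hyper", "normal", "normal",
                 "poor", "poor", "non", "non"))
  # out of window: signalled as NA for the caller to exclude
  expect_true(is.na(compartmentOf(150)))
  expect_true(is.na(compartmentOf(-1001)))
})

test_that("classification rounds to integers with ties away from zero", {
  expect_equal(as.character(compartmentOf(-100.4)), "non")
  expect_equal(as.character(compartmentOf(-100.5)), "poor")
  expect_equal(as.character(compartmentOf(-500.5)), "normal")
  expect_equal(as.character(compartmentOf(-500.49)), "poor")
  expect_equal(as.character(compartmentOf(100.4)), "non")
  expect_true(is.na(compartmentOf(100.5)))
  expect_true(is.na(compartmentOf(-1000.6)))
  expect_equal(as.character(compartmentOf(-1000.4)), "hyper")
})

test_that("density and gas fraction follow the linear mixture model", {
  expect_equal(tissueDensity(-1000), 0)
  expect_equal(tissueDensity(0), 1)
  expect_equal(tissueDensity(-500), 0.5)
  expect_equal(tissueDensity(100), 1.1)
  expect_error(tissueDensity(150), "HU")
  expect_equal(gasFraction(-1000), 1)
  expect_equal(gasFraction(0), 0)
  expect_equal(gasFraction(50), 0)
  expect_equal(gasFraction(-250), 0.25)
  expect_error(gasFraction(-1001), "HU")
})

test_that("a two-voxel slice decomposes into gas and tissue as expected", {
  # two 1-ml voxels at -1000 (pure gas) and 0 HU (water-equivalent tissue)
  g <- toyGrid(list(matrix(c(-1000, 0, 500, 500), 2, 2)))
  m <- LungMask(array(c(TRUE, TRUE, FALSE, FALSE), dim = c(2, 2, 1)))
  q <- sliceQuantities(g, m, 1)
  expect_equal(q$V, 2)
  expect_equal(q$M, 1)
  expect_equal(q$Vgas, 1)
  expect_equal(q$V_hyper, 1)
  expect_equal(q$V_non, 1)
  expect_equal(q$M_non, 1)
  expect_equal(q$M_hyper, 0)
  expect_equal(q$nVoxels, 2L)
  expect_equal(q$nExcluded, 0L)
})

test_that("member voxels outside the HU window are excluded and counted", {
  g <- toyGrid(list(matrix(c(-700, 150, -1050, 90), 2, 2)))
  m <- fullMask(g)
  q <- sliceQuantities(g, m, 1)
  expect_equal(q$nVoxels, 2L)
  expect_equal(q$nExcluded, 2L)
  expect_equal(q$V, 2)
})

test_that("slices with no member voxels yield all-zero quantities", {
  g <- toyGrid(list(-700, -700, -700))
  mem <- array(TRUE, dim = dim(g))
  mem[, , 2] <- FALSE
  p <- sliceProfile(g, LungMask(mem))
  expect_equal(p$V, c(4, 0, 4))
  expect_equal(p$M[2], 0)
  expect_equal(p$nVoxels[2], 0L)
})

test_that("slice volume is conserved: V = included voxels x voxel volume", {
  toy <- randomToy(11)
  p <- sliceProfile(toy$grid, toy$mask)
  vv <- voxelVolumeMl(gridSpacing(toy$grid))
  expect_equal(p$V, p$nVoxels * vv)
})

test_that("slice bucketing matches a voxel-by-voxel brute-force loop", {
  for (seed in c(1, 7, 23)) {
    toy <- randomToy(seed)
    got <- sliceProfile(toy$grid, toy$mask)
    want <- bruteForceProfile(toy$grid, toy$mask)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("compartments tile the totals at slice and lung level", {
  toy <- randomToy(5)
  p <- sliceProfile(toy$grid, toy$mask)
  expect_equal(p$V, p$V_non + p$V_poor + p$V_normal + p$V_hyper,
               tolerance = 1e-12)
  expect_equal(p$M, p$M_non + p$M_poor + p$M_normal + p$M_hyper,
               tolerance = 1e-12)
  s <- wholeLungSummary(p)
  expect_equal(sum(compartmentPct(s, "volume")), 100, tolerance = 1e-9)
  expect_equal(sum(compartmentPct(s, "mass")), 100, tolerance = 1e-9)
  expect_true(all(p$Vgas >= 0 & p$Vgas <= p$V + 1e-12))
})

test_that("whole-lung summary aggregates absolute quantities", {
  g <- toyGrid(list(matrix(c(-1000, 0, 500, 500), 2, 2)))
  m <- LungMask(array(c(TRUE, TRUE, FALSE, FALSE), dim = c(2, 2, 1)))
  s <- wholeLungSummary(sliceProfile(g, m))
  expect_equal(vTotal(s), 2)
  expect_equal(mTotal(s), 1)
  expect_equal(vGas(s), 1)
  expect_equal(vGas(s, percent = TRUE), 50)
  expect_equal(compartmentPct(s)[["hyper"]], 50)
  expect_equal(compartmentPct(s)[["non"]], 50)
})

test_that("whole-lung totals are additive over identical slices", {
  k <- 6
  g <- toyGrid(rep(list(-700), k))
  s <- wholeLungSummary(sliceProfile(g, fullMask(g)))
  expect_equal(vTotal(s), k * 4) # 4 one-ml voxels per slice
})

test_that("permuting slice rows does not change whole-lung totals", {
  toy <- randomToy(9)
  p <- sliceProfile(toy$grid, toy$mask)
  set.seed(1)
  perm <- p[sample(nrow(p)), ]
  expect_summary_equal(wholeLungSummary(p), wholeLungSummary(perm), 1e-12)
})

test_that("mass equals total minus gas volume for sub-water attenuation", {
  # under the linear mixture model, M = V - Vgas exactly when all HU <= 0
  set.seed(4)
  g <- toyGrid(lapply(1:4, function(k) matrix(runif(4, -1000, 0), 2, 2)))
  s <- wholeLungSummary(sliceProfile(g, fullMask(g)))
  expect_equal(mTotal(s), vTotal(s) - vGas(s), tolerance = 1e-12)
})

test_that("empty lungs are rejected", {
  g <- toyGrid(list(-700))
  m <- LungMask(array(FALSE, dim = dim(g)))
  expect_error(wholeLungSummary(sliceProfile(g, m)), "empty lung")
})

test_that("grid/mask shape mismatch is a hard error", {
  g <- toyGrid(list(-700, -700))
  m <- LungMask(array(TRUE, dim = c(2, 2, 3)))
  expect_error(sliceProfile(g, m), "does not match")
})

test_that("metricValue exposes every reported metric", {
  g <- toyGrid(list(matrix(c(-1000, 0, 500, 500), 2, 2)))
  m <- LungMask(array(c(TRUE, TRUE, FALSE, FALSE), dim = c(2, 2, 1)))
  s <- wholeLungSummary(sliceProfile(g, m))
  expect_equal(metricValue(s, "V_total"), 2)
  expect_equal(metricValue(s, "pct_V_hyper"), 50)
  expect_equal(metricValue(s, "pct_M_non"), 100)
  expect_equal(metricValue(s, "V_gas_pct"), 50)
  expect_error(metricValue(s, "nope"))
})
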