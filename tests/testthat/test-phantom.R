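# Smaller-than-default target volumes / coarser in-plane spacing are used in
# some blocks purely to keep the grids small; both are ordinary spec
# parameters.

test_that("a noise-free gradient-free phantom is single-compartment", {
  sp <- phantomSpec("sheep_normal", targetVTotalMl = 1200,
                    atelectasisFraction = 0, noiseSdHu = 0,
                    gradientSlopeHuPerMm = 0, inPlaneMm = 2, seed = 1)
  ph <- generatePhantom(sp)
  hu <- gridValues(ph$grid)[maskArray(ph$mask)]
  expect_equal(unique(hu), -700)
  expect_equal(compartmentPct(ph$truth)[["normal"]], 100)
  s <- wholeLungSummary(sliceProfile(ph$grid, ph$mask))
  expect_equal(compartmentPct(s)[["normal"]], 100)
})

test_that("lung-bearing slices number ceil(height / thickness)", {
  sp <- phantomSpec("sheep_normal", lungHeightMm = 278, inPlaneMm = 2,
                    targetVTotalMl = 1500, seed = 2)
  ph <- generatePhantom(sp)
  p <- sliceProfile(ph$grid, ph$mask)
  ext <- lungExtent(p)
  expect_equal(ext[["last"]] - ext[["first"]] + 1L, 28L) # ceil(278/10)
  # and an integer-ratio case
  sp2 <- phantomSpec("pig_normal", lungHeightMm = 300, sliceThicknessMm = 5,
                     inPlaneMm = 2, targetVTotalMl = 1200, seed = 2)
  p2 <- sliceProfile(generatePhantom(sp2)$grid, generatePhantom(sp2)$mask)
  ext2 <- lungExtent(p2)
  expect_equal(ext2[["last"]] - ext2[["first"]] + 1L, 60L)
})

test_that("phantom generation is seed-deterministic", {
  sp <- phantomSpec("pig_opacified", targetVTotalMl = 900, inPlaneMm = 2,
                    seed = 11)
  a <- generatePhantom(sp)
  b <- generatePhantom(sp)
  expect_identical(gridValues(a$grid), gridValues(b$grid))
  expect_identical(maskArray(a$mask), maskArray(b$mask))
  sp2 <- sp; sp2@seed <- 12L
  c <- generatePhantom(sp2)
  expect_false(identical(gridValues(a$grid), gridValues(c$grid)))
  # same mask geometry, different noise
  expect_identical(maskArray(a$mask), maskArray(c$mask))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generatePhantom(phantomSpec("pig_normal", targetVTotalMl = 800,
                                        inPlaneMm = 2.5, seed = 5)))
  expect_identical(runif(1), before)
})

test_that("whole-lung analysis recovers the constructive ground truth", {
  for (preset in c("sheep_opacified", "pig_normal")) {
    ph <- generatePhantom(phantomSpec(preset, targetVTotalMl = 1400,
                                      inPlaneMm = 1.5, seed = 21))
    s <- wholeLungSummary(sliceProfile(ph$grid, ph$mask))
    expect_summary_equal(s, ph$truth, 1e-9)
  }
})

test_that("the atelectasis fraction lands in the nonaerated compartment", {
  ph <- generatePhantom(phantomSpec("sheep_opacified", targetVTotalMl = 1500,
                                    atelectasisFraction = 0.25,
                                    inPlaneMm = 1.5, seed = 31))
  expect_equal(compartmentPct(ph$truth)[["non"]], 25, tolerance = 0.01)
  # dependent: atelectatic voxels are the dorsal-most ones
  idx <- which(maskArray(ph$mask))
  hu <- gridValues(ph$grid)[idx]
  ny <- dim(ph$grid)[2]
  nx <- dim(ph$grid)[1]
  iy <- ((idx - 1) %/% nx) %% ny + 1
  expect_gt(mean(iy[hu >= -100]), mean(iy[hu < -100]))
})

test_that("cohorts stay inside their preset ranges and reproduce", {
  n <- 10
  coh <- generateCohort(n, "sheep_normal", seed = 17, inPlaneMm = 1.5)
  v <- vapply(coh, function(p) vTotal(p$truth), 0)
  non <- vapply(coh, function(p) compartmentPct(p$truth)[["non"]], 0)
  expect_true(all(v >= 2245 & v <= 5638))
  expect_true(all(non <= 0.8))
  expect_true(stats::median(v) >= 2245 && stats::median(v) <= 5638)
  coh2 <- generateCohort(n, "sheep_normal", seed = 17, inPlaneMm = 1.5)
  v2 <- vapply(coh2, function(p) vTotal(p$truth), 0)
  expect_identical(v, v2)
  expect_error(generateCohort(3, "goat_normal", seed = 1), "unknown preset")
})

test_that("a zero recruitment delta yields an identical pair", {
  sp <- phantomSpec("sheep_opacified", targetVTotalMl = 1200,
                    inPlaneMm = 2, seed = 41)
  pr <- generateRecruitmentPair(sp, list(recruit = 0, inflate = 0))
  expect_identical(gridValues(pr$t1$grid), gridValues(pr$t2$grid))
  expect_true(all(pr$truthDelta == 0))
})

test_that("full recruitment clears the nonaerated compartment", {
  sp <- phantomSpec("sheep_opacified", targetVTotalMl = 1200,
                    atelectasisFraction = 0.3, inPlaneMm = 2, seed = 43)
  pr <- generateRecruitmentPair(sp, list(recruit = 1, inflate = 0.2))
  expect_equal(compartmentPct(pr$t1$truth)[["non"]], 30, tolerance = 0.05)
  expect_lt(compartmentPct(pr$t2$truth)[["non"]], 0.1)
  expect_gt(pr$truthDelta[["V_total"]], 0)
  expect_error(generateRecruitmentPair(sp, list(recruit = 1.5, inflate = 0)),
               "recruit")
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantomSpec("goat_normal"), "unknown preset")
  expect_error(phantomSpec("sheep_normal", lungHeightMm = 400), "218-320")
  expect_error(phantomSpec("sheep_normal", sliceThicknessMm = 3), "one of")
  expect_error(phantomSpec("sheep_normal", atelectasisFraction = 0.7),
               "0, 0.6")
  expect_error(phantomSpec("sheep_normal", noiseSdHu = -1), "non-negative")
})
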