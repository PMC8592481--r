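.seg_from <- function(void) new("VoidSegmentation", voidMap = void,
                                source = "test", params = list())

test_that("connected components respect 8-connectivity and separation", {
  void <- matrix(FALSE, 40, 40)
  void[5:14, 5:14] <- TRUE
  void[5:14, 20:29] <- TRUE
  comps <- labelFlowVoids(.seg_from(void))
  expect_equal(nComponents(comps), 2L)
  expect_equal(sort(componentAreas(comps)), c(100L, 100L))

  diag2 <- matrix(FALSE, 10, 10)
  diag2[cbind(2:5, 2:5)] <- TRUE  # diagonal chain: one component under 8-conn
  expect_equal(nComponents(labelFlowVoids(.seg_from(diag2))), 1L)
})

test_that("voids inside the exclusion mask vanish; straddlers are clipped", {
  void <- matrix(FALSE, 60, 60)
  void[25:34, 25:34] <- TRUE  # centered square, inside the FAZ disc
  faz <- buildExclusionMask(matrix(0.1, 60, 60), pixel_pitch = 10,
                            faz_radius_um = 120, caliber_cutoff_um = Inf)
  comps <- labelFlowVoids(.seg_from(void), faz)
  expect_equal(nComponents(comps), 0L)

  void2 <- matrix(FALSE, 60, 60)
  void2[28:33, 5:55] <- TRUE  # band crossing the disc: clipped, not dropped
  comps2 <- labelFlowVoids(.seg_from(void2), faz)
  expect_gt(nComponents(comps2), 0L)
  expect_lt(sum(componentAreas(comps2)), sum(void2))
})

test_that("metrics arithmetic: areas, mean size, counts, scaling", {
  void <- matrix(FALSE, 50, 50)
  void[11:20, 11:20] <- TRUE
  m <- flowVoidMetrics(labelFlowVoids(.seg_from(void)), pixel_pitch = 10)
  expect_equal(m@voidCount, 1L)
  expect_equal(m@totalArea, 0.01)
  expect_equal(m@meanSize, 10000)

  # k identical components: mean size invariant, total area proportional
  void3 <- matrix(FALSE, 50, 50)
  for (o in c(1, 13, 25, 37)) void3[o:(o + 4), 1:5] <- TRUE
  m3 <- flowVoidMetrics(labelFlowVoids(.seg_from(void3)), pixel_pitch = 10)
  expect_equal(m3@voidCount, 4L)
  expect_equal(m3@meanSize, 2500)
  expect_equal(m3@totalArea, 4 * 25 * 100 / 1e6)
})

test_that("zero components give zero count and missing mean size", {
  m <- flowVoidMetrics(labelFlowVoids(.seg_from(matrix(FALSE, 10, 10))),
                       pixel_pitch = 10)
  expect_equal(m@voidCount, 0L)
  expect_equal(m@totalArea, 0)
  expect_true(is.na(m@meanSize))
})

test_that("min_void_px discards speckle-sized components", {
  void <- matrix(FALSE, 20, 20)
  void[2, 2] <- TRUE
  void[10:12, 10:12] <- TRUE
  expect_equal(nComponents(labelFlowVoids(.seg_from(void), min_void_px = 1L)), 2L)
  expect_equal(nComponents(labelFlowVoids(.seg_from(void), min_void_px = 2L)), 1L)
})

test_that("void and vessel pixels partition the analyzable region", {
  gt <- fx_gt()
  seg <- phansalkarBinarize(gt@pristineIntensity, phansalkarParams())
  mask <- buildExclusionMask(matrix(0.1, 160, 160), pixel_pitch = 10,
                             faz_radius_um = 250, caliber_cutoff_um = Inf)
  excl <- excludedPixels(mask)
  void_px <- sum(voidMap(seg) & !excl)
  vessel_px <- sum(invertToVessels(seg) & !excl)
  expect_equal(void_px + vessel_px, sum(!excl))
})

test_that("VDI of rectangular bands tracks their width", {
  canvas <- matrix(FALSE, 40, 220)
  b1 <- canvas; b1[20, 11:210] <- TRUE          # 1 px wide: skeleton = band
  expect_equal(vesselDiameterIndex(b1), 1.0)
  b5 <- canvas; b5[18:22, 11:210] <- TRUE       # 5 px wide, 200 long
  v5 <- vesselDiameterIndex(b5)
  expect_lt(abs(v5 - 5) / 5, 0.05)
  b10 <- canvas; b10[14:23, 11:210] <- TRUE     # doubled width
  v10 <- vesselDiameterIndex(b10)
  expect_lt(abs(v10 - 2 * v5) / (2 * v5), 0.05)
})

test_that("VDI is undefined on an empty vessel map", {
  expect_error(vesselDiameterIndex(matrix(FALSE, 10, 10)), "undefined")
  v <- matrix(TRUE, 20, 20)
  expect_error(vesselDiameterIndex(v, matrix(TRUE, 20, 20)), "undefined")
})

test_that("skeleton is a thin subset of the vessel map", {
  gt <- fx_gt()
  sk <- skeletonize(gt@perfusionMap)
  expect_true(all(gt@perfusionMap[sk]))
  expect_lt(sum(sk), 0.6 * sum(gt@perfusionMap))
})

test_that("dimension mismatches error", {
  seg <- .seg_from(matrix(FALSE, 10, 10))
  mask <- buildExclusionMask(matrix(0.1, 12, 12), faz_radius_um = 0)
  expect_error(labelFlowVoids(seg, mask), "dimensions differ")
  expect_error(vesselDiameterIndex(matrix(TRUE, 10, 10), mask), "dimensions differ")
})
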