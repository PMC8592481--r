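test_that("calibrated meshwork hits the void-fraction target", {
  for (vf in c(0.10, 0.18, 0.30)) {
    gt <- fx_gt(vf = vf)
    realized <- mean(gt@trueVoidMask)
    expect_lt(abs(realized - vf) / vf, 0.10,
              label = sprintf("realized void fraction at target %.2f", vf))
    m <- trueMetrics(gt)
    # exact identity: total area is the void pixel count times pixel area
    expect_equal(m@totalArea, sum(gt@trueVoidMask) * pixelPitch(gt)^2 / 1e6)
    expect_equal(m@meanSize * m@voidCount, m@totalArea * 1e6,
                 tolerance = 1e-9)
  }
})

test_that("meshwork generation is deterministic and seed-sensitive", {
  p <- meshworkParams(grid_size = 96L)
  a <- simulateMeshwork(p, seed = 4)
  b <- simulateMeshwork(p, seed = 4)
  d <- simulateMeshwork(p, seed = 5)
  expect_identical(a@perfusionMap, b@perfusionMap)
  expect_identical(a@pristineIntensity, b@pristineIntensity)
  expect_false(identical(a@trueVoidMask, d@trueVoidMask))
})

test_that("saturating vessel width perfuses the whole grid gracefully", {
  gt <- simulateMeshwork(meshworkParams(grid_size = 96L, vessel_width = 1e5),
                         seed = 1)
  expect_equal(mean(gt@trueVoidMask), 0)
  expect_equal(trueMetrics(gt)@voidCount, 0L)
  expect_equal(trueMetrics(gt)@totalArea, 0)
  expect_true(is.na(trueMetrics(gt)@meanSize))
})

test_that("perfusion map and void mask are complementary", {
  gt <- fx_gt()
  expect_false(any(gt@trueVoidMask & gt@perfusionMap))
  expect_true(all(gt@trueVoidMask | gt@perfusionMap))
})

test_that("noiseless acquisition reproduces the pristine image exactly", {
  gt <- fx_gt()
  st <- simulateFrameStack(gt,
                           acquisitionParams(n_frames = 4, speckle_sigma = 0,
                                             dropout_prob = 0, max_shift = 0,
                                             psf_sigma = 0),
                           seed = 9)
  for (i in 1:4)
    expect_equal(intensity(st@cc[[i]]), gt@pristineIntensity)
})

test_that("injected shifts respect the bound and frame 1 is the anchor", {
  st <- fx_stack(max_shift = 6)
  expect_equal(st@trueShifts$dx[1], 0)
  expect_equal(st@trueShifts$dy[1], 0)
  expect_true(all(abs(st@trueShifts$dx) <= 6))
  expect_true(all(abs(st@trueShifts$dy) <= 6))
})

test_that("heavy dropout makes a single frame over-read the void area", {
  gt <- fx_gt()
  st <- simulateFrameStack(gt,
                           acquisitionParams(n_frames = 4, dropout_prob = 0.4,
                                             max_shift = 0),
                           seed = 13)
  naive <- mean(voidMap(phansalkarBinarize(intensity(st@cc[[1]]),
                                           phansalkarParams())))
  truth <- mean(gt@trueVoidMask)
  expect_gt(naive, 1.5 * truth)
})

test_that("per-frame naive void estimate decreases toward truth with N", {
  gt <- fx_gt()
  st <- simulateFrameStack(gt, acquisitionParams(n_frames = 9, max_shift = 0,
                                                 dropout_prob = 0.2),
                           seed = 17)
  est <- vapply(c(1, 4, 9), function(n) {
    avg <- Reduce(`+`, lapply(st@cc[1:n], intensity)) / n
    mean(voidMap(phansalkarBinarize(avg, phansalkarParams())))
  }, 0)
  truth <- mean(gt@trueVoidMask)
  expect_true(all(diff(est) < 0))
  expect_true(all(est > truth))
  expect_lt(abs(est[3] - truth), abs(est[1] - truth))
})

test_that("ground truth writes to TIFF plus JSON sidecar", {
  gt <- simulateMeshwork(meshworkParams(grid_size = 96L), seed = 2)
  dir <- withr::local_tempdir()
  writeGroundTruth(gt, dir, prefix = "t")
  expect_true(file.exists(file.path(dir, "t_perfusion.tif")))
  side <- jsonlite::read_json(file.path(dir, "t_metrics.json"))
  expect_equal(side$void_count, trueMetrics(gt)@voidCount)
  mask <- readBinaryMap(file.path(dir, "t_perfusion.tif"))
  expect_identical(mask, gt@perfusionMap)
})
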