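test_that("quality gating retains passing frames and preserves pairing", {
  st <- fx_flat_stack(scores = rep(10L, 9))
  out <- filterFrames(st, min_quality = 8L)
  expect_false(isExcluded(out))
  expect_equal(nFrames(out), 9L)

  st2 <- fx_flat_stack(scores = c(9L, 9L, 8L, 7L, 6L))
  out2 <- filterFrames(st2, min_quality = 8L)
  expect_true(isExcluded(out2))
  expect_match(out2$reason, "3 of 5")

  # artifact-flagged frames are dropped even at high score
  frames <- list(fx_flat_frame(score = 10L, artifact = TRUE),
                 fx_flat_frame(score = 9L), fx_flat_frame(score = 9L),
                 fx_flat_frame(score = 8L), fx_flat_frame(score = 8L))
  st3 <- FrameStack(frames, frames, eyeId = "a")
  out3 <- filterFrames(st3, min_quality = 8L)
  expect_false(isExcluded(out3))
  expect_equal(nFrames(out3), 4L)
  expect_equal(length(out3@scp), 4L)
})

test_that("registration of an unshifted stack is the identity", {
  gt <- fx_gt()
  st <- simulateFrameStack(gt, acquisitionParams(n_frames = 5, max_shift = 0),
                           seed = 31)
  reg <- registerStack(st, pipelineConfig())
  tr <- registrationTransforms(reg)
  expect_true(all(abs(tr$dx) < 0.1))
  expect_true(all(abs(tr$dy) < 0.1))
})

test_that("registration recovers injected shifts up to 8 px within 0.5 px", {
  gt <- fx_gt()
  st <- simulateFrameStack(gt, acquisitionParams(n_frames = 7, max_shift = 8),
                           seed = 33)
  reg <- registerStack(st, pipelineConfig())
  tr <- registrationTransforms(reg)
  expect_equal(nrow(tr), 7)
  expect_lt(max(abs(tr$dx - reg@trueShifts$dx)), 0.5)
  expect_lt(max(abs(tr$dy - reg@trueShifts$dy)), 0.5)
})

test_that("a structureless frame fails the registration floor and is dropped", {
  gt <- fx_gt()
  st <- simulateFrameStack(gt, acquisitionParams(n_frames = 5, max_shift = 2),
                           seed = 35)
  noise <- withr::with_seed(1, matrix(stats::runif(160 * 160), 160, 160))
  st@cc[[3]] <- EnFaceFrame(noise, 10)
  st@scp[[3]] <- EnFaceFrame(noise, 10)
  expect_warning(reg <- registerStack(st, pipelineConfig()), "registration score")
  expect_false(isExcluded(reg))
  expect_equal(nFrames(reg), 4L)
  expect_false(3 %in% registrationTransforms(reg)$frame)
})

test_that("averaging is idempotent on identical frames and exact on 0/1 pairs", {
  img <- fx_gt()@pristineIntensity
  fr <- EnFaceFrame(img, 10)
  st <- FrameStack(rep(list(fr), 5), rep(list(fr), 5))
  avg <- averageStack(st)
  expect_equal(intensity(avg), img)
  expect_equal(nFrames(avg), 5L)

  z <- EnFaceFrame(matrix(0, 16, 16)); o <- EnFaceFrame(matrix(1, 16, 16))
  st2 <- FrameStack(list(z, o), list(z, o))
  avg2 <- averageStack(st2, min_frames = 2L)
  expect_true(all(intensity(avg2) == 0.5))

  expect_error(averageStack(FrameStack(list(z, o, z), list(z, o, z))),
               "at least 4")
})

test_that("averaging is permutation-invariant over frames", {
  st <- fx_stack()
  perm <- c(4, 1, 6, 2, 5, 3)
  st_p <- FrameStack(st@cc[perm], st@scp[perm], eyeId = st@eyeId)
  st_o <- FrameStack(st@cc, st@scp, eyeId = st@eyeId)
  expect_equal(intensity(averageStack(st_p)), intensity(averageStack(st_o)))
})

test_that("register-then-average reproduces a shifted smooth image", {
  # shifted copies (reflect-padded crops, bilinear subpixel shifts <= 8 px)
  # of one smooth field must come back within interpolation tolerance
  img <- withr::with_seed(41, {
    x <- EBImage::gblur(matrix(stats::runif(160 * 160), 160, 160), sigma = 4)
    0.1 + 0.8 * (x - min(x)) / diff(range(x))
  })
  pad <- 10L
  padded <- CCvoid:::.reflect_pad(img, pad)
  ctr <- pad + seq_len(160)
  shifts <- withr::with_seed(42, matrix(stats::runif(12, -8, 8), ncol = 2))
  shifts[1, ] <- 0
  frames <- lapply(seq_len(6), function(i) {
    sh <- CCvoid:::.apply_shift(padded, shifts[i, 1], shifts[i, 2],
                                fill = 0.5)$intensity[ctr, ctr]
    EnFaceFrame(sh, 10)
  })
  st <- FrameStack(frames, frames, eyeId = "roundtrip")
  reg <- registerStack(st, pipelineConfig())
  avg <- averageStack(reg)
  mae <- mean(abs(intensity(avg) - img))
  expect_lt(mae, 0.02)
})

test_that("averaging raises contrast-to-noise and it grows with frame count", {
  gt <- fx_gt()
  st <- simulateFrameStack(gt, acquisitionParams(n_frames = 9, max_shift = 0),
                           seed = 43)
  cnr_single <- vapply(st@cc, function(f)
    contrastToNoise(intensity(f), gt@perfusionMap), 0)
  cnr_n <- vapply(4:9, function(n) {
    stn <- FrameStack(st@cc[1:n], st@scp[1:n])
    contrastToNoise(intensity(averageStack(stn)), gt@perfusionMap)
  }, 0)
  expect_gt(min(cnr_n), max(cnr_single))
  expect_true(all(diff(cnr_n) >= 0))
})
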