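# Shared fixtures, built once per test run and memoised. Small grids keep the
# imaging tests fast; the generators are deterministic given the seeds below.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# default-geometry ground truth at a reduced field of view
fx_gt <- function(vf = 0.11, grid = 160L, seed = 11) {
  fx_memo(sprintf("gt_%g_%d_%d", vf, grid, seed),
          simulateMeshwork(meshworkParams(grid_size = grid,
                                          void_fraction_target = vf),
                           seed = seed))
}

# default-acquisition degraded stack over fx_gt()
fx_stack <- function(n_frames = 6L, max_shift = 6, seed = 21) {
  fx_memo(sprintf("stack_%d_%g_%d", n_frames, max_shift, seed),
          simulateFrameStack(fx_gt(),
                             acquisitionParams(n_frames = n_frames,
                                               max_shift = max_shift),
                             seed = seed))
}

# pipeline config used for ground-truth recovery: no FAZ disc, no retinal
# vessel exclusion, so pipeline output is comparable to full-field truth
fx_recovery_config <- function() {
  pipelineConfig(faz_radius_um = 0, caliber_cutoff_um = Inf)
}

# a small frame with constant intensity, for gating fixtures
fx_flat_frame <- function(value = 0.5, score = 9L, artifact = FALSE, d = 8L) {
  EnFaceFrame(matrix(value, d, d), qualityScore = score,
              artifactFlag = artifact)
}

fx_flat_stack <- function(scores, artifacts = rep(FALSE, length(scores)),
                          eye_id = "eye") {
  frames <- mapply(fx_flat_frame, score = as.integer(scores),
                   artifact = artifacts,
                   MoreArgs = list(value = 0.5), SIMPLIFY = FALSE)
  FrameStack(frames, frames, eyeId = eye_id)
}

# independent brute-force Phansalkar oracle: explicit per-pixel loops over a
# reflectively padded image and an explicit Euclidean disc of offsets
oracle_phansalkar <- function(img, radius, k = 0.25, r = 0.5, p = 2, q = 10) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(radius:1, 1:nr, nr:(nr - radius + 1))
  ci <- c(radius:1, 1:nc, nc:(nc - radius + 1))
  pad <- img[ri, ci]
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  out <- matrix(NA, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- pad[cbind(i + radius + offs$di, j + radius + offs$dj)]
      m <- mean(vals)
      s <- sqrt(mean(vals^2) - m^2)
      t <- m * (1 + p * exp(-q * m) + k * ((s / r) - 1))
      out[i, j] <- img[i, j] < t
    }
  }
  out
}
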