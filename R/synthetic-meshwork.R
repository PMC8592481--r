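#' Simulate a ground-truth choriocapillaris meshwork
#'
#' Builds an anastomosing capillary network as the edge set of a Voronoi
#' tessellation of random lobule seeds, dilated to capillary caliber: a pixel
#' is perfused when the difference between its distances to the second-nearest
#' and nearest seed falls below an edge-band threshold. The flow voids are the
#' lobule interiors, which matches the lobular histology of the
#' choriocapillaris.
#'
#' With `vessel_width = NULL` (default) the threshold is calibrated by
#' quantile so the realized void fraction equals `void_fraction_target`
#' (a miss beyond 10% relative is an error, not silently clipped). An
#' explicit `vessel_width` takes precedence over the target; a width wide
#' enough to perfuse the whole grid simply yields zero voids.
#'
#' The pristine intensity is two-level (0.15 background / 0.85 perfused);
#' optical blur is a property of acquisition, see [acquisitionParams()].
#'
#' @param params a [meshworkParams()] list.
#' @param seed integer seed; identical seeds give bit-identical images.
#' @return A [GroundTruthImage-class] whose `trueMetrics` are computed
#'   exactly from the true void mask (VDI from the perfusion map).
#' @examples
#' gt <- simulateMeshwork(meshworkParams(grid_size = 96L), seed = 1)
#' trueMetrics(gt)
#' @export
simulateMeshwork <- function(params = meshworkParams(), seed = 1L) {
  if (!inherits(params, "MeshworkParams"))
    stop("params must come from meshworkParams()", call. = FALSE)
  g <- params$grid_size
  pitch <- params$pixel_pitch
  target <- params$void_fraction_target
  perf <- withr::with_seed(as.integer(seed), {
    area_mm2 <- (g * pitch / 1000)^2
    n_seeds <- max(3L, round(params$seed_density * area_mm2))
    sx <- stats::runif(n_seeds, 0.5, g + 0.5)
    sy <- stats::runif(n_seeds, 0.5, g + 0.5)
    diff_um <- nearest_two_diff(g, g, sx, sy) * pitch
    if (is.null(params$vessel_width)) {
      thr <- stats::quantile(diff_um, 1 - target, names = FALSE)
      p <- diff_um < thr
      realized <- mean(!p)
      if (abs(realized - target) / target > 0.10)
        stop(sprintf(paste("void_fraction_target %.3f is unreachable at",
                           "seed_density %.3g (realized %.3f); adjust the",
                           "density or the target"),
                     target, params$seed_density, realized), call. = FALSE)
      p
    } else {
      diff_um < params$vessel_width
    }
  })
  pristine <- 0.15 + 0.7 * perf
  void <- !perf
  comps <- .label8(void, min_void_px = 1L, analyzable_px = length(void))
  vdi <- if (any(perf)) {
    sum(perf) / sum(zhang_suen_thin(perf))
  } else NA_real_
  metrics <- flowVoidMetrics(comps, pitch, vdi = vdi)
  new("GroundTruthImage", perfusionMap = perf, pristineIntensity = pristine,
      trueVoidMask = void, trueMetrics = metrics, pixelPitch = pitch,
      params = unclass(params))
}

#' Simulate a degraded multi-frame acquisition of one eye
#'
#' Degrades a ground-truth meshwork into `n_frames` repeated CC frames with
#' paired SCP frames: per-pixel dropout of perfused signal (before noise),
#' Gaussian optical blur, a random injected translation per frame (recorded
#' as ground truth; frame 1 stays unshifted as the anchor), and multiplicative
#' log-normal speckle with unit mean. The SCP partner is an independent
#' vascular pattern with wider lobules and finer capillary calibers, imaged
#' under the same motion, which is what makes it usable as the registration
#' driver.
#'
#' @param gt a [GroundTruthImage-class] from [simulateMeshwork()].
#' @param acq an [acquisitionParams()] list.
#' @param seed integer seed.
#' @param scp_truth optional matrix in \[0, 1\] to use as the SCP pristine
#'   image; by default a coarser synthetic plexus is generated.
#' @return A [FrameStack-class] with `trueShifts` filled in.
#' @export
simulateFrameStack <- function(gt, acq = acquisitionParams(), seed = 1L,
                               scp_truth = NULL) {
  stopifnot(is(gt, "GroundTruthImage"))
  if (!inherits(acq, "AcquisitionParams"))
    stop("acq must come from acquisitionParams()", call. = FALSE)
  g <- nrow(gt@perfusionMap)
  pitch <- gt@pixelPitch
  withr::with_seed(as.integer(seed), {
    if (is.null(scp_truth)) {
      scp_seed <- sample.int(.Machine$integer.max, 1)
      # a finer plexus than the CC: capillary calibers below the default
      # 30-um major-vessel cutoff, so a healthy synthetic SCP is not
      # flagged as major vessel
      scp_gt <- simulateMeshwork(
        meshworkParams(grid_size = g, pixel_pitch = pitch, seed_density = 100,
                       void_fraction_target = 0.78),
        seed = scp_seed)
      scp_truth <- scp_gt@pristineIntensity
    }
    n <- acq$n_frames
    dx <- c(0, stats::runif(n - 1, -acq$max_shift, acq$max_shift))
    dy <- c(0, stats::runif(n - 1, -acq$max_shift, acq$max_shift))
    speckle <- function(img) {
      if (acq$speckle_sigma == 0) return(img)
      s <- acq$speckle_sigma
      img * exp(stats::rnorm(length(img), -s^2 / 2, s))
    }
    blur <- function(img) {
      if (acq$psf_sigma == 0) return(img)
      EBImage::gblur(img, sigma = acq$psf_sigma)
    }
    # a shifted view must sample real tissue beyond the nominal field, as a
    # real scan does; the truth canvas is therefore reflect-padded and each
    # frame is a translated crop of it (frame 1 crops the centre)
    pad <- ceiling(acq$max_shift) + 1L
    perf_pad <- .reflect_pad(gt@perfusionMap, pad)
    scp_pad <- .reflect_pad(scp_truth, pad)
    gp <- g + 2L * pad
    ctr <- pad + seq_len(g)
    cc <- vector("list", n); scp <- vector("list", n)
    for (i in seq_len(n)) {
      perf_i <- perf_pad
      if (acq$dropout_prob > 0)
        perf_i <- perf_i &
          (matrix(stats::runif(gp * gp), gp, gp) >= acq$dropout_prob)
      img <- blur(0.15 + 0.7 * perf_i)
      img <- .apply_shift(img, dy[i], dx[i], fill = 0.15)$intensity[ctr, ctr]
      img <- pmin(pmax(speckle(img), 0), 1)
      cc[[i]] <- EnFaceFrame(img, pitch, acq$quality_scores[i])
      sim <- blur(scp_pad)
      sim <- .apply_shift(sim, dy[i], dx[i], fill = 0.15)$intensity[ctr, ctr]
      sim <- pmin(pmax(speckle(sim), 0), 1)
      scp[[i]] <- EnFaceFrame(sim, pitch, acq$quality_scores[i])
    }
    FrameStack(cc, scp, eyeId = "synthetic",
               trueShifts = data.frame(frame = seq_len(n), dx = dx, dy = dy))
  })
}
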