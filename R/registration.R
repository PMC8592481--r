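#' Excluded-eye record
#'
#' [filterFrames()] and [registerStack()] mark an eye as excluded (rather
#' than erroring) when fewer than the minimum number of frames survive, so a
#' cohort run can continue and account for exclusions the way an intake
#' filter does.
#'
#' @param x any object.
#' @return `isExcluded` returns `TRUE` for an exclusion record.
#' @export
isExcluded <- function(x) inherits(x, "excludedEye")

.excluded_eye <- function(eye_id, stage, reason) {
  structure(list(eye_id = eye_id, status = "excluded", stage = stage,
                 reason = reason), class = "excludedEye")
}

#' @export
print.excludedEye <- function(x, ...) {
  cat(sprintf("Eye '%s' excluded at stage '%s': %s\n", x$eye_id, x$stage,
              x$reason))
  invisible(x)
}

#' Gate frames by signal-strength score and artifact flag
#'
#' Retains CC/SCP frame pairs whose signal-strength score is at least
#' `min_quality` (default 8 of 10) and whose artifact flag is clear. An eye
#' with fewer than `min_frames` surviving pairs is marked excluded with a
#' reason instead of erroring, mirroring intake exclusion for poor fixation
#' or image quality.
#'
#' @param stack a [FrameStack-class].
#' @param min_quality minimum score kept (frames with score >= this survive).
#' @param min_frames minimum surviving frames, default 4.
#' @return The filtered [FrameStack-class], or an exclusion record
#'   (see [isExcluded()]).
#' @export
filterFrames <- function(stack, min_quality = 8L, min_frames = 4L) {
  stopifnot(is(stack, "FrameStack"))
  scores <- vapply(stack@cc, function(f) f@qualityScore, integer(1))
  artifacts <- vapply(stack@cc, function(f) f@artifactFlag, logical(1))
  keep <- scores >= min_quality & !artifacts
  if (sum(keep) < min_frames)
    return(.excluded_eye(stack@eyeId, "filter",
                         sprintf("poor image quality: %d of %d frames pass (minimum %d)",
                                 sum(keep), length(keep), min_frames)))
  ts <- stack@trueShifts
  if (nrow(ts)) ts <- ts[keep, , drop = FALSE]
  FrameStack(stack@cc[keep], stack@scp[keep], eyeId = stack@eyeId,
             trueShifts = ts)
}

#' Phase-correlation translation estimate with subpixel refinement
#'
#' Estimates the translation of `img` relative to `ref` by the phase of the
#' normalized cross-power spectrum (Hann-windowed), followed by subpixel
#' refinement: the correlation surface is re-evaluated from the cross-power
#' spectrum on a 0.02-px grid around the integer peak (matrix-multiply DFT
#' upsampling). Returns the shift `(dy, dx)` such that `img` content sits at
#' `ref` content translated by `(dy, dx)`; translating `img` by
#' `(-dy, -dx)` aligns it onto `ref`.
#'
#' @param ref,img numeric matrices of identical dimensions.
#' @param max_shift search radius in pixels.
#' @return list with `dy`, `dx` (pixels, subpixel) and `peak` (correlation
#'   peak height, a registration quality hint).
#' @export
phaseCorrelate <- function(ref, img, max_shift = Inf) {
  stopifnot(identical(dim(ref), dim(img)))
  nr <- nrow(ref); nc <- ncol(ref)
  w <- outer(.hann(nr), .hann(nc))
  A <- stats::fft(ref * w)
  B <- stats::fft(img * w)
  X <- B * Conj(A)
  R <- X / (Mod(X) + 1e-12)
  cc <- Re(stats::fft(R, inverse = TRUE)) / (nr * nc)
  dr <- 0:(nr - 1); dr[dr > nr / 2] <- dr[dr > nr / 2] - nr
  dc <- 0:(nc - 1); dc[dc > nc / 2] <- dc[dc > nc / 2] - nc
  ccm <- cc
  ccm[outer(abs(dr) > max_shift, abs(dc) > max_shift, "|")] <- -Inf
  p <- arrayInd(which.max(ccm), dim(ccm))
  peak <- cc[p[1], p[2]]
  dy0 <- dr[p[1]]; dx0 <- dc[p[2]]
  # two-stage matrix-multiply DFT upsampling of the correlation surface
  # around the integer peak: 0.1-px pass over +-1 px, then 0.02-px pass
  fr <- ifelse(0:(nr - 1) > nr / 2, 0:(nr - 1) - nr, 0:(nr - 1))
  fc <- ifelse(0:(nc - 1) > nc / 2, 0:(nc - 1) - nc, 0:(nc - 1))
  eval_cc <- function(uy, ux) {
    E1 <- exp(2i * pi * outer(uy, fr) / nr)
    E2 <- exp(2i * pi * outer(fc, ux) / nc)
    Re(E1 %*% R %*% E2) / (nr * nc)
  }
  best <- c(dy0, dx0)
  for (step in c(0.1, 0.02)) {
    uy <- best[1] + seq(-5 * step, 5 * step, by = step)
    ux <- best[2] + seq(-5 * step, 5 * step, by = step)
    cs <- eval_cc(uy, ux)
    q <- arrayInd(which.max(cs), dim(cs))
    best <- c(uy[q[1]], ux[q[2]])
    peak <- cs[q[1], q[2]]
  }
  list(dy = best[1], dx = best[2], peak = peak)
}

#' Register a frame stack, SCP first
#'
#' The transforms are estimated on the superficial-capillary-plexus frames
#' against a reference frame (the highest quality score, ties to the first
#' acquired) and then applied to both the SCP and the paired CC frames --
#' the SCP carries the high-contrast landmarks, the CC inherits the motion.
#' Translation-only (phase correlation with subpixel refinement): inter-scan
#' eye motion at fixed scan geometry is dominantly translational.
#'
#' Aligned frames carry validity masks (pixels that stayed on canvas);
#' averaging later masks the invalid margins rather than zero-filling, so
#' edge averages stay unbiased. A frame whose post-alignment correlation
#' with the reference falls below `registration_floor` is dropped with a
#' warning; if fewer than `min_frames` remain, the eye is marked excluded.
#'
#' @param stack a [FrameStack-class] (at least 2 frames).
#' @param config a [pipelineConfig()]; uses `max_search_px`,
#'   `registration_floor`, `min_frames`.
#' @return The registered [FrameStack-class] carrying transforms and
#'   validity masks (see [registrationTransforms()]), or an exclusion record.
#' @export
registerStack <- function(stack, config = pipelineConfig()) {
  stopifnot(is(stack, "FrameStack"))
  n <- length(stack@cc)
  if (n < 2) stop("need at least 2 frames to register", call. = FALSE)
  scores <- vapply(stack@cc, function(f) f@qualityScore, integer(1))
  ref_idx <- which.max(scores)
  ref_scp <- intensity(stack@scp[[ref_idx]])
  d <- dim(ref_scp)
  cc_al <- vector("list", n); scp_al <- vector("list", n)
  masks <- vector("list", n)
  tr <- data.frame(frame = seq_len(n), dx = 0, dy = 0, score = NA_real_,
                   reference = ref_idx)
  for (i in seq_len(n)) {
    if (i == ref_idx) {
      cc_al[[i]] <- intensity(stack@cc[[i]])
      scp_al[[i]] <- intensity(stack@scp[[i]])
      masks[[i]] <- matrix(TRUE, d[1], d[2])
      tr$score[i] <- 1
      next
    }
    est <- phaseCorrelate(ref_scp, intensity(stack@scp[[i]]),
                          max_shift = config$max_search_px)
    s_al <- .apply_shift(intensity(stack@scp[[i]]), -est$dy, -est$dx, fill = 0)
    c_al <- .apply_shift(intensity(stack@cc[[i]]), -est$dy, -est$dx, fill = 0)
    v <- s_al$valid
    tr$dx[i] <- est$dx; tr$dy[i] <- est$dy
    tr$score[i] <- suppressWarnings(
      stats::cor(ref_scp[v], s_al$intensity[v]))
    if (!is.finite(tr$score[i])) tr$score[i] <- 0
    cc_al[[i]] <- c_al$intensity
    scp_al[[i]] <- s_al$intensity
    masks[[i]] <- v
  }
  keep <- tr$score >= config$registration_floor
  if (any(!keep))
    warning(sprintf("dropping %d frame(s) with registration score below %.2f",
                    sum(!keep), config$registration_floor))
  if (sum(keep) < config$min_frames)
    return(.excluded_eye(stack@eyeId, "register",
                         sprintf("registration failure: %d of %d frames align (minimum %d)",
                                 sum(keep), n, config$min_frames)))
  wrap <- function(int, old) EnFaceFrame(pmin(pmax(int, 0), 1),
                                         old@pixelPitch, old@qualityScore,
                                         old@artifactFlag, old@slabMeta)
  cc_f <- mapply(wrap, cc_al[keep], stack@cc[keep], SIMPLIFY = FALSE)
  scp_f <- mapply(wrap, scp_al[keep], stack@scp[keep], SIMPLIFY = FALSE)
  ts <- stack@trueShifts
  if (nrow(ts)) ts <- ts[keep, , drop = FALSE]
  out <- FrameStack(cc_f, scp_f, eyeId = stack@eyeId, trueShifts = ts)
  out@transforms <- tr[keep, , drop = FALSE]
  out@validMasks <- masks[keep]
  out
}

#' Registration transforms of a registered stack
#'
#' @param stack a [FrameStack-class] returned by [registerStack()].
#' @return data.frame with one row per retained frame: `frame` (original
#'   index), `dx`, `dy` (pixels), `score` (correlation with the reference
#'   after alignment), `reference`.
#' @export
registrationTransforms <- function(stack) {
  stopifnot(is(stack, "FrameStack"))
  stack@transforms
}

#' Average the registered frames of one eye
#'
#' Pixelwise mean over valid (in-canvas) contributions; off-canvas margins of
#' individual frames are masked, not zero-filled. No per-image histogram
#' stretch is applied -- inputs are already in \[0, 1\], so their mean is too,
#' and thresholds stay comparable across eyes.
#'
#' @param stack a registered [FrameStack-class] (an unregistered stack is
#'   averaged as-is, which is only sensible for already-aligned frames).
#' @param channel `"cc"` (default) or `"scp"`.
#' @param min_frames minimum frames required (default 4).
#' @return An [AveragedEnFace-class].
#' @export
averageStack <- function(stack, channel = c("cc", "scp"), min_frames = 4L) {
  stopifnot(is(stack, "FrameStack"))
  channel <- match.arg(channel)
  frames <- slot(stack, channel)
  n <- length(frames)
  if (n < min_frames)
    stop(sprintf("need at least %d frames to average, got %d", min_frames, n),
         call. = FALSE)
  d <- dim(intensity(frames[[1]]))
  masks <- stack@validMasks
  if (length(masks) == 0) masks <- rep(list(matrix(TRUE, d[1], d[2])), n)
  acc <- matrix(0, d[1], d[2]); support <- matrix(0L, d[1], d[2])
  for (i in seq_len(n)) {
    v <- masks[[i]]
    acc <- acc + intensity(frames[[i]]) * v
    support <- support + v
  }
  avg <- ifelse(support > 0, acc / pmax(support, 1L), 0)
  avg <- pmin(pmax(avg, 0), 1)
  new("AveragedEnFace", intensity = avg,
      pixelPitch = frames[[1]]@pixelPitch, nFramesUsed = as.integer(n),
      support = support,
      provenance = list(eye_id = stack@eyeId, channel = channel,
                        transforms = stack@transforms))
}
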