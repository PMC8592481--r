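#' Phansalkar local adaptive binarization
#'
#' Thresholds each pixel of the averaged choriocapillaris image against the
#' Phansalkar rule over a circular window of the configured radius:
#' \deqn{t = \mu_w (1 + p e^{-q \mu_w} + k(\sigma_w / r - 1))}
#' with \eqn{\mu_w}, \eqn{\sigma_w} the local window mean and standard
#' deviation. A pixel strictly below its threshold is a flow void; ties go to
#' vessel (documented because integer-quantized images hit ties). Window
#' statistics at the borders use reflective (symmetric) padding.
#'
#' The rule is designed for low-contrast images: the \eqn{p e^{-q\mu}} term
#' lifts the threshold where the local mean is low, which keeps dark,
#' low-variance regions classified as void.
#'
#' @param image an [AveragedEnFace-class], [EnFaceFrame-class] or numeric
#'   matrix with intensities in \[0, 1\].
#' @param params a [phansalkarParams()] list.
#' @return A [VoidSegmentation-class] (`TRUE` = flow void).
#' @export
phansalkarBinarize <- function(image, params = phansalkarParams()) {
  img <- .as_intensity(image)
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stop("image intensities must be normalized to [0, 1] before binarization",
         call. = FALSE)
  rad <- params$radius
  pad <- .reflect_pad(img, rad)
  # circular window: pixels at Euclidean distance <= radius
  K <- (outer((-rad:rad)^2, (-rad:rad)^2, "+") <= rad^2) * 1
  K <- K / sum(K)
  mu <- EBImage::filter2(pad, K)
  ex2 <- EBImage::filter2(pad^2, K)
  rows <- rad + seq_len(nrow(img)); cols <- rad + seq_len(ncol(img))
  mu <- mu[rows, cols]
  sdw <- sqrt(pmax(ex2[rows, cols] - mu^2, 0))
  thr <- mu * (1 + params$p * exp(-params$q * mu) +
                 params$k * ((sdw / params$r) - 1))
  src <- if (is(image, "AveragedEnFace"))
    paste0(image@provenance$eye_id %||% "image", "/avg") else "image"
  new("VoidSegmentation", voidMap = img < thr, source = src,
      params = unclass(params))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Invert a flow-void segmentation into a vessel map
#'
#' The exact logical complement: vessels white, voids black.
#'
#' @param seg a [VoidSegmentation-class].
#' @return logical matrix, `TRUE` = vessel.
#' @export
invertToVessels <- function(seg) {
  stopifnot(is(seg, "VoidSegmentation"))
  !seg@voidMap
}

#' Build the exclusion mask: major retinal vessels and the FAZ
#'
#' Major retinal vessels are segmented from the superficial-plexus image as
#' bright structures wider than the caliber cutoff: a global threshold
#' (Otsu's by default) followed by a morphological opening whose structuring
#' element removes structures narrower than the cutoff, then a small safety
#' dilation to suppress projection-artifact halos. The foveal avascular zone
#' is a central disc of configured radius (delineation of the FAZ is commonly
#' manual; the disc is the automatic stand-in, and a user-supplied mask can
#' replace the whole result downstream). The excluded region is the union.
#'
#' @param scp SCP image (object or matrix), already aligned to the CC frame
#'   of reference.
#' @param pixel_pitch um per pixel.
#' @param faz_radius_um FAZ disc radius in um (0 disables).
#' @param caliber_cutoff_um vessels wider than this are excluded
#'   (`Inf` disables vessel exclusion).
#' @param dilation_px safety margin around detected vessels, px.
#' @param threshold optional global threshold in \[0, 1\]; default Otsu.
#' @return An [ExclusionMask-class]. A mask covering more than half the
#'   field triggers a warning (likely segmentation failure).
#' @export
buildExclusionMask <- function(scp, pixel_pitch = 10, faz_radius_um = 250,
                               caliber_cutoff_um = 30, dilation_px = 2L,
                               threshold = NULL) {
  img <- .as_intensity(scp)
  d <- dim(img)
  major <- matrix(FALSE, d[1], d[2])
  rr <- floor(caliber_cutoff_um / pixel_pitch / 2)
  # a near-constant SCP image carries no vessel structure (and would make a
  # global threshold degenerate)
  if (is.finite(caliber_cutoff_um) && rr < min(d) / 2 &&
      diff(range(img)) > 1e-6) {
    rr <- max(1L, as.integer(rr))
    thr <- threshold %||% EBImage::otsu(img, range = c(0, 1))
    bw <- (img > thr) * 1
    brush <- EBImage::makeBrush(2L * rr + 1L, shape = "disc")
    opened <- EBImage::dilate(EBImage::erode(bw, brush), brush)
    if (dilation_px > 0) {
      db <- EBImage::makeBrush(2L * as.integer(dilation_px) + 1L, shape = "disc")
      opened <- EBImage::dilate(opened, db)
    }
    major <- opened > 0.5
  }
  faz <- matrix(FALSE, d[1], d[2])
  r_px <- faz_radius_um / pixel_pitch
  if (r_px > 0) {
    cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
    faz <- outer(seq_len(d[1]), seq_len(d[2]),
                 function(i, j) (i - cy)^2 + (j - cx)^2 <= r_px^2)
  }
  excluded <- major | faz
  if (mean(excluded) > 0.5)
    warning(sprintf("exclusion mask covers %.0f%% of the field - likely segmentation failure",
                    100 * mean(excluded)))
  new("ExclusionMask", excluded = excluded,
      components = list(major_vessel = major, faz = faz))
}
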