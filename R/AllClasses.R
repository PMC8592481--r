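#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib CCvoid, .registration = TRUE
NULL

.check_intensity <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) return("intensity must be a numeric matrix")
  if (anyNA(x)) return("intensity must not contain NA")
  if (min(x) < 0 || max(x) > 1) return("intensity values must lie in [0, 1]")
  NULL
}

#' EnFaceFrame: one grayscale en face OCTA image
#'
#' A single en face frame: a grayscale intensity grid normalized to \[0, 1\],
#' its pixel pitch (micrometres per pixel), the device signal-strength score
#' (0--10), an artifact flag (blink / fixation loss), and slab metadata
#' (nominal offset below the RPE and slab thickness, carried as provenance
#' only -- slab extraction is upstream of this package).
#'
#' @slot intensity numeric matrix in \[0, 1\] (rows = y, columns = x).
#' @slot pixelPitch micrometres per pixel, > 0.
#' @slot qualityScore integer signal-strength score in 0--10.
#' @slot artifactFlag logical, `TRUE` when the frame shows a motion/blink artifact.
#' @slot slabMeta list with elements `offset_um` and `thickness_um`.
#' @exportClass EnFaceFrame
setClass("EnFaceFrame",
  slots = c(intensity = "matrix", pixelPitch = "numeric",
            qualityScore = "integer", artifactFlag = "logical",
            slabMeta = "list"),
  validity = function(object) {
    msg <- .check_intensity(object@intensity)
    if (!is.null(msg)) return(msg)
    if (length(object@pixelPitch) != 1 || !is.finite(object@pixelPitch) ||
        object@pixelPitch <= 0) return("pixelPitch must be a single positive number")
    if (length(object@qualityScore) != 1 || is.na(object@qualityScore) ||
        object@qualityScore < 0 || object@qualityScore > 10)
      return("qualityScore must be a single integer in 0..10")
    if (length(object@artifactFlag) != 1 || is.na(object@artifactFlag))
      return("artifactFlag must be TRUE or FALSE")
    TRUE
  })

#' Construct an EnFaceFrame
#'
#' @param intensity numeric matrix in \[0, 1\].
#' @param pixelPitch micrometres per pixel.
#' @param qualityScore integer 0--10 device signal-strength score.
#' @param artifactFlag logical artifact flag.
#' @param slabMeta list of slab provenance (`offset_um`, `thickness_um`).
#' @return An [EnFaceFrame-class] object.
#' @export
EnFaceFrame <- function(intensity, pixelPitch = 10, qualityScore = 10L,
                        artifactFlag = FALSE,
                        slabMeta = list(offset_um = 29, thickness_um = 8)) {
  new("EnFaceFrame", intensity = intensity, pixelPitch = as.numeric(pixelPitch),
      qualityScore = as.integer(qualityScore), artifactFlag = artifactFlag,
      slabMeta = slabMeta)
}

#' FrameStack: the paired CC/SCP frames of one eye
#'
#' Holds the 4--9 repeated choriocapillaris (CC) en face frames of one eye
#' together with their paired superficial-capillary-plexus (SCP) frames, which
#' drive registration. After [registerStack()] the stack also carries the
#' estimated transforms and per-frame validity masks (pixels that stayed on
#' canvas after alignment).
#'
#' @slot cc list of [EnFaceFrame-class] (choriocapillaris slab).
#' @slot scp list of [EnFaceFrame-class] (superficial plexus), paired 1:1 with `cc`.
#' @slot eyeId opaque eye label.
#' @slot trueShifts data.frame of injected shifts (synthetic stacks only; 0 rows otherwise).
#' @slot transforms data.frame of estimated registration transforms (0 rows before registration).
#' @slot validMasks list of logical matrices, one per frame (empty before registration).
#' @exportClass FrameStack
setClass("FrameStack",
  slots = c(cc = "list", scp = "list", eyeId = "character",
            trueShifts = "data.frame", transforms = "data.frame",
            validMasks = "list"),
  validity = function(object) {
    if (length(object@cc) != length(object@scp))
      return("cc and scp frame lists must have the same length")
    if (length(object@cc) == 0) return("stack must contain at least one frame")
    ok <- vapply(c(object@cc, object@scp), is, logical(1), class2 = "EnFaceFrame")
    if (!all(ok)) return("all frames must be EnFaceFrame objects")
    d <- dim(object@cc[[1]]@intensity)
    dims <- vapply(c(object@cc, object@scp),
                   function(f) identical(dim(f@intensity), d), logical(1))
    if (!all(dims)) return("all frames must share the same dimensions")
    TRUE
  })

#' Construct a FrameStack
#'
#' @param cc list of CC [EnFaceFrame-class] objects.
#' @param scp list of paired SCP [EnFaceFrame-class] objects.
#' @param eyeId eye label.
#' @param trueShifts optional data.frame of injected ground-truth shifts.
#' @return A [FrameStack-class].
#' @export
FrameStack <- function(cc, scp, eyeId = "eye",
                       trueShifts = data.frame()) {
  new("FrameStack", cc = cc, scp = scp, eyeId = eyeId, trueShifts = trueShifts,
      transforms = data.frame(), validMasks = list())
}

#' AveragedEnFace: the registered, averaged en face image of one eye
#'
#' @slot intensity numeric matrix in \[0, 1\] -- the pixelwise mean over valid
#'   contributions.
#' @slot pixelPitch micrometres per pixel.
#' @slot nFramesUsed number of frames that entered the average.
#' @slot support integer matrix counting how many frames contributed at each pixel.
#' @slot provenance list: frame indices, transforms, channel averaged.
#' @exportClass AveragedEnFace
setClass("AveragedEnFace",
  slots = c(intensity = "matrix", pixelPitch = "numeric",
            nFramesUsed = "integer", support = "matrix", provenance = "list"),
  validity = function(object) {
    msg <- .check_intensity(object@intensity)
    if (!is.null(msg)) return(msg)
    if (!identical(dim(object@intensity), dim(object@support)))
      return("support must match intensity dimensions")
    TRUE
  })

#' FlowVoidMetrics: the per-eye choriocapillaris metrics
#'
#' Count, total area (mm^2) and mean size (um^2) of flow voids, the vessel
#' diameter index (VDI, average vessel caliber in pixels = total vessel area /
#' total skeleton length), and the analyzable area (mm^2) they refer to.
#' `meanSize` and `vdi` are `NA` when undefined (no voids / no vessels).
#'
#' @slot voidCount integer number of flow voids.
#' @slot totalArea total flow-void area in mm^2.
#' @slot meanSize mean individual flow-void size in um^2 (`NA` if no voids).
#' @slot vdi vessel diameter index in pixels (`NA` if not computed).
#' @slot analyzableArea analyzable (non-excluded) area in mm^2.
#' @slot pixelPitch micrometres per pixel.
#' @exportClass FlowVoidMetrics
setClass("FlowVoidMetrics",
  slots = c(voidCount = "integer", totalArea = "numeric", meanSize = "numeric",
            vdi = "numeric", analyzableArea = "numeric", pixelPitch = "numeric"),
  validity = function(object) {
    if (object@voidCount < 0) return("voidCount must be non-negative")
    if (object@totalArea < 0) return("totalArea must be non-negative")
    if (object@totalArea > object@analyzableArea + 1e-9)
      return("totalArea cannot exceed analyzableArea")
    if (object@voidCount > 0) {
      # internal consistency: meanSize * count == totalArea (unit-converted)
      if (abs(object@meanSize * object@voidCount - object@totalArea * 1e6) >
          1e-6 * max(1, object@totalArea * 1e6))
        return("meanSize * voidCount must equal totalArea (in um^2)")
    }
    TRUE
  })

#' GroundTruthImage: a synthetic choriocapillaris with known answers
#'
#' @slot perfusionMap logical matrix, `TRUE` where perfused vessel.
#' @slot pristineIntensity noise-free grayscale image in \[0, 1\].
#' @slot trueVoidMask logical matrix, complement of the perfusion map.
#' @slot trueMetrics exact [FlowVoidMetrics-class] of `trueVoidMask`.
#' @slot pixelPitch micrometres per pixel.
#' @slot params the [meshworkParams()] list that generated the image.
#' @exportClass GroundTruthImage
setClass("GroundTruthImage",
  slots = c(perfusionMap = "matrix", pristineIntensity = "matrix",
            trueVoidMask = "matrix", trueMetrics = "FlowVoidMetrics",
            pixelPitch = "numeric", params = "list"),
  validity = function(object) {
    if (any(object@trueVoidMask & object@perfusionMap))
      return("trueVoidMask and perfusionMap must be disjoint")
    if (!identical(dim(object@perfusionMap), dim(object@pristineIntensity)))
      return("perfusionMap and pristineIntensity dimensions differ")
    TRUE
  })

#' VoidSegmentation: binary flow-void map of an averaged image
#'
#' `TRUE` marks flow void (no flow signal), `FALSE` marks vessel.
#'
#' @slot voidMap logical matrix.
#' @slot source identifier of the segmented image.
#' @slot params the [phansalkarParams()] used.
#' @exportClass VoidSegmentation
setClass("VoidSegmentation",
  slots = c(voidMap = "matrix", source = "character", params = "list"),
  validity = function(object) {
    if (!is.logical(object@voidMap)) return("voidMap must be logical")
    TRUE
  })

#' ExclusionMask: pixels excluded from quantification
#'
#' Union of the major retinal vessel mask (segmented from the SCP image) and
#' the foveal avascular zone disc; `TRUE` marks excluded pixels.
#'
#' @slot excluded logical matrix.
#' @slot components list of logical matrices with provenance
#'   (`major_vessel`, `faz`).
#' @exportClass ExclusionMask
setClass("ExclusionMask",
  slots = c(excluded = "matrix", components = "list"),
  validity = function(object) {
    if (!is.logical(object@excluded)) return("excluded must be logical")
    TRUE
  })

#' VoidComponents: labeled connected flow voids
#'
#' @slot labels integer matrix; 0 = not a void, k = k-th component.
#' @slot areas integer vector of per-component pixel counts.
#' @slot analyzablePx number of analyzable (non-excluded) pixels.
#' @exportClass VoidComponents
setClass("VoidComponents",
  slots = c(labels = "matrix", areas = "integer", analyzablePx = "integer"),
  validity = function(object) {
    if (length(object@areas) > 0 && max(object@labels) != length(object@areas))
      return("labels and areas disagree on the number of components")
    TRUE
  })
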