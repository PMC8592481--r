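#' Accessors for CCvoid classes
#'
#' Small accessor layer so that slots are never reached into directly:
#' `intensity()`, `pixelPitch()`, `qualityScore()`, `nFrames()`, `voidMap()`,
#' `excludedPixels()`, `trueMetrics()`, `nComponents()`, `componentAreas()`.
#'
#' @param object a CCvoid object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setGeneric("qualityScore", function(object) standardGeneric("qualityScore"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("voidMap", function(object) standardGeneric("voidMap"))
#' @rdname accessors
#' @export
setGeneric("excludedPixels", function(object) standardGeneric("excludedPixels"))
#' @rdname accessors
#' @export
setGeneric("trueMetrics", function(object) standardGeneric("trueMetrics"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("componentAreas", function(object) standardGeneric("componentAreas"))

#' @rdname accessors
setMethod("intensity", "EnFaceFrame", function(object) object@intensity)
#' @rdname accessors
setMethod("intensity", "AveragedEnFace", function(object) object@intensity)
#' @rdname accessors
setMethod("intensity", "GroundTruthImage", function(object) object@pristineIntensity)
#' @rdname accessors
setMethod("pixelPitch", "EnFaceFrame", function(object) object@pixelPitch)
#' @rdname accessors
setMethod("pixelPitch", "AveragedEnFace", function(object) object@pixelPitch)
#' @rdname accessors
setMethod("pixelPitch", "GroundTruthImage", function(object) object@pixelPitch)
#' @rdname accessors
setMethod("pixelPitch", "FlowVoidMetrics", function(object) object@pixelPitch)
#' @rdname accessors
setMethod("qualityScore", "EnFaceFrame", function(object) object@qualityScore)
#' @rdname accessors
setMethod("nFrames", "FrameStack", function(object) length(object@cc))
#' @rdname accessors
setMethod("nFrames", "AveragedEnFace", function(object) object@nFramesUsed)
#' @rdname accessors
setMethod("voidMap", "VoidSegmentation", function(object) object@voidMap)
#' @rdname accessors
setMethod("excludedPixels", "ExclusionMask", function(object) object@excluded)
#' @rdname accessors
setMethod("trueMetrics", "GroundTruthImage", function(object) object@trueMetrics)
#' @rdname accessors
setMethod("nComponents", "VoidComponents", function(object) length(object@areas))
#' @rdname accessors
setMethod("componentAreas", "VoidComponents", function(object) object@areas)

#' Coerce FlowVoidMetrics to a one-row data.frame
#'
#' @param x a [FlowVoidMetrics-class] object.
#' @param ... ignored.
#' @return data.frame with columns `void_count`, `total_area_mm2`,
#'   `mean_size_um2`, `vdi`, `analyzable_area_mm2`.
#' @method as.data.frame FlowVoidMetrics
#' @export
as.data.frame.FlowVoidMetrics <- function(x, ...) {
  data.frame(void_count = x@voidCount, total_area_mm2 = x@totalArea,
             mean_size_um2 = x@meanSize, vdi = x@vdi,
             analyzable_area_mm2 = x@analyzableArea)
}
setMethod("as.data.frame", "FlowVoidMetrics", as.data.frame.FlowVoidMetrics)

setMethod("show", "EnFaceFrame", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("EnFaceFrame %dx%d px @ %.3g um/px, quality %d/10%s\n",
              d[1], d[2], object@pixelPitch, object@qualityScore,
              if (object@artifactFlag) " [artifact]" else ""))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@cc[[1]]@intensity)
  cat(sprintf("FrameStack '%s': %d paired CC/SCP frames, %dx%d px%s\n",
              object@eyeId, length(object@cc), d[1], d[2],
              if (nrow(object@transforms)) " (registered)" else ""))
  sc <- vapply(object@cc, function(f) f@qualityScore, integer(1))
  cat("  quality scores:", paste(sc, collapse = " "), "\n")
})

setMethod("show", "AveragedEnFace", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("AveragedEnFace %dx%d px @ %.3g um/px, %d frames averaged\n",
              d[1], d[2], object@pixelPitch, object@nFramesUsed))
})

setMethod("show", "FlowVoidMetrics", function(object) {
  cat("FlowVoidMetrics\n")
  cat(sprintf("  flow voids : %d\n", object@voidCount))
  cat(sprintf("  total area : %.4f mm^2\n", object@totalArea))
  cat(sprintf("  mean size  : %.1f um^2\n", object@meanSize))
  cat(sprintf("  VDI        : %.3f px\n", object@vdi))
  cat(sprintf("  analyzable : %.4f mm^2\n", object@analyzableArea))
})

setMethod("show", "GroundTruthImage", function(object) {
  d <- dim(object@perfusionMap)
  cat(sprintf("GroundTruthImage %dx%d px @ %.3g um/px, void fraction %.3f\n",
              d[1], d[2], object@pixelPitch, mean(object@trueVoidMask)))
})

setMethod("show", "VoidSegmentation", function(object) {
  d <- dim(object@voidMap)
  cat(sprintf("VoidSegmentation %dx%d px, void fraction %.3f (source: %s)\n",
              d[1], d[2], mean(object@voidMap), object@source))
})

setMethod("show", "ExclusionMask", function(object) {
  cat(sprintf("ExclusionMask: %.1f%% of field excluded (%s)\n",
              100 * mean(object@excluded),
              paste(names(object@components), collapse = " + ")))
})

setMethod("show", "VoidComponents", function(object) {
  cat(sprintf("VoidComponents: %d components, %d void px over %d analyzable px\n",
              length(object@areas), sum(object@areas), object@analyzablePx))
})
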