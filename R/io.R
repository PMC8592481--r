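# File-format layer: grayscale TIFF frames, CSV manifests, JSON sidecars.

.read_gray <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write a frame stack to TIFF files plus a CSV manifest
#'
#' One 16-bit grayscale TIFF per frame (CC and SCP), and a manifest CSV with
#' columns `eye_id`, `frame`, `frame_path_cc`, `frame_path_scp`,
#' `quality_score`, `artifact_flag`, `pixel_pitch_um`.
#'
#' @param stack a [FrameStack-class].
#' @param dir output directory (created if needed).
#' @param manifest manifest path; default `<dir>/manifest.csv`. Appends to an
#'   existing manifest so several eyes can share one.
#' @return the manifest path, invisibly.
#' @export
writeFrameStack <- function(stack, dir,
                            manifest = file.path(dir, "manifest.csv")) {
  stopifnot(is(stack, "FrameStack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nFrames(stack)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pcc <- file.path(dir, sprintf("%s_cc_%02d.tif", stack@eyeId, i))
    pscp <- file.path(dir, sprintf("%s_scp_%02d.tif", stack@eyeId, i))
    tiff::writeTIFF(intensity(stack@cc[[i]]), pcc, bits.per.sample = 16)
    tiff::writeTIFF(intensity(stack@scp[[i]]), pscp, bits.per.sample = 16)
    rows[[i]] <- data.frame(eye_id = stack@eyeId, frame = i,
                            frame_path_cc = pcc, frame_path_scp = pscp,
                            quality_score = qualityScore(stack@cc[[i]]),
                            artifact_flag = stack@cc[[i]]@artifactFlag,
                            pixel_pitch_um = pixelPitch(stack@cc[[i]]))
  }
  df <- do.call(rbind, rows)
  append <- file.exists(manifest)
  utils::write.table(df, manifest, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, qmethod = "double")
  invisible(manifest)
}

#' Read frame stacks from a CSV manifest
#'
#' @param manifest path to a manifest CSV as written by [writeFrameStack()].
#' @return named list of [FrameStack-class], one per `eye_id`.
#' @export
readFrameStacks <- function(manifest) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("eye_id", "frame_path_cc", "frame_path_scp", "quality_score")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"artifact_flag" %in% names(df)) df$artifact_flag <- FALSE
  if (!"pixel_pitch_um" %in% names(df)) df$pixel_pitch_um <- 10
  out <- lapply(split(df, df$eye_id), function(d) {
    d <- d[order(d$frame %||% seq_len(nrow(d))), , drop = FALSE]
    cc <- mapply(function(p, q, a, pp)
      EnFaceFrame(.read_gray(p), pp, as.integer(q), as.logical(a)),
      d$frame_path_cc, d$quality_score, d$artifact_flag, d$pixel_pitch_um,
      SIMPLIFY = FALSE)
    scp <- mapply(function(p, q, a, pp)
      EnFaceFrame(.read_gray(p), pp, as.integer(q), as.logical(a)),
      d$frame_path_scp, d$quality_score, d$artifact_flag, d$pixel_pitch_um,
      SIMPLIFY = FALSE)
    FrameStack(unname(cc), unname(scp), eyeId = d$eye_id[1])
  })
  out[unique(df$eye_id)]
}

#' Write an averaged en face image (TIFF + JSON provenance)
#'
#' @param avg an [AveragedEnFace-class].
#' @param path TIFF path; provenance goes to `<path>.json`.
#' @return the path, invisibly.
#' @export
writeAveraged <- function(avg, path) {
  stopifnot(is(avg, "AveragedEnFace"))
  tiff::writeTIFF(intensity(avg), path, bits.per.sample = 16)
  prov <- avg@provenance
  prov$n_frames_used <- nFrames(avg)
  prov$pixel_pitch_um <- pixelPitch(avg)
  jsonlite::write_json(.unclass_rec(prov), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a binary map (segmentation or mask) as an 8-bit TIFF (0/255)
#'
#' @param x a [VoidSegmentation-class], [ExclusionMask-class] or logical matrix.
#' @param path TIFF path.
#' @return the path, invisibly.
#' @export
writeBinaryMap <- function(x, path) {
  m <- if (is(x, "VoidSegmentation")) voidMap(x)
       else if (is(x, "ExclusionMask")) excludedPixels(x)
       else x
  stopifnot(is.logical(m), is.matrix(m))
  tiff::writeTIFF(m * 1, path, bits.per.sample = 8)
  invisible(path)
}

#' Read a binary map written by [writeBinaryMap()]
#'
#' @param path TIFF path.
#' @return logical matrix.
#' @export
readBinaryMap <- function(path) .read_gray(path) > 0.5

#' Write ground truth: perfusion mask TIFF plus a JSON metrics sidecar
#'
#' @param gt a [GroundTruthImage-class].
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return the directory, invisibly.
#' @export
writeGroundTruth <- function(gt, dir, prefix = "truth") {
  stopifnot(is(gt, "GroundTruthImage"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(gt@perfusionMap * 1, file.path(dir, paste0(prefix, "_perfusion.tif")),
                  bits.per.sample = 8)
  tiff::writeTIFF(gt@pristineIntensity, file.path(dir, paste0(prefix, "_pristine.tif")),
                  bits.per.sample = 16)
  side <- c(as.list(as.data.frame(trueMetrics(gt))),
            list(pixel_pitch_um = pixelPitch(gt), params = gt@params))
  jsonlite::write_json(side, file.path(dir, paste0(prefix, "_metrics.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
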