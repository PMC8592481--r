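# 8-connected component labeling of a logical matrix via an explicit
# pixel-adjacency graph. Flow voids are background-like lakes, so they get
# the 8-connectivity; the vessel phase is implicitly 4-connected, which
# avoids paradoxical adjacency at diagonal contacts.
.label8 <- function(void, min_void_px = 1L, analyzable_px = NULL) {
  nr <- nrow(void); nc <- ncol(void)
  if (is.null(analyzable_px)) analyzable_px <- length(void)
  lin <- which(void)
  labels <- matrix(0L, nr, nc)
  if (length(lin) == 0)
    return(new("VoidComponents", labels = labels, areas = integer(0),
               analyzablePx = as.integer(analyzable_px)))
  vid <- integer(nr * nc)
  vid[lin] <- seq_along(lin)
  efrom <- integer(0); eto <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
    c1 <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
    both <- void[r1, c1, drop = FALSE] & void[r1 + dr, c1 + dc, drop = FALSE]
    sel <- which(both)
    if (length(sel) == 0) next
    rr <- ((sel - 1L) %% length(r1)) + r1[1]
    cc <- ((sel - 1L) %/% length(r1)) + c1[1]
    efrom <- c(efrom, vid[(cc - 1L) * nr + rr])
    eto <- c(eto, vid[(cc + dc - 1L) * nr + (rr + dr)])
  }
  memb <- if (length(efrom)) {
    g <- igraph::make_graph(edges = rbind(efrom, eto), n = length(lin),
                            directed = FALSE)
    igraph::components(g)$membership
  } else seq_along(lin)
  sizes <- tabulate(memb)
  keep <- sizes >= min_void_px
  newid <- integer(length(sizes))
  newid[keep] <- seq_len(sum(keep))
  labels[lin] <- newid[memb]
  new("VoidComponents", labels = labels,
      areas = as.integer(sizes[keep]),
      analyzablePx = as.integer(analyzable_px))
}

#' Label connected flow voids
#'
#' Connected components (8-connectivity) of the void map restricted to the
#' analyzable region (`void & !excluded`). Components partially overlapping
#' the exclusion mask are clipped to the analyzable region, not dropped --
#' dropping would bias against large voids near the FAZ. Components smaller
#' than `min_void_px` are discarded (default 1, i.e. none).
#'
#' @param seg a [VoidSegmentation-class].
#' @param mask an [ExclusionMask-class], or `NULL` for no exclusion.
#' @param min_void_px smallest component kept, in pixels.
#' @return A [VoidComponents-class].
#' @export
labelFlowVoids <- function(seg, mask = NULL, min_void_px = 1L) {
  stopifnot(is(seg, "VoidSegmentation"))
  void <- seg@voidMap
  if (!is.null(mask)) {
    excl <- if (is(mask, "ExclusionMask")) mask@excluded else mask
    if (!identical(dim(excl), dim(void)))
      stop("segmentation and exclusion mask dimensions differ", call. = FALSE)
    void <- void & !excl
    analyzable <- sum(!excl)
  } else {
    analyzable <- length(void)
  }
  .label8(void, min_void_px = as.integer(min_void_px),
          analyzable_px = analyzable)
}

#' Per-eye flow-void metrics from labeled components
#'
#' `total_area = sum(areas) * pitch^2 / 1e6` (mm^2);
#' `mean_size = mean(areas) * pitch^2` (um^2); `void_count = n`.
#' With zero components the count and total area are 0 and the mean size is
#' reported as missing (`NA`), not zero.
#'
#' @param components a [VoidComponents-class].
#' @param pixel_pitch um per pixel.
#' @param vdi optional vessel diameter index to carry along (see
#'   [vesselDiameterIndex()]).
#' @return A [FlowVoidMetrics-class].
#' @export
flowVoidMetrics <- function(components, pixel_pitch, vdi = NA_real_) {
  stopifnot(is(components, "VoidComponents"))
  a <- components@areas
  n <- length(a)
  new("FlowVoidMetrics",
      voidCount = as.integer(n),
      totalArea = sum(a) * pixel_pitch^2 / 1e6,
      meanSize = if (n > 0) mean(a) * pixel_pitch^2 else NA_real_,
      vdi = as.numeric(vdi),
      analyzableArea = components@analyzablePx * pixel_pitch^2 / 1e6,
      pixelPitch = pixel_pitch)
}

#' Skeletonize a binary vessel map
#'
#' Topology-preserving Zhang-Suen thinning down to a one-pixel-wide
#' centerline.
#'
#' @param vessel logical matrix (`TRUE` = vessel).
#' @return logical matrix skeleton.
#' @export
skeletonize <- function(vessel) {
  stopifnot(is.logical(vessel), is.matrix(vessel))
  zhang_suen_thin(vessel)
}

#' Vessel diameter index (average vessel caliber)
#'
#' VDI = total vessel area / total vessel length = (vessel pixel count) /
#' (skeleton pixel count), both restricted to the analyzable region.
#' Reported in pixels; multiply by the pixel pitch for um.
#'
#' @param vessel logical vessel map (e.g. from [invertToVessels()]).
#' @param mask an [ExclusionMask-class] or logical matrix, or `NULL`.
#' @return VDI in pixels (> 0). Errors on an empty vessel map (undefined).
#' @export
vesselDiameterIndex <- function(vessel, mask = NULL) {
  stopifnot(is.logical(vessel), is.matrix(vessel))
  if (!is.null(mask)) {
    excl <- if (is(mask, "ExclusionMask")) mask@excluded else mask
    if (!identical(dim(excl), dim(vessel)))
      stop("vessel map and exclusion mask dimensions differ", call. = FALSE)
    vessel <- vessel & !excl
  }
  if (!any(vessel))
    stop("vessel map is empty within the analyzable region; VDI is undefined",
         call. = FALSE)
  sk <- zhang_suen_thin(vessel)
  sum(vessel) / sum(sk)
}
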