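# Shared low-level image helpers.

# Translate image content by (dy, dx) pixels (subpixel allowed) with bilinear
# interpolation: out[r, c] = img[r - dy, c - dx]. Pixels whose source falls
# off canvas are set to `fill` and flagged invalid.
.apply_shift <- function(img, dy, dx, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  r <- matrix(seq_len(nr), nr, nc) - dy
  cl <- matrix(rep(seq_len(nc), each = nr), nr, nc) - dx
  valid <- r >= 1 & r <= nr & cl >= 1 & cl <= nc
  r0 <- pmin(pmax(floor(r), 1), nr - 1L)
  c0 <- pmin(pmax(floor(cl), 1), nc - 1L)
  fr <- r - r0; fc <- cl - c0
  i00 <- r0 + (c0 - 1L) * nr
  out <- (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i00 + 1L] +
    (1 - fr) * fc * img[i00 + nr] + fr * fc * img[i00 + nr + 1L]
  out[!valid] <- fill
  dim(out) <- c(nr, nc)
  list(intensity = out, valid = valid)
}

# Symmetric (reflective, edge-duplicating) padding by r pixels on every side.
.reflect_pad <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  if (r >= nr || r >= nc)
    stop("padding radius must be smaller than the image", call. = FALSE)
  x[c(r:1, 1:nr, nr:(nr - r + 1)), c(r:1, 1:nc, nc:(nc - r + 1))]
}

.hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

.as_intensity <- function(x) {
  if (is(x, "AveragedEnFace") || is(x, "EnFaceFrame")) return(intensity(x))
  if (is(x, "GroundTruthImage")) return(x@pristineIntensity)
  if (is.matrix(x)) return(x)
  stop("expected an image object or matrix", call. = FALSE)
}

#' Contrast-to-noise ratio against a ground-truth perfusion mask
#'
#' CNR = (mean over perfused pixels - mean over void pixels) /
#' sqrt((var_perfused + var_void) / 2). Used to quantify how multi-frame
#' averaging turns the granular single-frame appearance into a continuous
#' meshwork.
#'
#' @param image an image object or numeric matrix.
#' @param perfusion logical matrix, `TRUE` where truly perfused.
#' @return CNR (dimensionless).
#' @export
contrastToNoise <- function(image, perfusion) {
  img <- .as_intensity(image)
  stopifnot(identical(dim(img), dim(perfusion)))
  v <- img[perfusion]; b <- img[!perfusion]
  (mean(v) - mean(b)) / sqrt((stats::var(v) + stats::var(b)) / 2)
}
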