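.fail_param <- function(field, why) {
  stop(sprintf("invalid parameter '%s': %s", field, why), call. = FALSE)
}

.need_scalar <- function(x, field, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x))
    .fail_param(field, "must be a single finite number")
  if ((strict_lo && x <= lo) || (!strict_lo && x < lo) || x > hi)
    .fail_param(field, sprintf("must be in %s%g, %g]",
                               if (strict_lo) "(" else "[", lo, hi))
  invisible(x)
}

#' Parameters of the synthetic choriocapillaris meshwork
#'
#' The synthetic ground truth is an anastomosing capillary network built from
#' the edges of a Voronoi tessellation of random lobule seeds, dilated to
#' capillary caliber. Defaults emulate a healthy macular 3 x 3-mm scan:
#' 300 px at 10 um/px and an 11% flow-void fraction (about 1 mm^2 of voids
#' on 9 mm^2). The default seed density of 205 lobules per mm^2 corresponds
#' to an intercapillary lobule spacing of roughly 70 um, the macular lobule
#' scale; each lobule interior that survives the capillary band becomes one
#' flow void.
#'
#' When `vessel_width` is `NULL` (default) the edge-band width is calibrated
#' internally so the realized void fraction hits `void_fraction_target`;
#' when given explicitly (in um) it takes precedence and the target is not
#' enforced (a saturating width simply yields zero voids).
#'
#' @param grid_size pixels per side (>= 64).
#' @param pixel_pitch um per pixel (> 0).
#' @param seed_density capillary lobule seeds per mm^2.
#' @param vessel_width mean capillary caliber in um, or `NULL` to calibrate.
#' @param void_fraction_target fraction of the field that is flow void, in (0, 1).
#' @return A validated parameter list of class `MeshworkParams`.
#' @export
meshworkParams <- function(grid_size = 300L, pixel_pitch = 10,
                           seed_density = 205, vessel_width = NULL,
                           void_fraction_target = 0.11) {
  .need_scalar(grid_size, "grid_size", lo = 64)
  .need_scalar(pixel_pitch, "pixel_pitch", lo = 0, strict_lo = TRUE)
  .need_scalar(seed_density, "seed_density", lo = 0, strict_lo = TRUE)
  if (!is.null(vessel_width))
    .need_scalar(vessel_width, "vessel_width", lo = 0, strict_lo = TRUE)
  .need_scalar(void_fraction_target, "void_fraction_target",
               lo = 0, hi = 1, strict_lo = TRUE)
  if (void_fraction_target >= 1)
    .fail_param("void_fraction_target", "must be in (0, 1)")
  structure(list(grid_size = as.integer(grid_size), pixel_pitch = pixel_pitch,
                 seed_density = seed_density, vessel_width = vessel_width,
                 void_fraction_target = void_fraction_target),
            class = "MeshworkParams")
}

#' Parameters of the synthetic acquisition (frame degradation)
#'
#' Controls how pristine ground truth is degraded into the 4--9 repeated en
#' face frames of one eye: an optical point-spread blur, per-pixel signal
#' dropout on perfused pixels (applied before noise, so averaging provably
#' recovers the perfusion support), multiplicative log-normal speckle, and a
#' random inter-frame translation. Frame 1 is the anchor: it carries zero
#' injected shift and the top quality score, so the registered canvas
#' coincides with the ground-truth canvas.
#'
#' The noise defaults model frames that already passed the device
#' signal-strength gate (score >= 8 of 10): speckle is the dominant
#' degradation and its scale (0.15) is calibrated so that averaging six or
#' more frames suppresses binarization flips of perfused pixels, while a
#' single frame still over-reads the void area substantially; total signal
#' dropout is correspondingly sparse (2% of perfused pixels per frame).
#'
#' @param n_frames number of repeated frames, 4--9.
#' @param speckle_sigma log-scale SD of the multiplicative speckle (0 = none).
#' @param dropout_prob per-frame probability that a perfused pixel loses
#'   signal (the "granular" look of single frames).
#' @param max_shift maximum injected |dx|, |dy| translation in pixels.
#' @param psf_sigma Gaussian optical blur SD in pixels (0 = none).
#' @param quality_scores integer vector (0--10) per frame, or `NULL` for the
#'   default `c(10, 9, 9, ...)`.
#' @return A validated parameter list of class `AcquisitionParams`.
#' @export
acquisitionParams <- function(n_frames = 6L, speckle_sigma = 0.15,
                              dropout_prob = 0.02, max_shift = 6,
                              psf_sigma = 0.5, quality_scores = NULL) {
  .need_scalar(n_frames, "n_frames", lo = 4, hi = 9)
  .need_scalar(speckle_sigma, "speckle_sigma", lo = 0)
  .need_scalar(dropout_prob, "dropout_prob", lo = 0, hi = 1)
  .need_scalar(max_shift, "max_shift", lo = 0)
  .need_scalar(psf_sigma, "psf_sigma", lo = 0)
  n_frames <- as.integer(n_frames)
  if (is.null(quality_scores))
    quality_scores <- c(10L, rep(9L, n_frames - 1L))
  if (length(quality_scores) != n_frames ||
      any(quality_scores < 0 | quality_scores > 10))
    .fail_param("quality_scores", "must be n_frames integers in 0..10")
  structure(list(n_frames = n_frames, speckle_sigma = speckle_sigma,
                 dropout_prob = dropout_prob, max_shift = max_shift,
                 psf_sigma = psf_sigma,
                 quality_scores = as.integer(quality_scores)),
            class = "AcquisitionParams")
}

#' Parameters of the synthetic cohort generator
#'
#' A linear-Gaussian statistical twin of a healthy-eye choriocapillaris
#' cohort. Covariates (age, axial length, subfoveal choroidal thickness) are
#' drawn from (truncated) normals; metrics are linear in one covariate plus a
#' Gaussian residual:
#' total area and mean void size depend on age, VDI depends on SFCT, and the
#' void count is age-independent (optionally SFCT-dependent via
#' `count_sfct_slope`, default 0).
#'
#' The intercepts and residual SDs are derived algebraically from the
#' marginal means/SDs and the per-year slopes of the cohort being emulated:
#' `intercept = marginal mean - slope * covariate mean` and
#' `resid_sd = sqrt(marginal_sd^2 - (slope * covariate_sd)^2)`. With the
#' defaults this gives marginal SDs of 0.20 mm^2 (total area), 201.5 um^2
#' (size) and 0.49 (VDI).
#'
#' Truncated covariates are moment-matched: the underlying normal is solved
#' so that the truncated distribution has exactly the requested mean and SD.
#'
#' @param n_subjects cohort size.
#' @param age_mean,age_sd realized mean/SD of age in years.
#' @param age_bounds truncation interval for age.
#' @param sfct_mean,sfct_sd subfoveal choroidal thickness, um.
#' @param axl_mean,axl_sd axial length, mm (upper-truncated at `axl_max`).
#' @param axl_max intake cutoff for axial length, mm.
#' @param ta_intercept,ta_age_slope,ta_resid_sd total flow-void area model
#'   (mm^2, mm^2/year, mm^2).
#' @param size_intercept,size_age_slope,size_resid_sd mean void size model
#'   (um^2, um^2/year, um^2).
#' @param count_mean,count_sd flow-void count marginal moments.
#' @param count_sfct_slope optional voids-per-um-SFCT slope (default 0).
#' @param vdi_intercept,vdi_sfct_slope,vdi_resid_sd VDI model (px, px/um, px).
#' @param sex_ratio fraction male.
#' @return A validated parameter list of class `CohortParams`.
#' @export
cohortParams <- function(n_subjects = 81L,
                         age_mean = 59.5, age_sd = 16.2,
                         age_bounds = c(20, 90),
                         sfct_mean = 238.7, sfct_sd = 56.8,
                         axl_mean = 24.26, axl_sd = 1.14, axl_max = 27,
                         ta_intercept = 0.740, ta_age_slope = 4.20e-3,
                         ta_resid_sd = 0.188,
                         size_intercept = 385.1, size_age_slope = 3.07,
                         size_resid_sd = 195.3,
                         count_mean = 1851, count_sd = 375,
                         count_sfct_slope = 0,
                         vdi_intercept = 5.044, vdi_sfct_slope = 3.252e-3,
                         vdi_resid_sd = 0.4538,
                         sex_ratio = 37 / 81) {
  .need_scalar(n_subjects, "n_subjects", lo = 1)
  for (f in c("age_sd", "sfct_sd", "axl_sd"))
    .need_scalar(get(f), f, lo = 0, strict_lo = TRUE)
  # residual SDs of 0 are allowed: they give the degenerate noise-free model
  for (f in c("ta_resid_sd", "size_resid_sd", "count_sd", "vdi_resid_sd"))
    .need_scalar(get(f), f, lo = 0)
  for (f in c("age_mean", "sfct_mean", "axl_mean", "axl_max", "ta_intercept",
              "ta_age_slope", "size_intercept", "size_age_slope", "count_mean",
              "count_sfct_slope", "vdi_intercept", "vdi_sfct_slope"))
    .need_scalar(get(f), f)
  .need_scalar(sex_ratio, "sex_ratio", lo = 0, hi = 1)
  if (length(age_bounds) != 2 || age_bounds[1] >= age_bounds[2])
    .fail_param("age_bounds", "must be an increasing interval")
  if ((count_sfct_slope * sfct_sd)^2 >= count_sd^2)
    .fail_param("count_sfct_slope",
                "implies a negative residual variance for the void count")
  structure(mget(c("n_subjects", "age_mean", "age_sd", "age_bounds",
                   "sfct_mean", "sfct_sd", "axl_mean", "axl_sd", "axl_max",
                   "ta_intercept", "ta_age_slope", "ta_resid_sd",
                   "size_intercept", "size_age_slope", "size_resid_sd",
                   "count_mean", "count_sd", "count_sfct_slope",
                   "vdi_intercept", "vdi_sfct_slope", "vdi_resid_sd",
                   "sex_ratio")),
            class = "CohortParams")
}

#' Parameters of the Phansalkar local threshold
#'
#' Per-pixel threshold over a circular window of the given radius:
#' `t = mu * (1 + p * exp(-q * mu) + k * (sigma / r - 1))`, with `mu`,
#' `sigma` the local mean and SD. `k`, `r`, `p`, `q` default to the method's
#' original values; the window radius is the one genuinely free knob and
#' defaults to 15 px (150 um at 10 um/px, several intercapillary distances).
#'
#' @param radius window radius in pixels (>= 1).
#' @param k threshold slope on the normalized local SD.
#' @param r normalization of the local SD (for images in \[0, 1\]).
#' @param p,q amplitude and decay of the low-mean correction term.
#' @return A validated parameter list of class `PhansalkarParams`.
#' @export
phansalkarParams <- function(radius = 15L, k = 0.25, r = 0.5, p = 2.0, q = 10.0) {
  .need_scalar(radius, "radius", lo = 1)
  .need_scalar(k, "k")
  .need_scalar(r, "r", lo = 0, strict_lo = TRUE)
  .need_scalar(p, "p")
  .need_scalar(q, "q")
  structure(list(radius = as.integer(radius), k = k, r = r, p = p, q = q),
            class = "PhansalkarParams")
}

#' Pipeline configuration
#'
#' One declarative object carrying every tunable of the per-eye pipeline:
#' quality gating, registration, binarization, exclusion and quantification.
#' Round-trips losslessly through YAML via [writePipelineConfig()] /
#' [readPipelineConfig()].
#'
#' @param min_quality minimum signal-strength score (frames with
#'   `qualityScore >= min_quality` are kept; default 8 of 10).
#' @param min_frames minimum surviving frames per eye (default 4).
#' @param phansalkar a [phansalkarParams()] list.
#' @param pixel_pitch um per pixel.
#' @param faz_radius_um radius of the central foveal-avascular-zone exclusion
#'   disc, um.
#' @param caliber_cutoff_um retinal vessels wider than this (on the SCP
#'   image) are excluded, um.
#' @param vessel_dilation_px safety margin dilated around excluded vessels, px.
#' @param min_void_px smallest flow-void component kept, px (default 1 = keep all).
#' @param registration_floor minimum post-alignment correlation between a
#'   frame and the reference; frames below it are dropped.
#' @param max_search_px registration search radius, px.
#' @param seed integer seed for any stochastic step.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(min_quality = 8L, min_frames = 4L,
                           phansalkar = phansalkarParams(),
                           pixel_pitch = 10, faz_radius_um = 250,
                           caliber_cutoff_um = 30, vessel_dilation_px = 2L,
                           min_void_px = 1L, registration_floor = 0.2,
                           max_search_px = 20, seed = 1L) {
  .need_scalar(min_quality, "min_quality", lo = 0, hi = 10)
  .need_scalar(min_frames, "min_frames", lo = 1)
  .need_scalar(pixel_pitch, "pixel_pitch", lo = 0, strict_lo = TRUE)
  .need_scalar(faz_radius_um, "faz_radius_um", lo = 0)
  if (length(caliber_cutoff_um) != 1 || !is.numeric(caliber_cutoff_um) ||
      is.na(caliber_cutoff_um) || caliber_cutoff_um < 0)
    .fail_param("caliber_cutoff_um", "must be a single non-negative number (Inf allowed)")
  .need_scalar(vessel_dilation_px, "vessel_dilation_px", lo = 0)
  .need_scalar(min_void_px, "min_void_px", lo = 1)
  .need_scalar(registration_floor, "registration_floor", lo = -1, hi = 1)
  .need_scalar(max_search_px, "max_search_px", lo = 1)
  .need_scalar(seed, "seed")
  if (!inherits(phansalkar, "PhansalkarParams"))
    phansalkar <- do.call(phansalkarParams, as.list(phansalkar))
  structure(list(min_quality = as.integer(min_quality),
                 min_frames = as.integer(min_frames),
                 phansalkar = phansalkar, pixel_pitch = pixel_pitch,
                 faz_radius_um = faz_radius_um,
                 caliber_cutoff_um = caliber_cutoff_um,
                 vessel_dilation_px = as.integer(vessel_dilation_px),
                 min_void_px = as.integer(min_void_px),
                 registration_floor = registration_floor,
                 max_search_px = max_search_px, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipelineConfig()] object.
#' @param path file path.
#' @return `readPipelineConfig` returns the reconstructed `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  x <- unclass(config)
  x$phansalkar <- unclass(x$phansalkar)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$phansalkar <- do.call(phansalkarParams, x$phansalkar)
  do.call(pipelineConfig, x)
}
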