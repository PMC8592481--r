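#' Run the full per-eye pipeline
#'
#' filter -> register -> average -> binarize -> mask -> quantify, with any
#' stage failure captured as a per-eye failure record (the batch goes on).
#' Deterministic given the stack and config.
#'
#' @param stack a [FrameStack-class].
#' @param config a [pipelineConfig()].
#' @param keep_images keep the averaged image, segmentation and mask in the
#'   result (for inspection; off by default).
#' @return list of class `eye_result`: `eye_id`, `status` (`"ok"`,
#'   `"excluded"` or `"failed"`), and for `"ok"` the
#'   [FlowVoidMetrics-class] plus a provenance list; otherwise `stage` and
#'   `reason`.
#' @export
runEye <- function(stack, config = pipelineConfig(), keep_images = FALSE) {
  stopifnot(is(stack, "FrameStack"), inherits(config, "PipelineConfig"))
  eye_id <- stack@eyeId
  stage <- "filter"
  tryCatch({
    fl <- filterFrames(stack, config$min_quality, config$min_frames)
    if (isExcluded(fl)) return(structure(unclass(fl), class = "eye_result"))
    stage <- "register"
    reg <- registerStack(fl, config)
    if (isExcluded(reg)) return(structure(unclass(reg), class = "eye_result"))
    stage <- "average"
    avg_cc <- averageStack(reg, "cc", config$min_frames)
    avg_scp <- averageStack(reg, "scp", config$min_frames)
    stage <- "binarize"
    seg <- phansalkarBinarize(avg_cc, config$phansalkar)
    stage <- "mask"
    mask <- buildExclusionMask(avg_scp, pixel_pitch = config$pixel_pitch,
                               faz_radius_um = config$faz_radius_um,
                               caliber_cutoff_um = config$caliber_cutoff_um,
                               dilation_px = config$vessel_dilation_px)
    # pixels never covered by any registered frame are not analyzable
    mask <- new("ExclusionMask",
                excluded = mask@excluded | (avg_cc@support == 0),
                components = c(mask@components,
                               list(no_support = avg_cc@support == 0)))
    stage <- "quantify"
    comps <- labelFlowVoids(seg, mask, config$min_void_px)
    vessels <- invertToVessels(seg)
    vdi <- vesselDiameterIndex(vessels, mask)
    metrics <- flowVoidMetrics(comps, config$pixel_pitch, vdi = vdi)
    out <- list(eye_id = eye_id, status = "ok", metrics = metrics,
                provenance = list(
                  n_frames_used = nFrames(avg_cc),
                  reference_frame = reg@transforms$reference[1],
                  transforms = reg@transforms,
                  config = c(unclass(config)["min_quality"],
                             phansalkar = list(unclass(config$phansalkar)),
                             pixel_pitch = config$pixel_pitch,
                             faz_radius_um = config$faz_radius_um)))
    if (keep_images)
      out$images <- list(averaged = avg_cc, averaged_scp = avg_scp,
                         segmentation = seg, mask = mask)
    structure(out, class = "eye_result")
  }, error = function(e) {
    structure(list(eye_id = eye_id, status = "failed", stage = stage,
                   reason = conditionMessage(e)), class = "eye_result")
  })
}

#' @export
print.eye_result <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("Eye '%s': ok (%d frames averaged)\n", x$eye_id,
                x$provenance$n_frames_used))
    show(x$metrics)
  } else {
    cat(sprintf("Eye '%s': %s at stage '%s' (%s)\n", x$eye_id, x$status,
                x$stage, x$reason))
  }
  invisible(x)
}

#' Run the pipeline over a cohort of eyes
#'
#' Runs [runEye()] for every stack, keeps the exclusion accounting
#' (recruited = analyzed + excluded, with per-eye reasons), joins the
#' per-eye metrics to the supplied covariates, and -- when covariates are
#' available -- computes the full [cohortStats()] report.
#'
#' @param stacks named list of [FrameStack-class] objects, or a manifest CSV
#'   path readable by [readFrameStacks()].
#' @param config a [pipelineConfig()].
#' @param covariates optional data.frame with `eye_id` plus subject
#'   covariates (`subject_id`, `age`, `sex`, `axial_length_mm`, `sfct_um`).
#' @return list of class `cohort_run`: `cohort` (joined table),
#'   `accounting` (`recruited`, `analyzed`, `excluded` data.frame),
#'   `stats` (report or `NULL`), `results` (per-eye records).
#' @export
runCohort <- function(stacks, config = pipelineConfig(), covariates = NULL) {
  if (is.character(stacks)) stacks <- readFrameStacks(stacks)
  if (length(stacks) == 0) stop("empty manifest: no eyes to analyze", call. = FALSE)
  results <- lapply(stacks, runEye, config = config)
  ok <- vapply(results, function(r) r$status == "ok", logical(1))
  if (!any(ok)) {
    reasons <- vapply(results, function(r) paste0(r$eye_id, ": ", r$reason), "")
    stop("all eyes failed:\n  ", paste(reasons, collapse = "\n  "), call. = FALSE)
  }
  excluded <- do.call(rbind, lapply(results[!ok], function(r)
    data.frame(eye_id = r$eye_id, stage = r$stage, reason = r$reason)))
  if (is.null(excluded))
    excluded <- data.frame(eye_id = character(0), stage = character(0),
                           reason = character(0))
  cohort <- do.call(rbind, lapply(results[ok], function(r)
    cbind(data.frame(eye_id = r$eye_id), as.data.frame(r$metrics))))
  rownames(cohort) <- NULL
  if (!is.null(covariates)) {
    stopifnot("eye_id" %in% names(covariates))
    cohort <- merge(covariates, cohort, by = "eye_id", sort = FALSE)
  }
  stats_report <- NULL
  needed <- c("age", "axial_length_mm", "sfct_um", "sex")
  if (all(needed %in% names(cohort)) && nrow(cohort) >= 5)
    stats_report <- cohortStats(cohort,
                                metrics = intersect(
                                  c("total_area_mm2", "mean_size_um2",
                                    "void_count", "vdi"), names(cohort)))
  structure(list(cohort = cohort,
                 accounting = list(recruited = length(stacks),
                                   analyzed = sum(ok),
                                   excluded = excluded),
                 stats = stats_report, results = results),
            class = "cohort_run")
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf("Cohort run: %d eyes recruited, %d analyzed, %d excluded\n",
              x$accounting$recruited, x$accounting$analyzed,
              nrow(x$accounting$excluded)))
  if (nrow(x$accounting$excluded))
    for (i in seq_len(nrow(x$accounting$excluded)))
      cat(sprintf("  - %s (%s: %s)\n", x$accounting$excluded$eye_id[i],
                  x$accounting$excluded$stage[i], x$accounting$excluded$reason[i]))
  invisible(x)
}
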