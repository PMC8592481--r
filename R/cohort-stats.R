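.check_xy <- function(x, y, min_n = 3L) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric", call. = FALSE)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < min_n)
    stop(sprintf("need at least %d observations", min_n), call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  invisible(length(x))
}

.corr_result <- function(r, p, n, df, covariates = character(0)) {
  structure(list(r = r, p_value = p, n = n, df = df, covariates = covariates),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  adj <- if (length(x$covariates))
    sprintf(" (adjusted for %s)", paste(x$covariates, collapse = ", ")) else ""
  cat(sprintf("r = %.3f, p = %.4g, n = %d, df = %d%s\n",
              x$r, x$p_value, x$n, x$df, adj))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Product-moment r with a two-sided p-value from the t distribution on
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite, non-constant).
#' @return A `corr_result`: `r`, `p_value`, `n`, `df`, `covariates` (empty).
#' @examples
#' pearsonCorr(c(1, 2, 3), c(1, 3, 2))   # r = 0.5
#' @export
pearsonCorr <- function(x, y) {
  n <- .check_xy(x, y)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance in x or y", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  .corr_result(unname(ct$estimate), ct$p.value, n, unname(ct$parameter))
}

#' Partial correlation (covariate-adjusted)
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on the covariates; the p-value uses n - 2 - k degrees of
#' freedom for k covariates. With no covariates this is exactly
#' [pearsonCorr()].
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data.frame of covariates
#'   (or `NULL`).
#' @return A `corr_result` carrying the covariate names.
#' @export
partialCorr <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0 ||
      (is.data.frame(covariates) && ncol(covariates) == 0))
    return(pearsonCorr(x, y))
  Z <- as.matrix(covariates)
  storage.mode(Z) <- "double"
  k <- ncol(Z)
  .check_xy(x, y, min_n = k + 3L)
  if (nrow(Z) != length(x)) stop("covariates must match x in length", call. = FALSE)
  if (!all(is.finite(Z))) stop("covariates must be finite", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("collinear covariates: design matrix is rank deficient", call. = FALSE)
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  if (stats::sd(rx) <= 1e-12 * (stats::sd(x) + 1e-300) ||
      stats::sd(ry) <= 1e-12 * (stats::sd(y) + 1e-300))
    stop("partial correlation undefined: zero residual variance after adjustment",
         call. = FALSE)
  r <- stats::cor(rx, ry)
  df <- length(x) - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  nm <- colnames(Z)
  if (is.null(nm)) nm <- paste0("z", seq_len(k))
  .corr_result(r, p, length(x), df, covariates = nm)
}

#' Levene-gated two-group comparison, optionally age-adjusted
#'
#' Levene's test (center = mean, the classic form) decides the t-test
#' branch: pooled-variance Student's t when Levene's p >= 0.05, Welch's t
#' otherwise. When an age covariate is supplied, the age-adjusted p-value is
#' the group-coefficient p from the linear model `value ~ group + age`
#' (ANCOVA-style -- a partial correlation is ill-defined for a binary
#' grouping reported via t tests).
#'
#' @param values numeric vector.
#' @param group factor/character with exactly two levels, each n >= 2.
#' @param age optional numeric covariate.
#' @return list of class `group_comparison`: `levene_p`, `method`
#'   (`"student"` or `"welch"`), `t`, `df`, `p_value`, `p_age_adjusted`
#'   (`NA` without `age`), `group_means`.
#' @export
groupCompare <- function(values, group, age = NULL) {
  g <- droplevels(factor(group))
  if (nlevels(g) != 2)
    stop("group must have exactly two levels", call. = FALSE)
  if (any(table(g) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  v1 <- values[g == levels(g)[1]]; v2 <- values[g == levels(g)[2]]
  degenerate <- stats::sd(v1) == 0 && stats::sd(v2) == 0
  lev_p <- if (degenerate) 1 else {
    lt <- suppressWarnings(car::leveneTest(values ~ g, center = mean))
    p <- lt[1, "Pr(>F)"]
    if (!is.finite(p)) 1 else p
  }
  var_equal <- lev_p >= 0.05
  if (degenerate && mean(v1) == mean(v2)) {
    tt <- list(statistic = 0, parameter = length(values) - 2, p.value = 1)
  } else {
    tt <- stats::t.test(v1, v2, var.equal = var_equal)
  }
  p_adj <- NA_real_
  if (!is.null(age)) {
    stopifnot(length(age) == length(values))
    fit <- stats::lm(values ~ g + age)
    p_adj <- stats::coef(summary(fit))[2, "Pr(>|t|)"]
  }
  structure(list(levene_p = lev_p,
                 method = if (var_equal) "student" else "welch",
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, p_age_adjusted = p_adj,
                 group_means = stats::setNames(c(mean(v1), mean(v2)), levels(g))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s t test (Levene p = %.3g): t = %.3f, df = %.1f, p = %.4g\n",
              x$method, x$levene_p, x$t, x$df, x$p_value))
  if (is.finite(x$p_age_adjusted))
    cat(sprintf("  age-adjusted group p = %.4g\n", x$p_age_adjusted))
  invisible(x)
}

#' Ordinary least-squares trend
#'
#' @param x,y numeric vectors (n >= 3; x non-constant).
#' @return list with `slope` (per unit of x, e.g. per year when x is age)
#'   and `intercept`.
#' @export
linearTrend <- function(x, y) {
  .check_xy(x, y)
  if (stats::var(x) == 0)
    stop("trend undefined: zero variance in x", call. = FALSE)
  cf <- stats::coef(stats::lm(y ~ x))
  list(slope = unname(cf[2]), intercept = unname(cf[1]))
}

#' Per-age-group summaries of the choriocapillaris metrics
#'
#' Mean and SD of each metric within the age bins \[20, 40), \[40, 60) and
#' \[60, Inf). An empty bin is reported as missing (`NA`), never as zero.
#'
#' @param cohort cohort data.frame with an `age` column.
#' @param metrics metric columns to summarize.
#' @return data.frame: `age_group`, `metric`, `n`, `mean`, `sd`.
#' @export
ageGroupSummary <- function(cohort,
                            metrics = c("total_area_mm2", "mean_size_um2",
                                        "void_count", "vdi")) {
  stopifnot("age" %in% names(cohort), all(metrics %in% names(cohort)))
  bins <- cut(cohort$age, breaks = c(20, 40, 60, Inf), right = FALSE,
              labels = c("20-39", "40-59", "60+"))
  if (anyNA(bins))
    warning("ages below 20 fall outside the age-group bins and are dropped")
  out <- expand.grid(age_group = levels(bins), metric = metrics,
                     stringsAsFactors = FALSE)
  out$n <- 0L; out$mean <- NA_real_; out$sd <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- cohort[[out$metric[i]]][!is.na(bins) & bins == out$age_group[i]]
    out$n[i] <- length(v)
    if (length(v) > 0) {
      out$mean[i] <- mean(v)
      out$sd[i] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
  }
  out
}

#' Full cohort statistics report
#'
#' Reproduces the statistical layer of a choriocapillaris cohort study:
#' for each metric (total area, mean size, count, VDI) the Pearson
#' correlations with age, axial length and SFCT; age-adjusted partial
#' correlations for axial length and SFCT; the Levene-gated, age-adjusted
#' sex comparison; OLS age trends; and per-age-group summaries.
#'
#' @param cohort cohort data.frame (schema of [simulateCohort()]).
#' @param metrics metric columns to analyze.
#' @return list of class `cohort_stats_report` with elements `n`, `summary`,
#'   `correlations`, `partial_correlations`, `sex_comparisons`, `trends`,
#'   `age_groups`.
#' @export
cohortStats <- function(cohort,
                        metrics = c("total_area_mm2", "mean_size_um2",
                                    "void_count", "vdi")) {
  stopifnot(all(c("age", "axial_length_mm", "sfct_um", "sex") %in% names(cohort)),
            all(metrics %in% names(cohort)))
  if (anyDuplicated(cohort$subject_id))
    stop("duplicate subject_id: one eye per subject is required", call. = FALSE)
  covs <- c(age = "age", axial_length = "axial_length_mm", sfct = "sfct_um")
  corrs <- list(); pcorrs <- list(); sexcmp <- list(); trends <- list()
  for (m in metrics) {
    y <- cohort[[m]]
    corrs[[m]] <- lapply(covs, function(cv) pearsonCorr(cohort[[cv]], y))
    pcorrs[[m]] <- lapply(covs[-1], function(cv)
      partialCorr(cohort[[cv]], y, covariates = data.frame(age = cohort$age)))
    sexcmp[[m]] <- groupCompare(y, cohort$sex, age = cohort$age)
    trends[[m]] <- linearTrend(cohort$age, y)
  }
  num <- c("age", "axial_length_mm", "sfct_um", metrics)
  summ <- data.frame(variable = num,
                     mean = vapply(num, function(v) mean(cohort[[v]]), 0),
                     sd = vapply(num, function(v) stats::sd(cohort[[v]]), 0))
  structure(list(n = nrow(cohort), summary = summ,
                 sex_counts = table(cohort$sex),
                 correlations = corrs, partial_correlations = pcorrs,
                 sex_comparisons = sexcmp, trends = trends,
                 age_groups = ageGroupSummary(cohort, metrics)),
            class = "cohort_stats_report")
}

#' @export
print.cohort_stats_report <- function(x, ...) {
  cat(sprintf("Cohort statistics report: n = %d eyes (%s)\n", x$n,
              paste(sprintf("%d %s", x$sex_counts, names(x$sex_counts)),
                    collapse = ", ")))
  cat("\nSummary (mean +/- SD):\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-16s %8.3f +/- %.3f\n", x$summary$variable[i],
                x$summary$mean[i], x$summary$sd[i]))
  cat("\nCorrelations with age:\n")
  for (m in names(x$correlations)) {
    cr <- x$correlations[[m]]$age
    cat(sprintf("  %-16s r = %6.3f, p = %.4g\n", m, cr$r, cr$p_value))
  }
  cat("\nAge trends (per year):\n")
  for (m in names(x$trends))
    cat(sprintf("  %-16s slope = %.4g\n", m, x$trends[[m]]$slope))
  invisible(x)
}

.unclass_rec <- function(x) {
  if (is.environment(x)) return(NULL)
  if (inherits(x, "table")) return(as.list(stats::setNames(as.vector(x), names(x))))
  if (is.list(x)) return(lapply(unclass(x), .unclass_rec))
  x
}

#' Write a statistics report as JSON
#'
#' @param report a `cohort_stats_report` from [cohortStats()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeStatsReport <- function(report, path) {
  jsonlite::write_json(.unclass_rec(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
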