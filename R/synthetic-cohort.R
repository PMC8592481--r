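# Moments of a normal(mu, sigma) truncated to [lo, hi].
.truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  ada <- if (is.finite(a)) a * da else 0
  bdb <- if (is.finite(b)) b * db else 0
  delta <- (da - db) / Z
  m <- mu + sigma * delta
  v <- sigma^2 * (1 + (ada - bdb) / Z - delta^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for the underlying (mu, sigma) such that the truncated distribution
# has exactly the requested mean and SD (moment matching). Without this,
# truncating N(59.5, 16.2) to [20, 90] would realize mean 58.7 and SD 14.6.
.match_truncnorm <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (!is.finite(lo) && !is.finite(hi)) return(c(mu = mean, sigma = sd))
  obj <- function(th) {
    m <- .truncnorm_moments(th[1], exp(th[2]), lo, hi)
    (m[1] - mean)^2 / sd^2 + (m[2] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse-CDF sampler for the truncated normal (deterministic in the RNG stream).
.rtruncnorm <- function(n, mu, sigma, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mu, sigma)
  phi <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(stats::runif(n, plo, phi), mu, sigma)
}

#' Simulate a statistical-twin cohort
#'
#' Draws a cohort of healthy subjects (one eye each) whose covariates and
#' choriocapillaris metrics follow the linear-Gaussian model of
#' [cohortParams()]: age and axial length from moment-matched truncated
#' normals, SFCT from a normal; total flow-void area and mean void size
#' linear in age, VDI linear in SFCT, void count age-independent; all with
#' Gaussian residuals. Deterministic given `seed`.
#'
#' @param params a [cohortParams()] list.
#' @param seed integer seed, or `NULL` to consume the current RNG stream
#'   (useful when replicating many cohorts under one outer seed).
#' @return data.frame with columns `subject_id`, `age`, `sex`, `eye`,
#'   `axial_length_mm`, `sfct_um`, `total_area_mm2`, `mean_size_um2`,
#'   `void_count`, `vdi`.
#' @examples
#' head(simulateCohort(cohortParams(), seed = 1))
#' @export
simulateCohort <- function(params = cohortParams(), seed = NULL) {
  if (!inherits(params, "CohortParams"))
    stop("params must come from cohortParams()", call. = FALSE)
  draw <- function() {
    n <- params$n_subjects
    ab <- .match_truncnorm(params$age_mean, params$age_sd,
                           params$age_bounds[1], params$age_bounds[2])
    age <- .rtruncnorm(n, ab["mu"], ab["sigma"],
                       params$age_bounds[1], params$age_bounds[2])
    xb <- .match_truncnorm(params$axl_mean, params$axl_sd, hi = params$axl_max)
    axl <- .rtruncnorm(n, xb["mu"], xb["sigma"], hi = params$axl_max)
    sfct <- stats::rnorm(n, params$sfct_mean, params$sfct_sd)
    n_male <- round(params$sex_ratio * n)
    sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
    eye <- sample(c("OD", "OS"), n, replace = TRUE)
    ta <- params$ta_intercept + params$ta_age_slope * age +
      stats::rnorm(n, 0, params$ta_resid_sd)
    sz <- params$size_intercept + params$size_age_slope * age +
      stats::rnorm(n, 0, params$size_resid_sd)
    count_resid <- sqrt(params$count_sd^2 -
                          (params$count_sfct_slope * params$sfct_sd)^2)
    count <- round(params$count_mean +
                     params$count_sfct_slope * (sfct - params$sfct_mean) +
                     stats::rnorm(n, 0, count_resid))
    vdi <- params$vdi_intercept + params$vdi_sfct_slope * sfct +
      stats::rnorm(n, 0, params$vdi_resid_sd)
    data.frame(subject_id = sprintf("S%04d", seq_len(n)),
               age = age, sex = factor(sex, levels = c("male", "female")),
               eye = eye, axial_length_mm = axl, sfct_um = sfct,
               total_area_mm2 = ta, mean_size_um2 = sz,
               void_count = count, vdi = vdi)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a cohort data.frame as produced by [simulateCohort()] or
#'   [runCohort()].
#' @param path file path.
#' @return `readCohort` returns the cohort data.frame.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("sex" %in% names(x)) x$sex <- factor(x$sex, levels = c("male", "female"))
  x
}
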