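test_that("pearson correlation matches hand-computed values", {
  expect_equal(pearsonCorr(c(1, 2, 3), c(2, 4, 6))$r, 1)
  # cov = 1/2, sd_x = sd_y = 1: r = 0.5
  res <- pearsonCorr(c(1, 2, 3), c(1, 3, 2))
  expect_equal(res$r, 0.5, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_error(pearsonCorr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearsonCorr(1:2, 2:3), "at least 3")
  expect_error(pearsonCorr(c(1, 2, NA), c(1, 2, 3)), "finite")
})

test_that("partial correlation with an orthogonal covariate equals simple r", {
  withr::with_seed(61, {
    x <- stats::rnorm(40); y <- x + stats::rnorm(40)
    z0 <- stats::rnorm(40)
    z <- stats::residuals(stats::lm(z0 ~ x + y))  # orthogonal by construction
  })
  simple <- pearsonCorr(x, y)
  partial <- partialCorr(x, y, covariates = data.frame(z = z))
  expect_equal(partial$r, simple$r, tolerance = 1e-10)
  expect_equal(partial$df, simple$df - 1)
})

test_that("partial correlation with no covariates is exactly pearson", {
  x <- c(0.3, 1.2, -0.5, 2.2, 0.8); y <- c(1.1, 0.2, 0.4, 1.9, -0.3)
  expect_identical(partialCorr(x, y), pearsonCorr(x, y))
  expect_identical(partialCorr(x, y, covariates = data.frame()),
                   pearsonCorr(x, y))
})

test_that("degenerate adjustments error", {
  withr::with_seed(62, {
    x <- stats::rnorm(30); z <- stats::rnorm(30)
  })
  expect_error(partialCorr(x, z, covariates = data.frame(z = z)),
               "zero residual variance")
  expect_error(partialCorr(x, x + z, covariates = cbind(z, 2 * z)),
               "collinear")
})

test_that("partial correlation matches the normal-equations oracle to 1e-10", {
  withr::with_seed(63, {
    for (rep in 1:20) {
      n <- 50
      Z <- cbind(z1 = stats::rnorm(n), z2 = stats::rnorm(n))
      x <- 0.5 * Z[, 1] + stats::rnorm(n)
      y <- -0.3 * Z[, 2] + 0.4 * x + stats::rnorm(n)
      got <- partialCorr(x, y, covariates = Z)
      # oracle: explicit normal-equations solve, then correlate residuals
      X <- cbind(1, Z)
      bx <- solve(crossprod(X), crossprod(X, x))
      by <- solve(crossprod(X), crossprod(X, y))
      rx <- x - X %*% bx; ry <- y - X %*% by
      r_o <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
      df <- n - 2 - 2
      t_o <- r_o * sqrt(df / (1 - r_o^2))
      p_o <- 2 * stats::pt(-abs(t_o), df)
      expect_equal(got$r, r_o, tolerance = 1e-10)
      expect_equal(got$p_value, p_o, tolerance = 1e-10)
    }
  })
})

test_that("identical groups compare as t = 0, p = 1", {
  res <- groupCompare(rep(c(1, 1, 2, 2), 2), rep(c("a", "b"), each = 4))
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
})

test_that("Levene gate picks Welch under variance inequality", {
  withr::with_seed(64, {
    v <- c(stats::rnorm(200, 0, 1), stats::rnorm(200, 0, 5))
  })
  g <- rep(c("a", "b"), each = 200)
  res <- groupCompare(v, g)
  expect_lt(res$levene_p, 0.05)
  expect_identical(res$method, "welch")

  withr::with_seed(65, {
    v2 <- c(stats::rnorm(200, 0, 1), stats::rnorm(200, 1, 1))
  })
  res2 <- groupCompare(v2, g)
  expect_gte(res2$levene_p, 0.05)
  expect_identical(res2$method, "student")
})

test_that("age-adjusted sex comparison reports the model coefficient p", {
  withr::with_seed(66, {
    age <- stats::runif(80, 20, 90)
    sex <- rep(c("male", "female"), 40)
    y <- 0.01 * age + stats::rnorm(80, 0, 0.1)
  })
  res <- groupCompare(y, sex, age = age)
  fit <- stats::lm(y ~ factor(sex, levels = c("male", "female")) + age)
  expect_equal(res$p_age_adjusted, stats::coef(summary(fit))[2, 4],
               tolerance = 1e-12)
  expect_error(groupCompare(y, rep("a", 80)), "two levels")
})

test_that("linear trend is exact on exact lines and ties to r", {
  x <- c(1, 3, 4, 7, 9)
  tr <- linearTrend(x, 2 * x + 1)
  expect_equal(tr$slope, 2)
  expect_equal(tr$intercept, 1)
  withr::with_seed(67, {
    a <- stats::rnorm(50); b <- 0.3 * a + stats::rnorm(50)
  })
  tr2 <- linearTrend(a, b)
  expect_equal(tr2$slope,
               pearsonCorr(a, b)$r * stats::sd(b) / stats::sd(a),
               tolerance = 1e-12)
  expect_error(linearTrend(rep(1, 5), 1:5), "zero variance")
})

test_that("age-group summaries match hand computation and report empty bins", {
  cohort <- data.frame(age = c(25, 30, 45, 65, 70, 80),
                       total_area_mm2 = c(1, 3, 5, 7, 9, 11))
  s <- ageGroupSummary(cohort, metrics = "total_area_mm2")
  expect_equal(s$n, c(2L, 1L, 3L))
  expect_equal(s$mean, c(2, 5, 9))
  expect_equal(s$sd, c(stats::sd(c(1, 3)), NA, 2))

  lone <- data.frame(age = rep(65, 4), total_area_mm2 = 1:4)
  s2 <- ageGroupSummary(lone, metrics = "total_area_mm2")
  expect_equal(s2$n, c(0L, 0L, 4L))
  expect_true(all(is.na(s2$mean[1:2])))
})

test_that("age-group means of total area rise in a mega-cohort", {
  co <- simulateCohort(cohortParams(n_subjects = 30000L), seed = 2)
  s <- ageGroupSummary(co, metrics = "total_area_mm2")
  expect_true(all(diff(s$mean) > 0))
})

test_that("the statistical battery reproduces the generative sign pattern", {
  # averaged over replicate cohorts: age drives total area and size,
  # not count or VDI; VDI tracks SFCT; axial length is null throughout
  withr::with_seed(68, {
    rs <- vapply(1:150, function(i) {
      co <- simulateCohort(cohortParams())
      c(ta_age = cor(co$age, co$total_area_mm2),
        size_age = cor(co$age, co$mean_size_um2),
        count_age = cor(co$age, co$void_count),
        vdi_age = cor(co$age, co$vdi),
        vdi_sfct = cor(co$sfct_um, co$vdi),
        ta_axl = cor(co$axial_length_mm, co$total_area_mm2))
    }, numeric(6))
  })
  m <- rowMeans(rs)
  expect_gt(m["ta_age"], 0.2)
  expect_gt(m["size_age"], 0.15)
  expect_gt(m["vdi_sfct"], 0.25)
  expect_lt(abs(m["count_age"]), 0.05)
  expect_lt(abs(m["vdi_age"]), 0.05)
  expect_lt(abs(m["ta_axl"]), 0.05)
  # and on one large cohort the true effects are significant
  big <- simulateCohort(cohortParams(n_subjects = 3000L), seed = 4)
  st <- cohortStats(big)
  expect_lt(st$correlations$total_area_mm2$age$p_value, 0.001)
  expect_lt(st$correlations$mean_size_um2$age$p_value, 0.001)
  expect_lt(st$correlations$vdi$sfct$p_value, 0.001)
})

test_that("the full report assembles and serializes", {
  co <- simulateCohort(cohortParams(), seed = 6)
  st <- cohortStats(co)
  expect_s3_class(st, "cohort_stats_report")
  expect_equal(st$n, 81)
  expect_named(st$trends, c("total_area_mm2", "mean_size_um2", "void_count", "vdi"))
  path <- withr::local_tempfile(fileext = ".json")
  writeStatsReport(st, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n, 81)
  expect_error(cohortStats(rbind(co, co[1, ])), "duplicate")
})
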