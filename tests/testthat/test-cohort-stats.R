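test_that("response transforms match their closed forms and floor zeros", {
  expect_equal(transform_response(0.9, "circularity"), log(0.1),
               tolerance = 1e-12)
  expect_equal(transform_response(1, "csm"), 0)
  expect_equal(transform_response(c(2, 5), "area_mm2"), c(2, 5))
  # zeros floored at half the smallest positive value
  tr <- transform_response(c(0, 0.01, 0.04), "csm")
  expect_equal(tr[1], log(0.005), ignore_attr = TRUE)
  expect_equal(attr(tr, "n_floored"), 1)
  # circularity of exactly 1 (perfect circle) floored the same way on 1 - x
  tr2 <- transform_response(c(1, 0.9, 0.8), "circularity")
  expect_equal(tr2[1], log(0.05), ignore_attr = TRUE)
  expect_true(all(is.finite(tr2)))
})

test_that("AICc matches hand arithmetic and limits to AIC", {
  expect_equal(aicc(-50, 2, 100), 104 + 12 / 97, tolerance = 1e-12)
  withr::with_seed(5, {
    for (i in 1:50) {
      ll <- stats::runif(1, -500, -10)
      k <- sample(1:10, 1)
      n <- k + 1 + sample(5:500, 1)
      expect_equal(aicc(ll, k, n),
                   -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1),
                   tolerance = 1e-9)
    }
  })
  expect_equal(aicc(-50, 3, 1e9), -2 * -50 + 6, tolerance = 1e-6)
  expect_error(aicc(-50, 10, 11), "undefined")
})

test_that("Akaike weights normalize and are shift-invariant", {
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-9)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  x <- c(103.2, 101.7, 110.4, 99.9)
  expect_equal(sum(akaike_weights(x)), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(x), akaike_weights(x + 57.3), tolerance = 1e-12)
})

test_that("strong parent random slopes are detected by stage one", {
  resp <- list(y = list(beta = c(5, 0.3, 0, 0), shelf = rep(0, 4),
                        re_sd = c(1, 0.25), re_cor = 0, resid_sd = 0.8,
                        scale = "identity"))
  hits <- vapply(1:10, function(s) {
    coh <- simulate_cohort(responses = resp, excl_beta = c(-20, 0), seed = s)
    d <- tibble::tibble(y = coh$y, P = coh$parental_age_days,
                        S = factor(coh$shelf), parent_id = coh$parent_id)
    suppressWarnings(select_random_structure(d))$structure
  }, character(1))
  expect_true(all(hits == "slope"))
})

test_that("zero random variance does not elect the random-slope structure", {
  resp <- list(y = list(beta = c(5, 0.3, 0, 0), shelf = rep(0, 4),
                        re_sd = c(0, 0), re_cor = 0, resid_sd = 1,
                        scale = "identity"))
  hits <- vapply(1:10, function(s) {
    coh <- simulate_cohort(responses = resp, excl_beta = c(-20, 0), seed = 50 + s)
    d <- tibble::tibble(y = coh$y, P = coh$parental_age_days,
                        S = factor(coh$shelf), parent_id = coh$parent_id)
    suppressWarnings(select_random_structure(d))$structure
  }, character(1))
  expect_lte(mean(hits == "slope"), 0.2)
})

test_that("stage-one selection is deterministic", {
  coh <- simulate_cohort(seed = 3)
  d <- tibble::tibble(y = coh$area_mm2, P = coh$parental_age_days,
                      S = factor(coh$shelf), parent_id = coh$parent_id)
  d <- d[!is.na(d$y), ]
  a <- suppressWarnings(select_random_structure(d))
  b <- suppressWarnings(select_random_structure(d))
  expect_identical(a$structure, b$structure)
  expect_equal(a$table$AICc, b$table$AICc, tolerance = 1e-12)
})

test_that("the fixed-effects dredge returns a coherent, sorted model table", {
  coh <- simulate_cohort(seed = 4)
  d <- tibble::tibble(y = coh$area_mm2, P = coh$parental_age_days,
                      S = factor(coh$shelf), parent_id = coh$parent_id)
  d <- d[!is.na(d$y), ]
  mt <- dredge_fixed(d, random = "slope")
  expect_equal(nrow(mt), 8)
  expect_true(all(diff(mt$AICc) >= 0))
  expect_equal(mt$dAICc[1], 0)
  expect_equal(sum(mt$weight), 1, tolerance = 1e-9)
  expect_true(all(mt$indistinguishable == (mt$dAICc < 2)))
  # df bookkeeping: cubic fixed (4) + random int/slope (3) + residual (1) = 8
  expect_equal(mt$df[mt$model == "P^3"], 8)
  expect_equal(mt$df[mt$model == "P^3 + S"], 11)
  expect_equal(mt$df[mt$model == "(intercept-only)"], 5)
  # generated with a dominant cubic: degree 3 ranked first
  expect_equal(mt$degree[1], 3)
  expect_s3_class(attr(mt, "best_fit"), "lme")
})

test_that("exclusion model recovers a positive age-damage slope", {
  coh <- simulate_cohort(seed = 9)
  ex <- fit_exclusion(coh)
  expect_gt(ex$slope, 0)
  expect_gt(ex$z_slope, 2)
  expect_equal(nrow(ex$table), 3)
  # logistic prediction monotone in age for a positive slope
  expect_true(all(diff(ex$curve$predicted) > 0))
  expect_true(all(ex$curve$lower <= ex$curve$predicted + 1e-12))
  expect_true(all(ex$curve$predicted <= ex$curve$upper + 1e-12))
  expect_true(all(ex$curve$lower >= 0 & ex$curve$upper <= 1))
})

test_that("prediction bands behave like fixed-effect confidence bands", {
  # model without shelf: shelf averaging is the identity
  coh <- simulate_cohort(seed = 13)
  d <- tibble::tibble(y = coh$area_mm2, P = coh$parental_age_days,
                      S = factor(coh$shelf), parent_id = coh$parent_id)
  d <- d[!is.na(d$y), ]
  fit <- nlme::gls(y ~ P, data = d)
  grid <- seq(min(d$P), max(d$P), length.out = 20)
  pb <- predict_with_bands(fit, grid, d)
  direct <- stats::coef(fit)[1] + stats::coef(fit)[2] * grid
  expect_equal(pb$predicted, unname(direct), tolerance = 1e-10)
  expect_true(all(pb$lower <= pb$predicted & pb$predicted <= pb$upper))

  # noise-free data: bands collapse onto the prediction
  resp0 <- list(y = list(beta = c(2, 0.1, 0, 0), shelf = rep(0, 4),
                         re_sd = c(0, 0), re_cor = 0, resid_sd = 0,
                         scale = "identity"))
  coh0 <- simulate_cohort(responses = resp0, excl_beta = c(-20, 0), seed = 2)
  d0 <- tibble::tibble(y = coh0$y, P = coh0$parental_age_days,
                       S = factor(coh0$shelf), parent_id = coh0$parent_id)
  fit0 <- stats::lm(y ~ P, data = d0)
  # zero-residual fit: vcov warns about the perfect fit, bands must collapse
  pb0 <- suppressWarnings(predict_with_bands(fit0, grid, d0))
  expect_lt(max(pb0$upper - pb0$lower), 1e-6)

  # band half-width shrinks roughly like 1/sqrt(n) when n grows 4x
  resp1 <- list(y = list(beta = c(2, 0.1, 0, 0), shelf = rep(0, 4),
                         re_sd = c(0, 0), re_cor = 0, resid_sd = 1,
                         scale = "identity"))
  width_at <- function(n_off, seed) {
    coh <- simulate_cohort(n_parents = 30, n_offspring = n_off,
                           responses = resp1, excl_beta = c(-20, 0),
                           seed = seed)
    d <- tibble::tibble(y = coh$y, P = coh$parental_age_days,
                        S = factor(coh$shelf), parent_id = coh$parent_id)
    f <- nlme::gls(y ~ P, data = d)
    pb <- predict_with_bands(f, grid, d)
    mean(pb$upper - pb$lower)
  }
  w1 <- mean(vapply(1:5, function(s) width_at(200, s), numeric(1)))
  w4 <- mean(vapply(1:5, function(s) width_at(800, s), numeric(1)))
  expect_equal(w1 / w4, 2, tolerance = 0.25)

  # extrapolation beyond the observed ages warns
  expect_warning(predict_with_bands(fit, c(0, grid), d), "extrapolat")
})

test_that("shelf-averaged predictions average the design across shelves", {
  resp <- list(y = list(beta = c(2, 0.1, 0, 0), shelf = c(0, 1, 2, 3),
                        re_sd = c(0, 0), re_cor = 0, resid_sd = 0.3,
                        scale = "identity"))
  coh <- simulate_cohort(responses = resp, excl_beta = c(-20, 0), seed = 31)
  d <- tibble::tibble(y = coh$y, P = coh$parental_age_days,
                      S = factor(coh$shelf), parent_id = coh$parent_id)
  fit <- nlme::gls(y ~ P + S, data = d)
  grid <- c(5, 15, 25)
  pb <- predict_with_bands(fit, grid, d)
  # manual average over the four shelf-specific predictions
  cf <- stats::coef(fit)
  manual <- cf["(Intercept)"] + cf["P"] * grid +
    mean(c(0, cf["S2"], cf["S3"], cf["S4"]))
  expect_equal(pb$predicted, unname(manual), tolerance = 1e-9)
})

test_that("residual diagnostics summarize and write the three displays", {
  resp <- list(y = list(beta = c(6, 0.3, -0.03, 0.0005), shelf = rep(0, 4),
                        re_sd = c(0, 0), re_cor = 0, resid_sd = 1,
                        scale = "identity"))
  coh <- simulate_cohort(n_offspring = 310, responses = resp,
                         excl_beta = c(-20, 0), seed = 17)
  d <- tibble::tibble(y = coh$y, P = coh$parental_age_days,
                      S = factor(coh$shelf), parent_id = coh$parent_id)
  fit <- nlme::gls(y ~ P + I(P^2) + I(P^3), data = d)
  dir <- withr::local_tempdir()
  dg <- residual_diagnostics(fit, dir = dir, prefix = "area")
  expect_named(dg$plots, c("histogram", "qq", "resid_vs_fitted"))
  expect_true(all(file.exists(dg$files)))
  expect_true(all(file.size(dg$files) > 0))
  # gaussian residuals at n ~ 300: skewness near zero
  expect_lt(abs(dg$skewness), 0.3)
})

test_that("log transform reduces the right skew of synthetic CSM draws", {
  x <- withr::with_seed(8, exp(stats::rnorm(310, -4, 0.6)))
  expect_gt(e1071::skewness(x), 0.5)
  expect_lt(abs(e1071::skewness(transform_response(x, "csm"))),
            abs(e1071::skewness(x)))
})

test_that("analyze_cohort ties the stages together and exposes broom methods", {
  coh <- simulate_cohort(seed = 23)
  fit <- suppressWarnings(analyze_cohort(coh, responses = c("area_mm2", "circularity")))
  g <- glance(fit)
  expect_equal(nrow(g), 2)
  expect_true(all(g$response == c("area_mm2", "circularity")))
  expect_identical(g$transform, c("identity", "log1m"))
  td <- tidy(fit)
  expect_equal(nrow(td), 16)
  expect_true(all(c("response", "model", "AICc", "weight") %in% names(td)))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_error(analyze_cohort(coh, responses = "not_a_column"), "not_a_column")
  # rerun is identical (full determinism of the analysis stage)
  fit2 <- suppressWarnings(analyze_cohort(coh, responses = c("area_mm2", "circularity")))
  expect_equal(tidy(fit), tidy(fit2), tolerance = 1e-12)
})
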