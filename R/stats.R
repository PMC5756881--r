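#' Response transforms used in the cohort analysis
#'
#' The symmetry measures (CSM and CSM_forced) are right-skewed and analyzed on
#' the `ln(x)` scale; circularity is left-skewed and analyzed as `ln(1 - x)`
#' (so that low transformed values mean broadly circular fronds); area and
#' perimeter are analyzed untransformed.
#'
#' Exact zeros (possible for perfectly symmetric synthetic fronds, never seen
#' in real data) would map to `-Inf`; they are floored at half the smallest
#' positive observed value, with attribute `"n_floored"` reporting how many
#' values were floored.
#'
#' @param x Numeric vector of measurements.
#' @param response Response name; anything containing `"csm"` is `ln(x)`
#'   transformed, anything containing `"circ"` is `ln(1 - x)` transformed,
#'   everything else is returned unchanged.
#' @return Transformed numeric vector (possibly with attribute `"n_floored"`).
#' @export
transform_response <- function(x, response) {
  kind <- response_transform_name(response)
  floor_log <- function(v) {
    zero <- !is.na(v) & v <= 0
    if (any(zero)) {
      pos <- v[!is.na(v) & v > 0]
      if (!length(pos)) stop("no positive values to anchor the zero floor")
      v[zero] <- min(pos) / 2
    }
    out <- log(v)
    if (any(zero)) attr(out, "n_floored") <- sum(zero)
    out
  }
  switch(kind,
    identity = x,
    log = floor_log(x),
    log1m = floor_log(1 - x))
}

response_transform_name <- function(response) {
  if (grepl("csm", response, ignore.case = TRUE)) return("log")
  if (grepl("circ", response, ignore.case = TRUE)) return("log1m")
  "identity"
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik Log-likelihood of the fitted model.
#' @param k Number of estimated parameters (fixed coefficients plus variance
#'   parameters plus the residual variance).
#' @param n Number of observations.
#' @return The AICc value.
#' @examples
#' aicc(-50, 2, 100)  # 104 + 12/97
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) stop("AICc undefined for n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from a set of AICc values
#'
#' `exp(-dAICc / 2)` normalized to sum to one; invariant to adding a constant
#' to every AICc value.
#'
#' @param x Numeric vector of AICc values (`NA` allowed for failed fits,
#'   which get weight `NA`).
#' @return Numeric vector of weights summing to 1 over the non-`NA` entries.
#' @export
akaike_weights <- function(x) {
  d <- x - min(x, na.rm = TRUE)
  w <- exp(-d / 2)
  w / sum(w, na.rm = TRUE)
}

## -- candidate fitting -------------------------------------------------------

fixed_formula <- function(degree, shelf) {
  rhs <- if (degree == 0) "1" else
    paste(c("P", "I(P^2)", "I(P^3)")[seq_len(degree)], collapse = " + ")
  if (shelf) rhs <- if (degree == 0) "S" else paste(rhs, "+ S")
  stats::as.formula(paste("y ~", rhs))
}

model_label <- function(degree, shelf) {
  base <- switch(degree + 1L, "(intercept-only)", "P", "P^2", "P^3")
  if (!shelf) return(base)
  if (degree == 0) "S" else paste(base, "+ S")
}

# Fit one gaussian candidate; returns NULL (with a message) when the fit fails.
fit_lmm_candidate <- function(data, degree, shelf, random, method) {
  f <- fixed_formula(degree, shelf)
  env <- new.env(parent = environment())
  env$data <- data
  environment(f) <- env
  tryCatch(
    switch(random,
      none = nlme::gls(f, data = data, method = method),
      intercept = nlme::lme(f, random = ~ 1 | parent_id, data = data,
                            method = method),
      slope = nlme::lme(f, random = ~ 1 + P | parent_id, data = data,
                        method = method,
                        control = nlme::lmeControl(opt = "optim",
                                                   maxIter = 200,
                                                   msMaxIter = 200,
                                                   returnObject = FALSE)),
      stop("unknown random structure: ", random)
    ),
    error = function(e) NULL)
}

#' Choose the random-effects structure for one response
#'
#' Stage one of the two-stage selection. Nine candidates are fitted with
#' restricted maximum likelihood: the three random-effects structures (parent
#' random intercept and slope; parent random intercept; no random effects)
#' crossed with the linear, quadratic and cubic polynomials of parental age.
#' The structure minimizing AICc is chosen. When the winning structure
#' differs across polynomials, the winner under the best-supported polynomial
#' (the one whose own minimum AICc is lowest) is taken, tie-broken by the
#' larger best-versus-second-best AICc margin. Non-convergent candidates are
#' dropped with a warning.
#'
#' @param data Data frame with columns `y` (transformed response), `P`
#'   (parental age, days), `S` (shelf factor) and `parent_id`.
#' @return List with `structure` (`"slope"`, `"intercept"` or `"none"`) and
#'   `table` (tibble of the nine REML candidates: degree, random, df, logLik,
#'   AICc).
#' @export
select_random_structure <- function(data) {
  stopifnot(all(c("y", "P", "parent_id") %in% names(data)))
  n <- nrow(data)
  grid <- expand.grid(degree = 1:3,
                      random = c("slope", "intercept", "none"),
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(degree, random) {
    fit <- fit_lmm_candidate(data, degree, shelf = FALSE, random = random,
                             method = "REML")
    if (is.null(fit)) {
      warning(sprintf("REML candidate (degree %d, %s) failed to converge; dropped",
                      degree, random), call. = FALSE)
      return(tibble::tibble(degree = degree, random = random,
                            df = NA_real_, logLik = NA_real_, AICc = NA_real_))
    }
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    tibble::tibble(degree = degree, random = random, df = k,
                   logLik = as.numeric(ll), AICc = aicc(as.numeric(ll), k, n))
  })
  tab <- dplyr::bind_rows(rows)
  per_degree <- tab |>
    dplyr::filter(!is.na(.data$AICc)) |>
    dplyr::group_by(.data$degree) |>
    dplyr::arrange(.data$AICc, .by_group = TRUE) |>
    dplyr::summarise(
      winner = dplyr::first(.data$random),
      best = dplyr::first(.data$AICc),
      margin = dplyr::nth(.data$AICc, 2, default = Inf) - dplyr::first(.data$AICc))
  winners <- unique(per_degree$winner)
  if (length(winners) == 1L) {
    structure_ <- winners
  } else {
    best_deg <- per_degree |>
      dplyr::arrange(.data$best, dplyr::desc(.data$margin))
    structure_ <- best_deg$winner[1]
  }
  list(structure = structure_, table = tab)
}

#' Dredge the fixed-effects candidates for one response
#'
#' Stage two of the two-stage selection. With the random-effects structure
#' held fixed, all eight fixed-effects models (parental-age polynomials of
#' degree 0-3, crossed with presence/absence of the shelf factor) are fitted
#' with maximum likelihood and ranked by AICc. Alternatives within 2 AICc of
#' the best fit approximately as well and are flagged. The winner is refitted
#' with restricted maximum likelihood for reporting and prediction.
#'
#' @inheritParams select_random_structure
#' @param random Random-effects structure from [select_random_structure()].
#' @return A `frond_model_table`: tibble with columns `model`, `degree`,
#'   `shelf`, `df`, `logLik`, `AICc`, `dAICc`, `weight`,
#'   `indistinguishable` (`dAICc < 2`), sorted by AICc, with the REML-refitted
#'   best model in attribute `"best_fit"` and `random` in attribute
#'   `"random"`.
#' @export
dredge_fixed <- function(data, random = "none") {
  stopifnot(all(c("y", "P", "parent_id") %in% names(data)))
  n <- nrow(data)
  grid <- expand.grid(degree = 0:3, shelf = c(FALSE, TRUE))
  rows <- purrr::pmap(grid, function(degree, shelf) {
    fit <- fit_lmm_candidate(data, degree, shelf, random, method = "ML")
    if (is.null(fit)) {
      return(tibble::tibble(model = model_label(degree, shelf),
                            degree = degree, shelf = shelf,
                            df = NA_real_, logLik = NA_real_, AICc = NA_real_))
    }
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    tibble::tibble(model = model_label(degree, shelf), degree = degree,
                   shelf = shelf, df = k, logLik = as.numeric(ll),
                   AICc = aicc(as.numeric(ll), k, n))
  })
  tab <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$AICc) |>
    dplyr::mutate(
      dAICc = .data$AICc - min(.data$AICc, na.rm = TRUE),
      weight = akaike_weights(.data$AICc),
      indistinguishable = .data$dAICc < 2)
  best_fit <- fit_lmm_candidate(data, tab$degree[1], tab$shelf[1], random,
                                method = "REML")
  structure(tab,
            class = c("frond_model_table", class(tab)),
            best_fit = best_fit, random = random, n = n)
}

#' @export
print.frond_model_table <- function(x, ...) {
  cat(sprintf("Fixed-effects model table (random structure: %s)\n",
              attr(x, "random")))
  NextMethod()
}

## -- exclusion analysis ------------------------------------------------------

#' Model the probability of frond exclusion as a function of parental age
#'
#' Fits binomial (logistic) models of the exclusion flag on parental age under
#' the three random-effects structures (parent random intercept and slope;
#' parent random intercept; none), selects the one minimizing AICc, and
#' returns the model table together with the selected model's slope Wald
#' statistic and a prediction curve with 95% confidence bands on the
#' probability scale.
#'
#' @param data Data frame with columns `excluded` (logical or 0/1),
#'   `parental_age_days` and `parent_id`.
#' @param age_grid Ages at which to predict (default: 100 points spanning the
#'   observed range).
#' @return An `exclusion_fit`: list with `table` (candidate comparison),
#'   `fit` (selected model), `z_slope` (Wald z of the age slope), `p_slope`,
#'   `curve` (tibble `age`, `predicted`, `lower`, `upper`) and `separation`
#'   flag.
#' @export
fit_exclusion <- function(data, age_grid = NULL) {
  stopifnot(all(c("excluded", "parental_age_days", "parent_id") %in% names(data)))
  d <- tibble::tibble(
    excluded = as.integer(data$excluded),
    P = as.numeric(data$parental_age_days),
    parent_id = data$parent_id)
  n <- nrow(d)
  separation <- FALSE
  fits <- list(
    `intercept+slope` = tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(excluded ~ P + (1 + P | parent_id), data = d,
                    family = stats::binomial))),
      error = function(e) NULL),
    intercept = tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(excluded ~ P + (1 | parent_id), data = d,
                    family = stats::binomial))),
      error = function(e) NULL),
    none = withCallingHandlers(
      stats::glm(excluded ~ P, data = d, family = stats::binomial),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separation <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
  )
  tab <- purrr::imap(fits, function(fit, nm) {
    if (is.null(fit)) {
      return(tibble::tibble(random = nm, df = NA_real_, logLik = NA_real_,
                            AICc = NA_real_))
    }
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    tibble::tibble(random = nm, df = k, logLik = as.numeric(ll),
                   AICc = aicc(as.numeric(ll), k, n))
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$AICc) |>
    dplyr::mutate(dAICc = .data$AICc - min(.data$AICc, na.rm = TRUE),
                  weight = akaike_weights(.data$AICc))
  best_name <- tab$random[1]
  fit <- fits[[best_name]]
  cf <- if (inherits(fit, "merMod")) {
    stats::coef(summary(fit))
  } else {
    stats::coef(summary(fit))
  }
  z <- cf["P", if (inherits(fit, "merMod")) "z value" else "z value"]
  p <- cf["P", grep("^Pr", colnames(cf), value = TRUE)]
  if (is.null(age_grid)) {
    age_grid <- seq(min(d$P), max(d$P), length.out = 100)
  }
  curve <- predict_with_bands(fit, age_grid, d)
  structure(
    list(table = tab, fit = fit, random = best_name,
         z_slope = unname(z), p_slope = unname(p),
         slope = unname(cf["P", "Estimate"]),
         slope_se = unname(cf["P", "Std. Error"]),
         curve = curve, separation = separation),
    class = "exclusion_fit")
}

#' @export
print.exclusion_fit <- function(x, ...) {
  cat("Exclusion (damage) analysis: logistic model of exclusion on parental age\n")
  cat(sprintf("  selected random structure: %s\n", x$random))
  cat(sprintf("  age slope: %.4f (SE %.4f), z = %.3f, p = %.3g\n",
              x$slope, x$slope_se, x$z_slope, x$p_slope))
  if (x$separation) cat("  WARNING: complete or quasi-complete separation detected\n")
  invisible(x)
}

## -- prediction curves -------------------------------------------------------

#' Population-level predictions with 95% confidence bands
#'
#' Predicts the response over a parental-age grid from a fitted candidate
#' model, with random effects at zero (population level) and normal-
#' approximation confidence bands from the fixed-effects covariance matrix.
#' When the model contains the shelf factor, the design rows are averaged
#' across shelf levels, so the curve is the prediction averaged over shelves.
#' For binomial models the bands are computed on the link scale and
#' back-transformed, so `lower <= predicted <= upper` always holds.
#'
#' @param fit A model from [dredge_fixed()] (`"best_fit"` attribute),
#'   [select_random_structure()] candidates, or [fit_exclusion()]: `gls`,
#'   `lme`, `glm` or `merMod`.
#' @param age_grid Numeric vector of parental ages (days).
#' @param data The data the model was fitted to (used for shelf levels and
#'   the observed age range).
#' @param level Confidence level (default 0.95).
#' @return Tibble with `age`, `predicted`, `lower`, `upper`.
#' @export
predict_with_bands <- function(fit, age_grid, data, level = 0.95) {
  if (min(age_grid) < min(data$P) - 1e-9 || max(age_grid) > max(data$P) + 1e-9) {
    warning("age_grid extends beyond the observed parental-age range; extrapolating")
  }
  f <- stats::formula(fit)
  if (inherits(fit, "merMod")) f <- lme4::nobars(f)
  tt <- stats::delete.response(stats::terms(f))
  has_shelf <- "S" %in% all.vars(tt)
  if (has_shelf) {
    lev <- levels(data$S)
    nd <- expand.grid(P = age_grid, S = factor(lev, levels = lev))
  } else {
    nd <- data.frame(P = age_grid)
  }
  X <- stats::model.matrix(tt, nd)
  if (has_shelf) {
    # average the design rows across shelf levels for each grid age
    X <- rowsum(X, group = rep(seq_along(age_grid), times = length(lev))) /
      length(lev)
  }
  beta <- if (inherits(fit, "merMod")) lme4::fixef(fit)
    else if (inherits(fit, "lme")) nlme::fixef(fit)
    else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  eta <- unname(drop(X %*% beta))
  se <- unname(sqrt(pmax(rowSums((X %*% V) * X), 0)))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  lower <- eta - zq * se
  upper <- eta + zq * se
  binom <- (inherits(fit, "glm") && stats::family(fit)$family == "binomial") ||
    (inherits(fit, "glmerMod"))
  if (binom) {
    eta <- stats::plogis(eta); lower <- stats::plogis(lower)
    upper <- stats::plogis(upper)
  }
  tibble::tibble(age = age_grid, predicted = eta, lower = lower, upper = upper)
}

## -- diagnostics -------------------------------------------------------------

#' Residual diagnostics for a fitted candidate model
#'
#' Builds the three standard residual displays (histogram, normal
#' quantile-quantile plot, residuals versus fitted values) and summarizes
#' residual skewness and kurtosis. If `dir` is given the plots are written as
#' PNG files.
#'
#' @param fit A fitted `gls`, `lme` or `lm`-like model.
#' @param dir Output directory for PNG files (optional).
#' @param prefix File-name prefix.
#' @return List with `skewness`, `kurtosis`, `plots` (named list of ggplot
#'   objects) and `files` (paths written, or `NULL`).
#' @export
residual_diagnostics <- function(fit, dir = NULL, prefix = "model") {
  r <- as.numeric(stats::residuals(fit))
  fv <- as.numeric(stats::fitted(fit))
  d <- tibble::tibble(resid = r, fitted = fv)
  p_hist <- ggplot2::ggplot(d, ggplot2::aes(x = .data$resid)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::labs(x = "residual", y = "count") + ggplot2::theme_minimal()
  p_qq <- ggplot2::ggplot(d, ggplot2::aes(sample = .data$resid)) +
    ggplot2::stat_qq(size = 0.7) + ggplot2::stat_qq_line() +
    ggplot2::labs(x = "theoretical quantile", y = "residual quantile") +
    ggplot2::theme_minimal()
  p_fit <- ggplot2::ggplot(d, ggplot2::aes(x = .data$fitted, y = .data$resid)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "fitted value", y = "residual") + ggplot2::theme_minimal()
  plots <- list(histogram = p_hist, qq = p_qq, resid_vs_fitted = p_fit)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(dir, paste0(prefix, "_", names(plots), ".png"))
    for (i in seq_along(plots)) {
      suppressMessages(ggplot2::ggsave(files[i], plots[[i]], width = 4,
                                       height = 3.2, dpi = 120))
    }
  }
  list(skewness = e1071::skewness(r), kurtosis = e1071::kurtosis(r),
       plots = plots, files = files)
}
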