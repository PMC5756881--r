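#' Run the full parental-age analysis on a cohort table
#'
#' For each response, applies the appropriate transform (see
#' [transform_response()]), chooses the random-effects structure by REML/AICc
#' ([select_random_structure()]), dredges the eight fixed-effects candidates
#' by ML/AICc ([dredge_fixed()]), refits the winner with REML, and computes a
#' population-level prediction curve averaged across shelves
#' ([predict_with_bands()]). Excluded fronds are dropped from the response
#' models but analyzed separately with the binomial exclusion model
#' ([fit_exclusion()]).
#'
#' @param data Cohort tibble (see [simulate_cohort()] for the schema:
#'   `parent_id`, `parental_age_days`, `shelf`, `excluded`, plus measurement
#'   columns).
#' @param responses Character vector of measurement columns to analyze.
#' @param age_grid Parental-age grid for prediction curves (default: 100
#'   points spanning the observed range).
#' @param exclusion Run the exclusion analysis too? (Needs an `excluded`
#'   column.)
#' @return A `cohort_analysis` object; see [tidy.cohort_analysis()],
#'   [glance.cohort_analysis()] and [autoplot.cohort_analysis()].
#' @examples
#' \donttest{
#' coh <- simulate_cohort(seed = 1)
#' fit <- analyze_cohort(coh, responses = c("area_mm2", "csm"))
#' glance(fit)
#' }
#' @export
analyze_cohort <- function(data,
                           responses = c("area_mm2", "perimeter_mm",
                                         "circularity", "csm", "csm_forced"),
                           age_grid = NULL, exclusion = TRUE) {
  need <- c("parent_id", "parental_age_days", "shelf")
  missing_cols <- setdiff(c(need, responses), names(data))
  if (length(missing_cols)) {
    stop("cohort data is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(age_grid)) {
    age_grid <- seq(min(data$parental_age_days), max(data$parental_age_days),
                    length.out = 100)
  }
  res <- purrr::map(rlang::set_names(responses), function(resp) {
    d <- tibble::tibble(
      y = transform_response(data[[resp]], resp),
      P = as.numeric(data$parental_age_days),
      S = factor(data$shelf),
      parent_id = data$parent_id)
    d <- d[stats::complete.cases(d$y, d$P), ]
    rs <- select_random_structure(d)
    mt <- dredge_fixed(d, random = rs$structure)
    curve <- predict_with_bands(attr(mt, "best_fit"), age_grid, d)
    list(response = resp, transform = response_transform_name(resp),
         random_structure = rs$structure, random_table = rs$table,
         model_table = mt, best_fit = attr(mt, "best_fit"), curve = curve,
         n = nrow(d))
  })
  excl <- NULL
  if (exclusion && "excluded" %in% names(data)) {
    excl <- fit_exclusion(data, age_grid = age_grid)
  }
  structure(list(responses = res, exclusion = excl, age_grid = age_grid,
                 data = data),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n")
  g <- glance(x)
  print(g)
  if (!is.null(x$exclusion)) {
    cat("\n")
    print(x$exclusion)
  }
  invisible(x)
}

#' Tidy the model tables of a cohort analysis
#'
#' Binds the per-response fixed-effects model tables into one tibble, one row
#' per candidate model.
#'
#' @param x A `cohort_analysis`.
#' @param ... Unused.
#' @return Tibble with `response`, `model`, `df`, `logLik`, `AICc`, `dAICc`,
#'   `weight`, `indistinguishable`.
#' @export
tidy.cohort_analysis <- function(x, ...) {
  purrr::map_dfr(x$responses, function(r) {
    dplyr::mutate(tibble::as_tibble(r$model_table),
                  response = r$response, .before = 1)
  })
}

#' One-row-per-response summary of a cohort analysis
#'
#' @inheritParams tidy.cohort_analysis
#' @return Tibble with the selected random structure, best fixed-effects
#'   model, its df, AICc and Akaike weight, and the sample size used.
#' @export
glance.cohort_analysis <- function(x, ...) {
  purrr::map_dfr(x$responses, function(r) {
    tibble::tibble(
      response = r$response,
      transform = r$transform,
      random_structure = r$random_structure,
      best_model = r$model_table$model[1],
      df = r$model_table$df[1],
      AICc = r$model_table$AICc[1],
      weight = r$model_table$weight[1],
      n = r$n)
  })
}

#' Prediction curves of a cohort analysis
#'
#' Plots the population-level prediction of each analyzed response (on its
#' analysis scale) against parental age, with 95% confidence bands, plus the
#' exclusion-probability curve when available.
#'
#' @param object A `cohort_analysis`.
#' @param ... Unused.
#' @return A ggplot object (facetted by response).
#' @export
autoplot.cohort_analysis <- function(object, ...) {
  curves <- purrr::map_dfr(object$responses, function(r) {
    lab <- switch(r$transform,
                  identity = r$response,
                  log = paste0("ln(", r$response, ")"),
                  log1m = paste0("ln(1 - ", r$response, ")"))
    dplyr::mutate(r$curve, response = lab)
  })
  if (!is.null(object$exclusion)) {
    curves <- dplyr::bind_rows(
      curves,
      dplyr::mutate(object$exclusion$curve, response = "P(excluded)"))
  }
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$age, y = .data$predicted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(x = "parental age at detachment (days)",
                  y = "predicted response") +
    ggplot2::theme_minimal()
}

#' @importFrom generics glance
#' @export
generics::glance

#' @export
generics::tidy

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
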