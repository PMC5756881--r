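#' Default response-generating parameters for synthetic cohorts
#'
#' Returns the per-response generating parameters used by
#' [simulate_cohort()]. Each element is a list with `beta` (intercept, linear,
#' quadratic, cubic coefficients of parental age in days), `shelf` (per-shelf
#' additive offsets), `re_sd` (parent random intercept and random slope SDs),
#' `re_cor` (their correlation), `resid_sd` (residual SD) and `scale` (the
#' scale on which the linear predictor acts: `"identity"` for the size
#' measures, `"log"` for the symmetry measures, `"log1m"`, i.e. the
#' `ln(1 - x)` scale, for circularity).
#'
#' Defaults emulate the study system qualitatively: offspring area and
#' perimeter rise over the parent's first week and then decline steeply
#' (a cubic with turning points near days 7 and 40), with parent-level random
#' intercepts and slopes; the three shape measures have no parent-level random
#' effects and at most weak parental-age trends.
#'
#' @param n_shelves Number of shelves.
#' @return Named list of per-response parameter lists.
#' @export
cohort_response_defaults <- function(n_shelves = 4L) {
  shelf0 <- rep(0, n_shelves)
  list(
    area_mm2 = list(
      beta = c(6, 0.336, -0.0282, 0.0004), shelf = shelf0,
      re_sd = c(0.5, 0.03), re_cor = 0, resid_sd = 0.9, scale = "identity"),
    perimeter_mm = list(
      beta = c(9.5, 0.35, -0.03, 0.00042),
      shelf = c(0, 0.15, -0.1, -0.2)[seq_len(n_shelves)],
      re_sd = c(0.6, 0.035), re_cor = 0, resid_sd = 1.1, scale = "identity"),
    circularity = list(
      beta = c(-2.0, 0.01, 0, 0),
      shelf = c(0, 0.05, -0.05, 0.08)[seq_len(n_shelves)],
      re_sd = c(0, 0), re_cor = 0, resid_sd = 0.25, scale = "log1m"),
    csm = list(
      beta = c(-4.0, 0, 0, 0), shelf = shelf0,
      re_sd = c(0, 0), re_cor = 0, resid_sd = 0.6, scale = "log"),
    csm_forced = list(
      beta = c(-3.7, 0, 0, 0), shelf = shelf0,
      re_sd = c(0, 0), re_cor = 0, resid_sd = 0.6, scale = "log")
  )
}

#' Simulate a synthetic offspring cohort
#'
#' Generates a cohort table with the statistical structure of the parental-age
#' study: `n_parents` parent plants, each contributing a strictly increasing
#' schedule of offspring detachment ages (integer days), offspring assigned
#' randomly to shelves, each response following
#' `b0 + b1*P + b2*P^2 + b3*P^3 + shelf offset + parent random intercept +
#' parent random slope * P + Gaussian residual` on its generating scale, and
#' an age-dependent damage/exclusion process
#' `excluded ~ Bernoulli(plogis(e0 + e1 * P))`. Excluded fronds keep their
#' metadata but carry `NA` measurements (damaged fronds cannot be measured).
#'
#' Defaults mirror the study's design: 30 parents, 403 offspring in total,
#' 4 shelves, detachment ages spanning days 1-30, and an exclusion process
#' rising with parental age to about 23% overall.
#'
#' @param n_parents Number of parent plants.
#' @param n_offspring Total number of offspring across parents (distributed as
#'   evenly as possible).
#' @param n_shelves Number of shelves.
#' @param age_range Integer range of possible detachment ages (days).
#' @param responses Per-response generating parameters
#'   ([cohort_response_defaults()] or any named subset of the same shape).
#' @param excl_beta Intercept and slope of the exclusion logistic on parental
#'   age.
#' @param seed RNG seed (locally scoped); the cohort is reproducible given
#'   the parameters and seed.
#' @return Tibble with columns `frond_id`, `parent_id`, `parental_age_days`,
#'   `shelf`, `excluded`, and one column per response; generating parameters
#'   attached as attribute `"params"`.
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' nrow(coh)            # 403
#' mean(coh$excluded)   # about 0.23
#' @export
simulate_cohort <- function(n_parents = 30L, n_offspring = 403L,
                            n_shelves = 4L, age_range = c(1L, 30L),
                            responses = cohort_response_defaults(n_shelves),
                            excl_beta = c(-2.9, 0.1), seed = NULL) {
  stopifnot(n_parents >= 1L, n_offspring >= n_parents, length(excl_beta) == 2L)
  ages_avail <- seq(age_range[1], age_range[2])
  base <- n_offspring %/% n_parents
  counts <- rep(base, n_parents) + (seq_len(n_parents) <= n_offspring %% n_parents)
  if (max(counts) > length(ages_avail)) {
    stop("more offspring per parent than distinct detachment ages available")
  }
  local_seed(seed, {
    parent_id <- rep(sprintf("parent_%02d", seq_len(n_parents)), counts)
    age <- unlist(lapply(counts, function(m) sort(sample(ages_avail, m))))
    n <- length(age)
    shelf <- sample(seq_len(n_shelves), n, replace = TRUE)
    out <- tibble::tibble(
      frond_id = sprintf("frond_%03d", seq_len(n)),
      parent_id = parent_id,
      parental_age_days = as.numeric(age),
      shelf = shelf)
    for (nm in names(responses)) {
      pr <- responses[[nm]]
      sd_i <- pr$re_sd[1]; sd_s <- pr$re_sd[2]
      rho <- if (is.null(pr$re_cor)) 0 else pr$re_cor
      b_i <- stats::rnorm(n_parents, 0, sd_i)
      b_s_raw <- stats::rnorm(n_parents, 0, 1)
      b_s <- if (sd_i > 0 && sd_s > 0) {
        sd_s * (rho * b_i / sd_i + sqrt(1 - rho^2) * b_s_raw)
      } else {
        sd_s * b_s_raw
      }
      pidx <- rep(seq_len(n_parents), counts)
      eta <- pr$beta[1] + pr$beta[2] * age + pr$beta[3] * age^2 +
        pr$beta[4] * age^3 + pr$shelf[shelf] +
        b_i[pidx] + b_s[pidx] * age +
        stats::rnorm(n, 0, pr$resid_sd)
      out[[nm]] <- switch(pr$scale,
        identity = eta,
        log = exp(eta),
        log1m = 1 - exp(pmin(eta, -1e-8)),
        stop("unknown generating scale: ", pr$scale))
    }
    p_excl <- stats::plogis(excl_beta[1] + excl_beta[2] * age)
    out$excluded <- stats::runif(n) < p_excl
    for (nm in names(responses)) out[[nm]][out$excluded] <- NA_real_
    out <- out[, c("frond_id", "parent_id", "parental_age_days", "shelf",
                   "excluded", names(responses))]
    attr(out, "params") <- list(
      n_parents = n_parents, n_offspring = n_offspring, n_shelves = n_shelves,
      age_range = age_range, responses = responses, excl_beta = excl_beta,
      seed = seed)
    out
  })
}
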