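#' Age bands used throughout the pipeline
#'
#' Thirteen ordered five-year bands from 30-34 to 90+, matching the
#' stratification of registry population tables for adult cancers.
#'
#' @return Character vector of band labels, in order.
#' @export
age_bands <- function() {
  c("30-34", "35-39", "40-44", "45-49", "50-54", "55-59", "60-64",
    "65-69", "70-74", "75-79", "80-84", "85-89", "90+")
}

#' Default adult age pyramid
#'
#' Share of the 30+ population in each five-year band. The shape is a
#' smoothly declining adult pyramid typical of a western European population;
#' it is a shipped constant, overridable wherever a pyramid is accepted.
#'
#' @return Named numeric vector over [age_bands()] summing to 1.
#' @export
default_age_pyramid <- function() {
  p <- c(0.105, 0.100, 0.100, 0.100, 0.095, 0.090, 0.085,
         0.080, 0.075, 0.060, 0.045, 0.035, 0.030)
  stats::setNames(p / sum(p), age_bands())
}

#' Generate a stratified population table
#'
#' Draws per-area population sizes around `mean_area_pop` (truncated
#' log-normal, so sizes stay within roughly 0.6-1.6 times the mean, matching
#' the bounded sizes of real DSAs) with small independent year-to-year
#' fluctuations, then splits each area-year total deterministically into
#' sex (1:1) and age strata according to `pyramid`. Every (area, sex, age
#' band, year) stratum is present.
#'
#' @param geo A [generate_geography()] object (or any object with
#'   `$areas$area_id`).
#' @param mean_area_pop Mean area population (persons aged 30+); must be
#'   positive.
#' @param n_years Number of calendar years (years are labelled
#'   `first_year, first_year + 1, ...`).
#' @param seed Integer seed.
#' @param first_year First calendar year label.
#' @param sdlog Dispersion of area sizes on the log scale (truncated at
#'   +/- 2.58 sd).
#' @param pyramid Age-band shares, defaults to [default_age_pyramid()].
#'
#' @return Tibble with columns `area_id`, `sex` (`"M"`/`"F"`), `age_group`,
#'   `year`, `person_years`.
#' @export
generate_population <- function(geo, mean_area_pop = 1600, n_years = 9,
                                seed = 1L, first_year = 2008,
                                sdlog = 0.18, pyramid = default_age_pyramid()) {
  if (!is.finite(mean_area_pop) || mean_area_pop <= 0) {
    stop("`mean_area_pop` must be positive.", call. = FALSE)
  }
  if (!is.finite(n_years) || n_years < 1) {
    stop("`n_years` must be at least 1.", call. = FALSE)
  }
  stopifnot(identical(sort(names(pyramid)), sort(age_bands())), all(pyramid >= 0))
  pyramid <- pyramid[age_bands()] / sum(pyramid)
  ids <- geo$areas$area_id
  n <- length(ids)
  years <- first_year + seq_len(n_years) - 1L

  withr_seed(seed, {
    z <- stats::rnorm(n, 0, sdlog)
    z <- pmin(pmax(z, -2.58 * sdlog), 2.58 * sdlog)
    area_tot <- mean_area_pop * exp(z) / exp(sdlog^2 / 2)
    yr_fac <- matrix(pmin(pmax(stats::rnorm(n * n_years, 1, 0.01), 0.97), 1.03),
                     nrow = n)
  })

  grid <- tidyr::expand_grid(
    area_id = ids,
    sex = c("M", "F"),
    age_group = age_bands(),
    year = years
  )
  ai <- match(grid$area_id, ids)
  yi <- match(grid$year, years)
  grid$person_years <- area_tot[ai] * yr_fac[cbind(ai, yi)] *
    0.5 * unname(pyramid[grid$age_group])
  grid$age_group <- factor(grid$age_group, levels = age_bands())
  grid
}

#' Default stage-specific baseline rate table
#'
#' Baseline incidence rates per person-year by sex, age band and stage. Stage
#' totals are calibrated so that, under [default_age_pyramid()], the crude
#' rates are approximately `stage_rates` per 100,000 person-years (defaults
#' 20, 5 and 2 for stages I, II and III-IV). Incidence rises with age
#' (log-linearly across bands, steeper for later stages, the qualitative
#' pattern seen in registry data) and is moderately higher in men.
#'
#' @param stage_rates Named crude target rates per 100,000 person-years.
#' @param age_slope Per-band log-linear age slope for each stage.
#' @param male_excess Multiplicative male/female rate ratio.
#' @param pyramid Age pyramid used for the crude-rate calibration.
#'
#' @return Tibble with columns `sex`, `age_group`, `stage`, `rate`
#'   (per person-year).
#' @export
baseline_rates <- function(stage_rates = c("I" = 20, "II" = 5, "III-IV" = 2),
                           age_slope = c("I" = 0.05, "II" = 0.12, "III-IV" = 0.10),
                           male_excess = 1.2,
                           pyramid = default_age_pyramid()) {
  stopifnot(identical(names(stage_rates), stage_levels()),
            all(stage_rates >= 0))
  bands <- age_bands()
  k <- seq_along(bands) - 1
  out <- tidyr::expand_grid(sex = c("M", "F"), age_group = bands,
                            stage = stage_levels())
  sexmul <- ifelse(out$sex == "M", male_excess, 1)
  agemul <- exp(age_slope[out$stage] * k[match(out$age_group, bands)])
  # normalise so the pyramid-weighted (sex-averaged) rate hits the target
  norm <- vapply(stage_levels(), function(s) {
    sum(pyramid[bands] * 0.5 * (male_excess + 1) * exp(age_slope[s] * k))
  }, numeric(1))
  out$rate <- (stage_rates[out$stage] / 1e5) * sexmul * agemul / norm[out$stage]
  out$age_group <- factor(out$age_group, levels = bands)
  out$stage <- factor(out$stage, levels = stage_levels())
  out
}

#' Stage labels
#' @return `c("I", "II", "III-IV")`.
#' @export
stage_levels <- function() c("I", "II", "III-IV")
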