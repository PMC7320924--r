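#' European Standard Population 2013 weights, adult bands
#'
#' The 2013 European Standard Population weights for the thirteen five-year
#' bands 30-34 through 90+ (the 90-94 and 95+ weights are merged),
#' renormalised to sum to 1.
#'
#' @return Named numeric vector over [age_bands()].
#' @export
esp2013_weights <- function() {
  w <- c(6500, 7000, 7000, 7000, 7000, 6500, 6000,
         5500, 5000, 4000, 2500, 1500, 1000)
  stats::setNames(w / sum(w), age_bands())
}

#' Directly age-standardised incidence rates
#'
#' Computes, per calendar year and stage, the directly standardised incidence
#' per 100,000 person-years: the standard-population-weighted average of
#' age-band-specific rates. Age-specific rates pool the sexes by default
#' (cases and person-years summed over sex before the rate is formed); set
#' `by_sex = TRUE` for sex-specific curves.
#'
#' @param cases Case table (`area_id`, `sex`, `age_group`, `year`, `stage`).
#' @param pop Population table (`area_id`, `sex`, `age_group`, `year`,
#'   `person_years`).
#' @param std Standard-population weights over [age_bands()]; rescaling all
#'   weights by a constant does not change the result. Defaults to
#'   [esp2013_weights()].
#' @param by_sex Stratify the output (and the standardisation) by sex.
#'
#' @return Tibble with `year`, `stage` (and `sex` if requested) and `rate`
#'   (per 100,000 person-years).
#' @export
direct_standardised_rates <- function(cases, pop, std = esp2013_weights(),
                                      by_sex = FALSE) {
  stopifnot(all(age_bands() %in% names(std)), all(std >= 0), any(std > 0))
  w <- std[age_bands()] / sum(std[age_bands()])

  sex_groups <- if (by_sex) "sex" else character(0)
  py <- dplyr::summarise(
    dplyr::group_by(pop, dplyr::across(dplyr::all_of(c("year", sex_groups, "age_group")))),
    person_years = sum(.data$person_years), .groups = "drop")

  obs <- dplyr::count(cases,
    dplyr::across(dplyr::all_of(c("year", "stage", sex_groups, "age_group"))),
    name = "O")

  grid <- tidyr::expand_grid(
    year = sort(unique(pop$year)),
    stage = factor(stage_levels(), levels = stage_levels()),
    age_group = factor(age_bands(), levels = age_bands()))
  if (by_sex) grid <- tidyr::expand_grid(grid, sex = c("M", "F"))

  tab <- dplyr::left_join(grid, py, by = c("year", sex_groups, "age_group"))
  tab <- dplyr::left_join(tab, obs, by = c("year", "stage", sex_groups, "age_group"))
  tab$O[is.na(tab$O)] <- 0L
  tab$person_years[is.na(tab$person_years)] <- 0

  bad <- tab$person_years <= 0 & tab$O > 0
  if (any(bad)) {
    stop("cases observed in strata with zero person-years (first: year ",
         tab$year[bad][1], ", age ", as.character(tab$age_group[bad][1]), ").",
         call. = FALSE)
  }
  empty <- tab$person_years <= 0
  if (any(empty)) {
    warning(sum(empty), " empty age strata contribute rate 0 to the ",
            "standardised rates.", call. = FALSE)
  }
  tab$r <- ifelse(empty, 0, tab$O / tab$person_years)
  tab$w <- unname(w[as.character(tab$age_group)])
  out <- dplyr::summarise(
    dplyr::group_by(tab, dplyr::across(dplyr::all_of(c("year", "stage", sex_groups)))),
    rate = 1e5 * sum(.data$w * .data$r) / sum(.data$w), .groups = "drop")
  out
}

#' Expected counts by indirect standardisation
#'
#' For one stage, computes each area's expected count `E_i` from the sex- and
#' age-specific incidence of a comparison population: the reference rate in a
#' (sex, age band) stratum is the total observed count divided by the total
#' person-years in the comparison areas (pooled over years), and
#' `E_i = sum over strata of person_years_i * reference rate`. With the whole
#' study area as comparison the expected counts calibrate exactly:
#' `sum(E) = sum(O)`.
#'
#' @param cases Case table (all stages; filtered internally).
#' @param pop Population table covering every area in `cases`.
#' @param stage Stage to tabulate (one of [stage_levels()]).
#' @param comparison Area ids forming the comparison population; defaults to
#'   every area in `pop` (the "regional" convention). Local analyses pass the
#'   urban subarea's ids.
#'
#' @return Tibble `area_id`, `stage`, `O`, `E` with one row per area in `pop`.
#' @export
expected_counts <- function(cases, pop, stage, comparison = NULL) {
  stopifnot(stage %in% stage_levels())
  ids <- sort(unique(pop$area_id))
  if (is.null(comparison)) comparison <- ids
  if (length(comparison) == 0L) stop("`comparison` must be non-empty.", call. = FALSE)
  missing <- setdiff(unique(cases$area_id), ids)
  if (length(missing) > 0L) {
    stop("case areas missing from the population table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }

  cs <- cases[as.character(cases$stage) == stage, ]
  obs_strat <- dplyr::count(cs, .data$area_id, .data$sex, .data$age_group,
                            name = "O", .drop = FALSE)
  py_strat <- dplyr::summarise(dplyr::group_by(pop, .data$area_id, .data$sex,
                                               .data$age_group),
                               PY = sum(.data$person_years), .groups = "drop")

  in_cmp <- function(x) x$area_id %in% comparison
  ref_O <- dplyr::summarise(
    dplyr::group_by(obs_strat[in_cmp(obs_strat), ], .data$sex, .data$age_group),
    O = sum(.data$O), .groups = "drop")
  ref_PY <- dplyr::summarise(
    dplyr::group_by(py_strat[in_cmp(py_strat), ], .data$sex, .data$age_group),
    PY = sum(.data$PY), .groups = "drop")
  ref <- dplyr::full_join(ref_O, ref_PY, by = c("sex", "age_group"))
  ref$O[is.na(ref$O)] <- 0L
  ref$PY[is.na(ref$PY)] <- 0
  if (any(ref$PY <= 0 & ref$O > 0)) {
    stop("a stratum with cases has zero comparison person-years.", call. = FALSE)
  }
  ref$rate <- ifelse(ref$PY > 0, ref$O / ref$PY, 0)

  e_tab <- dplyr::left_join(py_strat, ref[, c("sex", "age_group", "rate")],
                            by = c("sex", "age_group"))
  e_tab$rate[is.na(e_tab$rate)] <- 0
  E <- dplyr::summarise(dplyr::group_by(e_tab, .data$area_id),
                        E = sum(.data$PY * .data$rate), .groups = "drop")
  O <- dplyr::count(cs, .data$area_id, name = "O")

  out <- tibble::tibble(area_id = ids, stage = stage)
  out <- dplyr::left_join(out, O, by = "area_id")
  out <- dplyr::left_join(out, E, by = "area_id")
  out$O[is.na(out$O)] <- 0L
  out$E[is.na(out$E)] <- 0
  out
}

#' Standardised incidence ratios
#'
#' Adds `sir = O / E` to an observed/expected table. Areas with `E = 0` and
#' `O = 0` get a missing SIR (flagged with a warning, and excluded from
#' smoothing input by [fit_bym()]); `E = 0` with `O > 0` is a data error.
#'
#' @param oe Tibble with columns `O` and `E` (e.g. from [expected_counts()]).
#' @return The input with a `sir` column appended.
#' @export
compute_sir <- function(oe) {
  stopifnot(all(c("O", "E") %in% names(oe)), all(oe$E >= 0), all(oe$O >= 0))
  if (any(oe$E == 0 & oe$O > 0)) {
    stop("observed cases in an area with zero expected count.", call. = FALSE)
  }
  sir <- ifelse(oe$E > 0, oe$O / oe$E, NA_real_)
  if (anyNA(sir)) {
    warning(sum(is.na(sir)), " area(s) with O = 0 and E = 0: SIR set to NA.",
            call. = FALSE)
  }
  oe$sir <- sir
  oe
}

#' Stage distribution and late-stage proportions by group
#'
#' Tabulates, for a grouping variable (age band, deprivation quintile, ...),
#' the per-stage case counts, the column percentages (each stage's count as a
#' share of that stage's total across groups), and the proportion of cases
#' with a late-stage tumour under the chosen definition (stage II-IV, or
#' stage III-IV only).
#'
#' @param x Either a case table with a `stage` column and the grouping
#'   column, or a pre-aggregated count table with columns `group`, `stage`,
#'   `n` (one row per group x stage).
#' @param group Name of the grouping column when `x` is a case table.
#' @param late Late-stage definition, `"II-IV"` (default) or `"III-IV"`.
#'
#' @return Tibble with one row per group: counts `n_I`, `n_II`, `n_III_IV`,
#'   column percentages `pct_*`, `n_total` and `prop_late`.
#' @export
stage_proportions <- function(x, group = "group", late = c("II-IV", "III-IV")) {
  late <- match.arg(late)
  if (all(c("stage", "n") %in% names(x))) {
    counts <- dplyr::summarise(
      dplyr::group_by(x, group = .data[[group]], stage = .data$stage),
      n = sum(.data$n), .groups = "drop")
  } else {
    stopifnot("stage" %in% names(x), group %in% names(x))
    if (anyNA(x$stage)) stop("every case must be staged.", call. = FALSE)
    counts <- dplyr::count(x, group = .data[[group]], stage = .data$stage)
  }
  counts$stage <- factor(as.character(counts$stage), levels = stage_levels())
  if (anyNA(counts$stage)) stop("unknown stage label in input.", call. = FALSE)

  wide <- tidyr::pivot_wider(counts, names_from = "stage", values_from = "n",
                             values_fill = 0L,
                             names_expand = TRUE)
  names(wide) <- c("group", "n_I", "n_II", "n_III_IV")
  tot <- c(sum(wide$n_I), sum(wide$n_II), sum(wide$n_III_IV))
  wide$pct_I <- 100 * wide$n_I / tot[1]
  wide$pct_II <- 100 * wide$n_II / tot[2]
  wide$pct_III_IV <- 100 * wide$n_III_IV / tot[3]
  wide$n_total <- wide$n_I + wide$n_II + wide$n_III_IV
  n_late <- if (late == "II-IV") wide$n_II + wide$n_III_IV else wide$n_III_IV
  wide$prop_late <- n_late / wide$n_total
  attr(wide, "late_definition") <- late
  wide
}
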