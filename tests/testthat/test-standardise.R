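make_case_rows <- function(n, area, sex, age, year, stage) {
  if (n == 0) return(NULL)
  tibble::tibble(area_id = area, sex = sex,
                 age_group = factor(age, levels = age_bands()),
                 year = year, stage = factor(stage, levels = stage_levels()))[
                   rep(1, n), ]
}

test_that("directly standardised rate of a constant rate is that constant", {
  # one area, all bands with person-years such that every band rate is r
  bands <- age_bands()
  py <- tidyr::expand_grid(area_id = "A", sex = c("M", "F"),
                           age_group = factor(bands, levels = bands),
                           year = 2010L)
  py$person_years <- 10000
  r <- 5 / 10000  # 5 cases per band per sex-summed 20000 PY
  cases <- dplyr::bind_rows(lapply(bands, function(b) {
    make_case_rows(10, "A", "M", b, 2010L, "I")
  }))
  out <- direct_standardised_rates(cases, py)
  got <- out$rate[out$stage == "I"]
  expect_equal(got, 1e5 * 10 / 20000, tolerance = 1e-12)

  # invariance to rescaling the standard weights
  out2 <- direct_standardised_rates(cases, py, std = esp2013_weights() * 37)
  expect_equal(out$rate, out2$rate, tolerance = 1e-12)
})

test_that("two-band hand example standardises to the weighted mean", {
  bands <- age_bands()
  py <- tidyr::expand_grid(area_id = "A", sex = c("M", "F"),
                           age_group = factor(bands, levels = bands),
                           year = 2010L)
  py$person_years <- ifelse(py$age_group %in% c("30-34", "35-39"), 50000, 0)
  # rates 10 and 30 per 100k over the two populated bands (100k PY pooled)
  cases <- dplyr::bind_rows(
    make_case_rows(10, "A", "F", "30-34", 2010L, "I"),
    make_case_rows(30, "A", "F", "35-39", 2010L, "I"))
  w <- stats::setNames(rep(0, 13), bands)
  w["30-34"] <- 0.25; w["35-39"] <- 0.75
  expect_warning(out <- direct_standardised_rates(cases, py, std = w),
                 "empty")
  expect_equal(out$rate[out$stage == "I"], 25, tolerance = 1e-9)

  # all standard mass on one band returns that band's crude rate
  w2 <- stats::setNames(rep(0, 13), bands); w2["35-39"] <- 1
  out2 <- suppressWarnings(direct_standardised_rates(cases, py, std = w2))
  expect_equal(out2$rate[out2$stage == "I"], 30, tolerance = 1e-9)
})

test_that("cases in an empty stratum raise a data-consistency error", {
  bands <- age_bands()
  py <- tidyr::expand_grid(area_id = "A", sex = c("M", "F"),
                           age_group = factor(bands, levels = bands),
                           year = 2010L)
  py$person_years <- 0
  cases <- make_case_rows(1, "A", "F", "30-34", 2010L, "I")
  expect_error(direct_standardised_rates(cases, py), "zero person-years")
})

test_that("internal-reference expected counts calibrate exactly", {
  s <- std_study()
  for (stage in c("I", "II")) {
    oe <- expected_counts(s$cases, s$pop, stage)
    expect_equal(sum(oe$E), sum(oe$O), tolerance = 1e-9)
  }
})

test_that("expected counts match a hand enumeration on a 2x2 toy", {
  bands <- age_bands()
  py <- tidyr::expand_grid(area_id = c("A", "B"), sex = "F",
                           age_group = factor(bands, levels = bands),
                           year = 2010L)
  py$person_years <- 0
  py$person_years[py$age_group == "30-34"] <- c(100, 300)
  py$person_years[py$age_group == "35-39"] <- c(200, 100)
  cases <- dplyr::bind_rows(
    make_case_rows(2, "A", "F", "30-34", 2010L, "I"),
    make_case_rows(6, "B", "F", "30-34", 2010L, "I"),
    make_case_rows(3, "A", "F", "35-39", 2010L, "I"))
  oe <- expected_counts(cases, py, "I")
  # reference rates: 8/400 in 30-34, 3/300 in 35-39
  expect_equal(oe$E[oe$area_id == "A"], 100 * 8 / 400 + 200 * 3 / 300,
               tolerance = 1e-12)
  expect_equal(oe$E[oe$area_id == "B"], 300 * 8 / 400 + 100 * 3 / 300,
               tolerance = 1e-12)

  # a zero-population area gets E = 0
  py0 <- py; py0$person_years[py0$area_id == "B"] <- 0
  cases0 <- dplyr::bind_rows(
    make_case_rows(2, "A", "F", "30-34", 2010L, "I"))
  oe0 <- expected_counts(cases0, py0, "I")
  expect_equal(oe0$E[oe0$area_id == "B"], 0)
})

test_that("a restricted comparison population changes the reference rates", {
  s <- std_study()
  local_ids <- s$geo$areas$area_id[s$geo$areas$col <= 5]
  oe <- expected_counts(s$cases, s$pop, "I", comparison = local_ids)
  in_local <- oe$area_id %in% local_ids
  expect_equal(sum(oe$E[in_local]), sum(oe$O[in_local]), tolerance = 1e-9)
})

test_that("SIR arithmetic and degenerate cases behave as specified", {
  oe <- tibble::tibble(area_id = c("a", "b", "c"),
                       O = c(3L, 0L, 5L), E = c(3, 2, 2.5))
  out <- compute_sir(oe)
  expect_equal(out$sir, c(1, 0, 2))
  expect_warning(
    out2 <- compute_sir(tibble::tibble(area_id = "a", O = 0L, E = 0)),
    "NA")
  expect_true(is.na(out2$sir))
  expect_error(compute_sir(tibble::tibble(area_id = "a", O = 2L, E = 0)),
               "zero expected")
})

test_that("published late-stage proportions are reproduced exactly", {
  counts <- melanoma_stage_counts("age")
  prop <- stage_proportions(counts, late = "II-IV")
  got <- stats::setNames(round(prop$prop_late, 2), prop$group)
  expect_equal(got[["30-34"]], 0.14)
  expect_equal(got[["90+"]], 0.68)
  reg <- stage_proportions(melanoma_stage_counts("region"), late = "II-IV")
  expect_equal(round(reg$prop_late[reg$group == "Q5"], 2), 0.24)
  expect_equal(round(reg$prop_late[reg$group == "Q1"], 2), 0.35)
})

test_that("stage percentages are column shares that sum to 100", {
  prop <- stage_proportions(melanoma_stage_counts("age"))
  expect_equal(sum(prop$pct_I), 100, tolerance = 1e-9)
  expect_equal(sum(prop$pct_II), 100, tolerance = 1e-9)
  expect_equal(sum(prop$pct_III_IV), 100, tolerance = 1e-9)
  expect_equal(round(prop$pct_I[prop$group == "30-34"], 1), 3.5)
})

test_that("single-stage groups give degenerate late proportions", {
  x <- tibble::tibble(group = c("g1", "g2"), stage = c("I", "II"),
                      n = c(10L, 4L))
  p <- stage_proportions(x, late = "II-IV")
  expect_equal(p$prop_late[p$group == "g1"], 0)
  expect_equal(p$prop_late[p$group == "g2"], 1)
  p2 <- stage_proportions(x, late = "III-IV")
  expect_equal(p2$prop_late, c(0, 0))
})
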