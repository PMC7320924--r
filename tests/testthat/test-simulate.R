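test_that("ICAR draws sum to zero and require a connected graph", {
  geo <- generate_geography(4, 5, 0, seed = 1)
  set.seed(1)
  u <- simulate_icar(geo$adjacency, tau = 10)
  expect_equal(sum(u), 0, tolerance = 1e-10)
  expect_equal(length(u), 20L)
  disconnected <- list(A = "B", B = "A", C = "D", D = "C")
  expect_error(simulate_icar(disconnected, 1), "connected")
})

test_that("ICAR marginal scale shrinks with the precision", {
  geo <- generate_geography(5, 5, 0, seed = 1)
  set.seed(2)
  sd_small_tau <- mean(replicate(30, sd(simulate_icar(geo$adjacency, 1))))
  sd_large_tau <- mean(replicate(30, sd(simulate_icar(geo$adjacency, 100))))
  expect_gt(sd_small_tau, 5 * sd_large_tau)
})

test_that("zero baseline rates give an empty case table", {
  geo <- generate_geography(2, 2, 0, seed = 1)
  pop <- generate_population(geo, 800, 2, seed = 1)
  pr <- risk_params(baseline = baseline_rates(
    stage_rates = c("I" = 0, "II" = 0, "III-IV" = 0)))
  cases <- simulate_cases(pop, geo, pr, seed = 1)
  expect_equal(nrow(cases), 0L)
})

test_that("simulated totals match the Poisson expectation without fields", {
  # near-degenerate fields (huge precisions), no quintile or alpha effects:
  # total counts should be Poisson with mean sum(PY * rate)
  geo <- generate_geography(2, 2, 0, seed = 1)
  pop <- generate_population(geo, 2000, 3, seed = 2)
  pr <- risk_params(
    quintile_log_effects = list("I" = rep(0, 5), "II" = rep(0, 5),
                                "III-IV" = rep(0, 5)),
    tau_u = c("I" = 1e8, "II" = 1e8, "III-IV" = 1e8),
    tau_v = c("I" = 1e8, "II" = 1e8, "III-IV" = 1e8))
  b <- pr$baseline
  joined <- merge(as.data.frame(pop), as.data.frame(b),
                  by = c("sex", "age_group"))
  expected_total <- sum(joined$person_years * joined$rate)
  totals <- vapply(1:200, function(s) {
    nrow(simulate_cases(pop, geo, pr, seed = 1000 + s))
  }, numeric(1))
  se <- sqrt(expected_total / 200)
  expect_lt(abs(mean(totals) - expected_total), 3 * se)
})

test_that("simulated crude rates track the stage-specific baselines", {
  geo <- generate_geography(8, 8, 0, seed = 3)
  pop <- generate_population(geo, 2000, 9, seed = 4)
  cases <- simulate_cases(pop, geo, seed = 5)
  py_tot <- sum(pop$person_years)
  crude <- table(cases$stage) / py_tot * 1e5
  # Monte-Carlo + random-field tolerance around the 20 / 5 / 2 targets
  expect_equal(unname(crude[["I"]]), 20, tolerance = 0.25)
  expect_equal(unname(crude[["II"]]), 5, tolerance = 0.35)
  expect_equal(unname(crude[["III-IV"]]), 2, tolerance = 0.5)
})

test_that("aggregated simulated counts match a direct Poisson sampler", {
  # exchangeability with stratum-by-stratum Poisson sampling on a 4-area toy
  geo <- generate_geography(2, 2, 0, seed = 1)
  pop <- generate_population(geo, 1500, 2, seed = 2)
  pr <- risk_params(
    quintile_log_effects = list("I" = rep(0, 5), "II" = rep(0, 5),
                                "III-IV" = rep(0, 5)),
    tau_u = c("I" = 1e8, "II" = 1e8, "III-IV" = 1e8),
    tau_v = c("I" = 1e8, "II" = 1e8, "III-IV" = 1e8))
  b <- pr$baseline
  joined <- merge(as.data.frame(pop), as.data.frame(b),
                  by = c("sex", "age_group"))
  mu_area <- tapply(joined$person_years * joined$rate, joined$area_id, sum)

  sim_counts <- vapply(1:500, function(s) {
    cs <- simulate_cases(pop, geo, pr, seed = 3000 + s)
    vapply(names(mu_area), function(a) sum(cs$area_id == a), numeric(1))
  }, numeric(4))
  set.seed(99)
  direct <- vapply(1:500, function(s) stats::rpois(4, mu_area), numeric(4))

  for (i in 1:4) {
    se_mean <- sqrt(mu_area[i] / 500)
    expect_lt(abs(mean(sim_counts[i, ]) - mean(direct[i, ])), 4 * se_mean)
    # Poisson: variance ~ mean
    expect_lt(abs(stats::var(sim_counts[i, ]) / mu_area[i] - 1), 0.35)
  }
})

test_that("stage recoding follows the thickness/ulceration/spread rules", {
  expect_equal(recode_stage(0.8, TRUE, FALSE), "I")
  expect_equal(recode_stage(1.5, FALSE, FALSE), "I")
  expect_equal(recode_stage(1.5, TRUE, FALSE), "II")
  expect_equal(recode_stage(3.2, FALSE, FALSE), "II")
  expect_equal(recode_stage(5.0, FALSE, TRUE), "III-IV")
  expect_equal(recode_stage(NA, FALSE, TRUE), "III-IV")
  # boundaries: 1.0 is thin; 2.0 still in the ulceration-dependent band
  expect_equal(recode_stage(1.0, TRUE, FALSE), "I")
  expect_equal(recode_stage(2.0, FALSE, FALSE), "I")
  expect_equal(recode_stage(2.0, TRUE, FALSE), "II")
  expect_error(recode_stage(NA, FALSE, FALSE), "unstageable")
  expect_equal(recode_stage(NA, FALSE, FALSE, on_unstageable = "na"),
               NA_character_)
})

test_that("case simulation is deterministic and validates its inputs", {
  geo <- generate_geography(2, 2, 0, seed = 1)
  pop <- generate_population(geo, 1500, 2, seed = 2)
  c1 <- simulate_cases(pop, geo, seed = 42)
  c2 <- simulate_cases(pop, geo, seed = 42)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  pop_bad <- pop
  pop_bad$area_id[1] <- "ZZZZ"
  expect_error(simulate_cases(pop_bad, geo, seed = 1), "missing from geography")
})
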