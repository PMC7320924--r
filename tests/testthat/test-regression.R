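test_that("identical smoothed SIRs give unit ratios", {
  q <- stats::setNames(rep(paste0("Q", 1:5), each = 4), sprintf("i%02d", 1:20))
  theta <- stats::setNames(rep(1.3, 20), names(q))
  out <- ecological_regression(theta, q, var_log_sir = rep(0.01, 20))
  expect_equal(out$ratio, rep(1, 5), tolerance = 1e-9)
  expect_equal(out$ci_low[2:5], rep(1, 4), tolerance = 1e-6)
})

test_that("equal weights reduce WLS to group-mean differences", {
  set.seed(3)
  q <- stats::setNames(rep(paste0("Q", 1:5), each = 8), sprintf("j%02d", 1:40))
  theta <- stats::setNames(exp(stats::rnorm(40, 0, 0.3)), names(q))
  out <- ecological_regression(theta, q, var_log_sir = rep(0.25, 40))
  gm <- tapply(log(theta), as.character(q), mean)
  oracle <- exp(gm[paste0("Q", 2:5)] - gm[["Q1"]])
  expect_equal(out$ratio[2:5], as.numeric(oracle), tolerance = 1e-9)
})

test_that("WLS is invariant to rescaling all weights", {
  set.seed(4)
  q <- stats::setNames(rep(paste0("Q", 1:5), each = 6), sprintf("k%02d", 1:30))
  theta <- stats::setNames(exp(stats::rnorm(30, 0, 0.2)), names(q))
  v <- stats::runif(30, 0.01, 0.2)
  o1 <- ecological_regression(theta, q, var_log_sir = v)
  o2 <- ecological_regression(theta, q, var_log_sir = v * 1000)
  expect_equal(o1$ratio, o2$ratio, tolerance = 1e-9)
  expect_equal(o1$ci_low, o2$ci_low, tolerance = 1e-9)
})

test_that("ecological regression validates its inputs", {
  q <- stats::setNames(rep(c("Q1", "Q2", "Q3", "Q4"), each = 5),
                       sprintf("m%02d", 1:20))
  theta <- stats::setNames(rep(1, 20), names(q))
  expect_error(ecological_regression(theta, q, var_log_sir = rep(0.1, 20)),
               "Q5")
  q2 <- stats::setNames(c(rep(paste0("Q", 1:4), each = 5), "Q5"),
                        sprintf("m%02d", 1:21))
  theta2 <- stats::setNames(rep(1, 21), names(q2))
  expect_error(ecological_regression(theta2, q2, var_log_sir = rep(0.1, 21)),
               "fewer than 2")
  expect_error(ecological_regression(theta, q, var_log_sir = rep(0, 20)),
               "positive")
})

test_that("a 2x2 table gives the closed-form cross-product odds ratio", {
  # exposed/unexposed x late/early with counts (30, 70) / (10, 90):
  # OR = 30*90 / (70*10)
  d <- tibble::tibble(
    area_id = "x",
    sex = rep("F", 200),
    age_group = rep(c("30-34", "35-39"), c(100, 100)),
    stage = c(rep("II", 30), rep("I", 70), rep("II", 10), rep("I", 90)),
    year = 2010L)
  out <- late_stage_logistic(d, covariates = "age_group")
  or <- out$or[out$level == "35-39"]
  # reference is 30-34 (the exposed row), so invert for the cross-product
  expect_equal(1 / or, 30 * 90 / (70 * 10), tolerance = 1e-6)
})

test_that("glm IRLS agrees with direct Newton optimisation", {
  set.seed(8)
  n <- 400
  d <- tibble::tibble(
    area_id = "x",
    sex = sample(c("M", "F"), n, TRUE),
    age_group = sample(age_bands()[1:4], n, TRUE),
    year = 2010L)
  lp <- -1 + 0.5 * (d$sex == "M") + 0.2 * match(d$age_group, age_bands())
  d$stage <- ifelse(stats::runif(n) < stats::plogis(lp), "II", "I")
  out <- late_stage_logistic(d, covariates = c("age_group", "sex"))

  X <- stats::model.matrix(~ factor(age_group, levels = age_bands()[1:4]) +
                             factor(sex, levels = c("F", "M")), data = d)
  y <- as.integer(d$stage == "II")
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(reltol = 1e-14))
  newton_or <- exp(opt$par[-1])
  got <- out$or[!is.na(out$ci_low)]
  expect_equal(unname(got), unname(newton_or), tolerance = 1e-5)
})

test_that("null-data odds ratios centre on one with covering intervals", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 600
    d <- tibble::tibble(
      area_id = "x",
      sex = sample(c("M", "F"), n, TRUE),
      age_group = sample(age_bands()[1:3], n, TRUE),
      stage = sample(c("I", "II"), n, TRUE, prob = c(0.75, 0.25)),
      year = 2010L)
    out <- late_stage_logistic(d, covariates = c("age_group", "sex"))
    est <- out[!is.na(out$ci_low), ]
    hits <- hits + sum(est$ci_low <= 1 & 1 <= est$ci_high)
    total <- total + nrow(est)
  }
  expect_gte(hits / total, 0.90)
})

test_that("a monotone age gradient in truth appears in the fitted ORs", {
  mono <- 0L
  for (s in 1:10) {
    set.seed(200 + s)
    n <- 1500
    d <- tibble::tibble(
      area_id = "x",
      sex = "F",
      age_group = sample(age_bands()[c(1, 5, 9, 13)], n, TRUE),
      year = 2010L)
    k <- match(d$age_group, age_bands()[c(1, 5, 9, 13)]) - 1
    d$stage <- ifelse(stats::runif(n) < stats::plogis(-2 + 0.8 * k), "II", "I")
    out <- late_stage_logistic(d, covariates = "age_group")
    ors <- out$or
    mono <- mono + !is.unsorted(ors)
  }
  expect_gte(mono, 8L)
})

test_that("separation is reported as an actionable error", {
  d <- tibble::tibble(
    area_id = "x",
    sex = rep(c("M", "F"), each = 30),
    age_group = "30-34",
    stage = rep(c("II", "I"), each = 30),
    year = 2010L)
  expect_error(late_stage_logistic(d, covariates = "sex"), "separation")
})
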