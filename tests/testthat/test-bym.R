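test_that("single-area fit matches the conjugate Poisson-Gamma picture", {
  # one island area: u pinned at 0, so theta = exp(alpha + v); with O = E = 50
  # the posterior for theta concentrates near 1 and PP near 0.5
  sir <- tibble::tibble(area_id = "solo", O = 50L, E = 50)
  expect_warning(
    fit <- fit_bym(sir, list(solo = character(0)), mcmc = mc_quick(1)),
    "island")
  expect_equal(fit$summary$smoothed_sir, 1, tolerance = 0.1)
  expect_equal(unname(posterior_pp(fit)), 0.5, tolerance = 0.1)
  # conjugate oracle: with a flat prior on log-mean, posterior ~ Gamma(O, E);
  # its mean O/E = 1 and its sd bounds the credible spread
  expect_lt(fit$summary$ci_high - fit$summary$ci_low, 4 * sqrt(50) / 50 * 1.5)
})

test_that("homogeneous data shrink every area to the null", {
  geo <- generate_geography(5, 5, 0, seed = 1)
  sir <- tibble::tibble(area_id = geo$areas$area_id, O = 100L, E = 100)
  fit <- fit_bym(sir, geo$adjacency, mcmc = mc_quick(2))
  expect_true(all(fit$summary$smoothed_sir > 0.95 &
                    fit$summary$smoothed_sir < 1.05))
  pp <- posterior_pp(fit)
  expect_true(all(pp > 0.2 & pp < 0.8))
})

test_that("posterior exceedance probabilities count draws above one", {
  th <- matrix(2, 200, 3)
  expect_equal(unname(posterior_pp(fake_fit(th))), rep(1, 3))
  th2 <- matrix(rep(c(0.5, 1.5), each = 100), 200, 2)
  expect_equal(unname(posterior_pp(fake_fit(th2))), c(0.5, 0.5))
  set.seed(1)
  th3 <- matrix(exp(stats::rnorm(1000 * 2, 0, 0.3)), 1000, 2)
  expect_equal(unname(posterior_pp(fake_fit(th3))), colMeans(th3 > 1))
  expect_error(posterior_pp(fake_fit(matrix(1, 50, 2))), "100")
})

test_that("variance fraction hits its limits and orders correctly", {
  n_draw <- 100
  u <- matrix(stats::rnorm(n_draw * 10), n_draw, 10)
  v0 <- matrix(1e-12 * stats::rnorm(n_draw * 10), n_draw, 10)
  expect_equal(variance_fraction(fake_fit(exp(u), u = u, v = v0)), 1,
               tolerance = 1e-6)
  expect_equal(variance_fraction(fake_fit(exp(v0), u = v0, v = u)), 0,
               tolerance = 1e-6)

  # strong spatial structure in the generative model shows up in the fit
  geo <- generate_geography(8, 8, 0, seed = 4)
  set.seed(11)
  u_true <- simulate_icar(geo$adjacency, 10)   # big structured field
  O <- stats::rpois(64, 30 * exp(u_true))
  sir <- tibble::tibble(area_id = geo$areas$area_id, O = O,
                        E = 30 * sum(O) / sum(30 * exp(u_true)))
  fit <- fit_bym(sir, geo$adjacency, mcmc = mc_quick(3))
  expect_gt(variance_fraction(fit), 0.5)
})

test_that("DIC arithmetic matches the closed-form Poisson deviance", {
  # draws all identical -> pD = 0 and DIC = deviance at the plug-in
  O <- c(3L, 7L, 5L)
  E <- c(4, 6, 5)
  th <- matrix(rep(c(0.8, 1.2, 1.0), each = 150), 150, 3)
  f <- fake_fit(th, O = O, E = E)
  d <- compute_dic(f)
  closed <- sum(-2 * stats::dpois(O, E * c(0.8, 1.2, 1.0), log = TRUE))
  expect_equal(d$mean_deviance, closed, tolerance = 1e-9)
  expect_equal(d$pD, 0, tolerance = 1e-9)
  expect_equal(d$dic, closed, tolerance = 1e-9)
})

test_that("zero-inflation recovery and nesting behave as expected", {
  geo <- generate_geography(10, 10, 0, seed = 20)
  set.seed(21)
  O <- stats::rpois(100, 8)
  O[sample(100, 50)] <- 0L
  sir <- tibble::tibble(area_id = geo$areas$area_id, O = O, E = rep(8, 100))
  fz <- fit_zip_bym(sir, geo$adjacency, mcmc = mc_quick(5))
  expect_gt(mean(fz$draws$pi), 0.3)
  expect_lt(mean(fz$draws$pi), 0.7)

  # no zeros in the data: pi posterior collapses towards 0
  set.seed(22)
  O2 <- stats::rpois(100, 10) + 1L
  sir2 <- tibble::tibble(area_id = geo$areas$area_id, O = O2, E = rep(10, 100))
  fz2 <- fit_zip_bym(sir2, geo$adjacency, mcmc = mc_quick(6))
  expect_lt(mean(fz2$draws$pi), 0.1)

  # degenerate pi prior at 0 reduces the ZIP fit to the Poisson fit
  fz0 <- fit_zip_bym(sir2, geo$adjacency,
                     priors = prior_spec(zip_pi = c(0.001, 1000)),
                     mcmc = mc_quick(7))
  fp <- fit_bym(sir2, geo$adjacency, mcmc = mc_quick(7))
  expect_equal(fz0$summary$smoothed_sir, fp$summary$smoothed_sir,
               tolerance = 0.05)
})

test_that("smoothing shrinks variance and preserves equal-precision ranking", {
  s <- std_study()
  fit <- fit_bym(s$sir, s$geo$adjacency, mcmc = mc_quick(8))
  ok <- s$sir$E > 0
  expect_lt(stats::var(fit$summary$smoothed_sir),
            stats::var(s$sir$sir[ok]) + 1e-12)

  # equal-E areas: smoothed ranking follows raw ranking (use near-equal E)
  sirq <- tibble::tibble(area_id = s$geo$areas$area_id,
                         O = s$sir$O, E = rep(mean(s$sir$E), nrow(s$sir)))
  fitq <- fit_bym(sirq, s$geo$adjacency, mcmc = mc_quick(9))
  grp <- split(seq_len(nrow(sirq)), sirq$O)
  med_by_O <- vapply(grp, function(i) stats::median(fitq$summary$smoothed_sir[i]),
                     numeric(1))
  med_by_O <- med_by_O[order(as.numeric(names(med_by_O)))]
  expect_true(all(diff(med_by_O) > -0.02))  # monotone up to MC noise
})

test_that("alternative vague hyperpriors leave the smoothed SIRs unchanged", {
  s <- std_study()
  mc <- mcmc_control(n_iter = 8000, burn_in = 4000, thin = 2, n_chains = 2,
                     seed = 1)
  f0 <- fit_bym(s$sir, s$geo$adjacency, prior_spec(), mc)
  f1 <- fit_bym(s$sir, s$geo$adjacency,
                prior_spec(tau_u = c(1, 0.001), tau_v = c(1, 0.001)), mc)
  f2 <- fit_bym(s$sir, s$geo$adjacency,
                prior_spec(tau_u = c(0.1, 1e-4), tau_v = c(0.1, 1e-4)), mc)
  expect_lt(max(abs(f1$summary$smoothed_sir / f0$summary$smoothed_sir - 1)),
            0.05)
  expect_lt(max(abs(f2$summary$smoothed_sir / f0$summary$smoothed_sir - 1)),
            0.05)
})

test_that("fits are reproducible for a fixed seed", {
  s <- std_study()
  f1 <- fit_bym(s$sir, s$geo$adjacency, mcmc = mc_quick(77))
  f2 <- fit_bym(s$sir, s$geo$adjacency, mcmc = mc_quick(77))
  expect_identical(f1$draws$theta, f2$draws$theta)
  expect_identical(f1$draws$tau_u, f2$draws$tau_u)
})

test_that("degenerate graphs and inputs are handled explicitly", {
  sir <- tibble::tibble(area_id = c("a", "b", "c", "d"),
                        O = c(1L, 2L, 0L, 1L), E = rep(1, 4))
  disconnected <- list(a = "b", b = "a", c = "d", d = "c")
  expect_error(fit_bym(sir, disconnected, mcmc = mc_quick(1)), "disconnected")

  sir0 <- tibble::tibble(area_id = c("a", "b", "c", "d"),
                         O = rep(0L, 4), E = rep(1, 4))
  expect_warning(fit_bym(sir0, ring4(), mcmc = mc_quick(1)),
                 "prior-dominated")

  sirE <- tibble::tibble(area_id = c("a", "b", "c", "d"),
                         O = c(1L, 1L, 0L, 1L), E = c(1, 1, 0, 1))
  expect_warning(fit_bym(sirE, ring4(), mcmc = mc_quick(1)), "E = 0")
  sirE2 <- sirE; sirE2$O[3] <- 2L
  expect_error(fit_bym(sirE2, ring4(), mcmc = mc_quick(1)), "cannot be smoothed")
})

test_that("quintile fixed effects in the model are recovered on simulation", {
  geo <- generate_geography(10, 10, 1, seed = 30)
  set.seed(31)
  qnum <- as.integer(substring(as.character(geo$areas$quintile), 2))
  beta_true <- c(0, 0.1, 0.1, 0.17, 0.3)
  eta <- beta_true[qnum]
  O <- stats::rpois(100, 15 * exp(eta))
  sir <- tibble::tibble(area_id = geo$areas$area_id, O = O,
                        E = 15 * sum(O) / sum(15 * exp(eta)))
  fit <- fit_bym(sir, geo$adjacency, mcmc = mc_quick(32, n_iter = 6000,
                                                     burn_in = 3000),
                 covariates = geo$areas$quintile)
  cs <- fit$covariate_summary
  expect_equal(nrow(cs), 4L)
  # Q5 effect clearly positive and of the right size
  expect_gt(cs$ratio[4], 1.05)
  expect_lt(abs(cs$ratio[4] - exp(0.3)), 0.25)
  expect_true(all(cs$ci_low < cs$ratio & cs$ratio < cs$ci_high))
})
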