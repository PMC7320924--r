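# Shared fixtures and micro-helpers for the suite. Everything is generated
# in code; nothing is read from disk except the published count table that
# ships with the package.

# a 4-area ring graph
ring4 <- function() {
  list(a = c("b", "d"), b = c("a", "c"), c = c("b", "d"), d = c("c", "a"))
}

# quick MCMC settings for tests that only need a rough posterior
mc_quick <- function(seed = 1L, n_iter = 3000, burn_in = 1500, thin = 2,
                     n_chains = 2) {
  mcmc_control(n_iter = n_iter, burn_in = burn_in, thin = thin,
               n_chains = n_chains, seed = seed)
}

# minimal constructed bym_fit for summary-arithmetic tests (not a real fit)
fake_fit <- function(theta, O = NULL, E = NULL, u = NULL, v = NULL,
                     deviance = NULL, family = "poisson", pi = NULL) {
  n_draw <- nrow(theta)
  n <- ncol(theta)
  if (is.null(u)) u <- matrix(0, n_draw, n)
  if (is.null(v)) v <- matrix(0, n_draw, n)
  if (is.null(O)) O <- rep(1L, n)
  if (is.null(E)) E <- rep(1, n)
  if (is.null(deviance)) {
    deviance <- vapply(seq_len(n_draw), function(d) {
      sum(-2 * stats::dpois(O, E * theta[d, ], log = TRUE))
    }, numeric(1))
  }
  if (is.null(pi)) pi <- rep(0, n_draw)
  ids <- sprintf("Z%02d", seq_len(n))
  colnames(theta) <- ids
  structure(list(
    area_id = ids, O = O, E = E, family = family,
    draws = list(theta = theta, u = u, v = v, alpha = rep(0, n_draw),
                 tau_u = rep(1, n_draw), tau_v = rep(1, n_draw),
                 pi = pi, deviance = deviance,
                 chain = rep(1:2, length.out = n_draw))),
    class = "bym_fit")
}

# small simulated study used by several expensive tests (memoised per session)
std_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geo <- generate_geography(8, 10, 1, seed = 3)
      pop <- generate_population(geo, 3200, 9, seed = 4)
      cases <- simulate_cases(pop, geo, seed = 5)
      sir <- suppressWarnings(compute_sir(expected_counts(cases, pop, "I")))
      cache <<- list(geo = geo, pop = pop, cases = cases, sir = sir)
    }
    cache
  }
})
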