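#' Prior specification for the BYM model
#'
#' Gamma (shape/rate) priors on the structured and unstructured precisions —
#' the package's concrete rendering of minimally informative precision
#' priors — and a flat prior on the global log-level `alpha`. The defaults
#' (shape 0.5, rate 0.0005) are vague on the log-precision scale; posterior
#' summaries are insensitive to reasonable alternatives (see the package
#' vignette).
#'
#' @param tau_u,tau_v Length-2 numeric `c(shape, rate)` for each precision.
#' @param zip_pi Length-2 numeric `c(a, b)` Beta prior on the zero-inflation
#'   mixing weight (used by [fit_zip_bym()] only).
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(tau_u = c(0.5, 0.0005), tau_v = c(0.5, 0.0005),
                       zip_pi = c(1, 1)) {
  stopifnot(length(tau_u) == 2L, length(tau_v) == 2L, length(zip_pi) == 2L,
            all(tau_u > 0), all(tau_v > 0), all(zip_pi > 0))
  structure(list(tau_u = tau_u, tau_v = tau_v, zip_pi = zip_pi),
            class = "prior_spec")
}

#' MCMC settings for [fit_bym()]
#'
#' @param n_iter Iterations per chain (including burn-in).
#' @param burn_in Burn-in iterations discarded per chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed (chain `c` uses `seed + c - 1`).
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_iter = 20000, burn_in = 10000, thin = 5,
                         n_chains = 4, seed = 1L) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1, n_chains >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Fit the Besag-York-Mollie model to small-area observed/expected counts
#'
#' Markov chain Monte Carlo for the model `O_i ~ Poisson(E_i * theta_i)`,
#' `log theta_i = alpha + u_i + v_i`, with a sum-to-zero intrinsic CAR prior
#' on the structured effects `u` and i.i.d. Gaussian unstructured effects
#' `v`. Sampling is Metropolis-within-Gibbs: adaptive single-site random-walk
#' updates for `alpha`, `u_i`, `v_i` and conjugate Gamma updates for the two
#' precisions; the sum-to-zero constraint is imposed by recentring `u` each
#' sweep (transferring the mean into `alpha`). Areas without neighbours
#' (islands) have `u_i` pinned to 0 with a warning; rows with `E = 0`
#' (or a missing SIR) are dropped from the fit with a warning.
#'
#' @param sir Tibble for one stage with columns `area_id`, `O`, `E` (a
#'   [compute_sir()] output works as-is).
#' @param adjacency Named neighbour list covering the areas in `sir`.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_control()].
#' @param family `"poisson"` (default) or `"zip"` for the zero-inflated
#'   alternative (see [fit_zip_bym()]).
#' @param covariates Optional area-level fixed effects added to the linear
#'   predictor (`log theta_i = alpha + x_i' beta + u_i + v_i`): a factor
#'   aligned with the areas of `sir` (first level is the reference; dummy
#'   coding), or a numeric design matrix. Coefficients get diffuse
#'   `N(0, 10^2)` priors. This is the fully Bayesian ecological-regression
#'   variant: `exp(beta)` draws are returned in `$draws$beta` and summarised
#'   in `$covariate_summary`.
#'
#' @return Object of class `bym_fit` with elements
#'   `area_id`; `O`; `E`; `draws` (list of matrices/vectors pooled across
#'   chains: `alpha`, `u`, `v`, `theta`, `tau_u`, `tau_v`, `pi`, `deviance`,
#'   plus `chain` index); `summary` (per-area tibble with raw and smoothed
#'   SIR, 95% credible interval and `pp = Pr(theta > 1 | data)`);
#'   `diagnostics` (acceptance rates and split-chain R-hat for `alpha` and
#'   the log-precisions, with a warning above 1.1); `dic` (see
#'   [compute_dic()]).
#' @export
fit_bym <- function(sir, adjacency, priors = prior_spec(),
                    mcmc = mcmc_control(), family = c("poisson", "zip"),
                    covariates = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(priors, "prior_spec"), inherits(mcmc, "mcmc_control"),
            all(c("area_id", "O", "E") %in% names(sir)))
  sir <- as.data.frame(sir)

  if (!is.null(covariates) && !is.matrix(covariates)) {
    f <- factor(covariates)
    covariates <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(covariates) <- sub("^f", "", colnames(covariates))
  }
  if (!is.null(covariates)) stopifnot(nrow(covariates) == nrow(sir))

  drop <- sir$E <= 0
  if (any(drop)) {
    if (any(drop & sir$O > 0)) {
      stop("areas with O > 0 but E = 0 cannot be smoothed.", call. = FALSE)
    }
    warning(sum(drop), " area(s) with E = 0 excluded from the BYM fit.",
            call. = FALSE)
    sir <- sir[!drop, ]
    if (!is.null(covariates)) covariates <- covariates[!drop, , drop = FALSE]
  }
  if (nrow(sir) < 1L) stop("no areas left to fit.", call. = FALSE)
  if (all(sir$O == 0)) {
    warning("all observed counts are zero; the posterior is prior-dominated.",
            call. = FALSE)
  }
  ids <- sir$area_id
  nb <- adjacency_index(adjacency, ids)
  pinned <- lengths(nb) == 0L
  if (any(pinned)) {
    warning(sum(pinned), " island area(s) without neighbours: structured ",
            "effect pinned to 0.", call. = FALSE)
  }
  comp <- graph_components(nb)
  free_comp <- unique(comp[!pinned])
  if (length(free_comp) > 1L) {
    stop("the adjacency graph (excluding islands) is disconnected; ",
         "fit components separately.", call. = FALSE)
  }

  n <- length(ids)
  nb0 <- lapply(nb, function(x) as.integer(x - 1L))
  X <- if (is.null(covariates)) matrix(0, n, 0) else as.matrix(covariates)
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    chains[[ch]] <- withr_seed(mcmc$seed + ch - 1L, {
      bym_mcmc_cpp(as.integer(sir$O), as.numeric(sir$E), nb0,
                   priors$tau_u[1], priors$tau_u[2],
                   priors$tau_v[1], priors$tau_v[2],
                   mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                   family == "zip", priors$zip_pi[1], priors$zip_pi[2],
                   as.integer(pinned), X)
    })
  }

  pool <- function(name) do.call(c, lapply(chains, `[[`, name))
  pool_m <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  draws <- list(
    alpha = pool("alpha"),
    u = pool_m("u"), v = pool_m("v"),
    tau_u = pool("tau_u"), tau_v = pool("tau_v"),
    pi = pool("pi"), deviance = pool("deviance"),
    chain = rep(seq_len(mcmc$n_chains),
                each = length(chains[[1]]$alpha)))
  draws$theta <- exp(draws$alpha + draws$u + draws$v)
  if (ncol(X) > 0) {
    draws$beta <- pool_m("beta")
    colnames(draws$beta) <- colnames(X)
    draws$theta <- draws$theta * exp(draws$beta %*% t(X))
  }
  colnames(draws$u) <- colnames(draws$v) <- colnames(draws$theta) <- ids

  theta_mean <- colMeans(draws$theta)
  qs <- apply(draws$theta, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  summary <- tibble::tibble(
    area_id = ids,
    O = sir$O, E = sir$E,
    raw_sir = sir$O / sir$E,
    smoothed_sir = unname(theta_mean),
    smoothed_sir_median = unname(qs[2, ]),
    ci_low = unname(qs[1, ]), ci_high = unname(qs[3, ]),
    pp = unname(colMeans(draws$theta > 1)))
  if ("stage" %in% names(sir)) {
    summary <- tibble::add_column(summary, stage = sir$stage, .after = 1)
  }

  covariate_summary <- NULL
  if (ncol(X) > 0) {
    bq <- apply(draws$beta, 2, stats::quantile, probs = c(0.025, 0.975))
    covariate_summary <- tibble::tibble(
      term = colnames(X),
      ratio = exp(colMeans(draws$beta)),
      ci_low = exp(bq[1, ]), ci_high = exp(bq[2, ]))
  }

  rhat <- c(alpha = split_rhat(draws$alpha, draws$chain),
            log_tau_u = split_rhat(log(draws$tau_u), draws$chain),
            log_tau_v = split_rhat(log(draws$tau_v), draws$chain))
  if (any(is.finite(rhat) & rhat > 1.1)) {
    warning("split-chain R-hat above 1.1 for: ",
            paste(names(rhat)[is.finite(rhat) & rhat > 1.1], collapse = ", "),
            "; consider longer chains.", call. = FALSE)
  }
  accept <- colMeans(do.call(rbind, lapply(chains, `[[`, "accept")))

  fit <- structure(list(
    area_id = ids, O = sir$O, E = sir$E, family = family,
    draws = draws, summary = summary,
    covariate_summary = covariate_summary,
    diagnostics = list(accept = accept, rhat = rhat),
    priors = priors, mcmc = mcmc, pinned = pinned), class = "bym_fit")
  fit$dic <- compute_dic(fit)
  fit
}

#' Fit the zero-inflated Poisson BYM alternative
#'
#' Same hierarchy as [fit_bym()] but with observation model
#' `O_i ~ pi * delta_0 + (1 - pi) * Poisson(E_i * theta_i)`: a global
#' structural-zero probability `pi` with a Beta prior, sampled by data
#' augmentation of per-area zero indicators. When the data carry no
#' structural zeros the posterior of `pi` concentrates near 0 and the fit
#' reduces to the Poisson model.
#'
#' @inheritParams fit_bym
#' @return A `bym_fit` with `family = "zip"`; posterior draws of `pi` are in
#'   `$draws$pi`.
#' @export
fit_zip_bym <- function(sir, adjacency, priors = prior_spec(),
                        mcmc = mcmc_control()) {
  fit_bym(sir, adjacency, priors = priors, mcmc = mcmc, family = "zip")
}

#' @export
print.bym_fit <- function(x, ...) {
  cat(sprintf("<bym_fit> %s likelihood, %d areas, %d retained draws\n",
              x$family, length(x$area_id), length(x$draws$alpha)))
  cat(sprintf("  DIC %.1f (pD %.1f); structured variance fraction %.2f\n",
              x$dic$dic, x$dic$pD, variance_fraction(x)))
  invisible(x)
}

#' Posterior probability of an elevated smoothed SIR
#'
#' `PP_i = Pr(theta_i > 1 | data)`, estimated as the fraction of retained
#' draws with `theta_i > 1`.
#'
#' @param fit A `bym_fit` with at least 100 retained draws.
#' @return Named numeric vector of per-area posterior probabilities.
#' @export
posterior_pp <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  if (length(fit$draws$alpha) < 100L) {
    stop("at least 100 retained draws are needed for PP estimation.",
         call. = FALSE)
  }
  colMeans(fit$draws$theta > 1)
}

#' Structured share of the random-effect variance
#'
#' For each retained draw, the empirical variance of the structured effects
#' divided by the total empirical random-effect variance,
#' `var(u) / (var(u) + var(v))`; the posterior mean of this ratio is
#' returned. This empirical-variance convention measures how much of the
#' realised between-area variability is spatially structured.
#'
#' @param fit A `bym_fit`.
#' @return Scalar in `[0, 1]`.
#' @export
variance_fraction <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  vu <- apply(fit$draws$u, 1, stats::var)
  vv <- apply(fit$draws$v, 1, stats::var)
  mean(vu / (vu + vv))
}

#' Deviance information criterion
#'
#' `DIC = mean deviance + pD` with `pD = mean deviance - deviance at the
#' posterior mean parameters` (plug-in: posterior mean `theta_i`, and
#' posterior mean `pi` for the zero-inflated family). Lower is better.
#'
#' @param fit A `bym_fit` (Poisson or zero-inflated).
#' @return List with `dic`, `pD` and `mean_deviance`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  dbar <- mean(fit$draws$deviance)
  theta_hat <- colMeans(fit$draws$theta)
  mu <- fit$E * theta_hat
  if (fit$family == "zip") {
    pi_hat <- mean(fit$draws$pi)
    lik <- ifelse(fit$O == 0, pi_hat, 0) +
      (1 - pi_hat) * stats::dpois(fit$O, mu)
    dhat <- sum(-2 * log(pmax(lik, 1e-300)))
  } else {
    dhat <- sum(-2 * stats::dpois(fit$O, mu, log = TRUE))
  }
  pD <- dbar - dhat
  list(dic = dbar + pD, pD = pD, mean_deviance = dbar)
}

# Split-chain R-hat (each chain halved) for a vector of pooled draws.
split_rhat <- function(x, chain) {
  halves <- lapply(split(x, chain), function(xc) {
    m <- length(xc) %/% 2L
    list(xc[seq_len(m)], xc[m + seq_len(m)])
  })
  parts <- unlist(halves, recursive = FALSE)
  m <- length(parts); n <- length(parts[[1]])
  if (n < 2L || m < 2L) return(NA_real_)
  means <- vapply(parts, mean, numeric(1))
  vars <- vapply(parts, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
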