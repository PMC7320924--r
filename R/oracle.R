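#' Brute-force reference posterior for tiny BYM problems
#'
#' Computes posterior means of the smoothed SIRs `theta_i` for the same
#' hierarchy as [fit_bym()] by self-normalised importance sampling, entirely
#' independently of the MCMC code path: the two precision parameters are
#' integrated out analytically (Gamma priors are conjugate to the Gaussian
#' field given the quadratic forms), the sum-to-zero constraint is imposed by
#' parametrising `u` on the `n - 1` free coordinates, the marginal posterior
#' over `(alpha, u, v)` is maximised numerically, and draws come from a
#' two-component multivariate-t mixture around the mode (one component at the
#' Laplace scale, one inflated) so both the near-zero prior ridge and the
#' likelihood tails are covered. Intended for graphs with at most ~6 areas,
#' where the `2n`-dimensional integral is well within reach of importance
#' sampling; used as an independent correctness check on the MCMC.
#'
#' @param sir Tibble with `O`, `E` (all `E > 0`).
#' @param adjacency Named neighbour list (connected graph).
#' @param priors A [prior_spec()].
#' @param n_samples Importance-sample size.
#' @param seed Integer seed.
#' @return List with `theta_mean` (posterior mean per area), `pp`
#'   (`Pr(theta > 1)`), `alpha_mean` and `ess` (effective sample size of the
#'   importance weights; should be at least a few thousand for trust).
#' @export
bym_reference_posterior <- function(sir, adjacency, priors = prior_spec(),
                                    n_samples = 2e5, seed = 1L) {
  stopifnot(all(sir$E > 0))
  ids <- sir$area_id
  n <- length(ids)
  if (n > 8) stop("reference oracle is for tiny graphs (n <= 8).", call. = FALSE)
  nb <- adjacency_index(adjacency, ids)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, nb[[i]]] <- 1
  Q <- diag(rowSums(W)) - W
  O <- as.numeric(sir$O); E <- as.numeric(sir$E)
  a_u <- priors$tau_u[1]; b_u <- priors$tau_u[2]
  a_v <- priors$tau_v[1]; b_v <- priors$tau_v[2]
  k_u <- n - 1  # ICAR rank on a connected graph

  # phi = (alpha, u_free[1..n-1], v[1..n]); u_n = -sum(u_free)
  expand_u <- function(uf) c(uf, -sum(uf))
  log_post <- function(phi) {
    alpha <- phi[1]
    u <- expand_u(phi[2:n])
    v <- phi[(n + 1):(2 * n)]
    eta <- alpha + u + v
    ll <- sum(O * eta - E * exp(eta))
    Su <- drop(u %*% Q %*% u)
    Sv <- sum(v^2)
    ll - (a_u + k_u / 2) * log(b_u + Su / 2) - (a_v + n / 2) * log(b_v + Sv / 2)
  }

  d <- 2 * n
  opt <- stats::optim(rep(0, d), function(p) -log_post(p), method = "BFGS",
                      control = list(maxit = 500))
  mode <- opt$par
  H <- stats::optimHess(mode, function(p) -log_post(p))
  # regularise and factor the Laplace covariance
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, max(ev$values) * 1e-8)
  L <- ev$vectors %*% diag(1 / sqrt(lam))  # maps z -> scaled directions

  df <- 4
  scales <- c(1, 3)
  mix_w <- c(0.6, 0.4)
  withr_seed(seed, {
    comp <- sample.int(2, n_samples, replace = TRUE, prob = mix_w)
    Z <- matrix(stats::rnorm(n_samples * d), n_samples, d)
    g <- stats::rchisq(n_samples, df) / df
    Td <- Z / sqrt(g)  # standard t draws
  })
  draws <- Td %*% t(L) * scales[comp]
  draws <- sweep(draws, 2, mode, "+")

  # mixture proposal log-density (multivariate t with scale matrix s^2 * Sigma)
  Li <- diag(sqrt(lam)) %*% t(ev$vectors)  # Sigma^{-1/2}
  zstd <- draws
  zstd <- sweep(zstd, 2, mode, "-") %*% t(Li)
  r2 <- rowSums(zstd^2)
  ld_half <- -0.5 * sum(log(1 / lam))  # -0.5 log|Sigma|
  lt_dens <- function(s) {
    lgamma((df + d) / 2) - lgamma(df / 2) - (d / 2) * log(df * pi) +
      ld_half - d * log(s) - ((df + d) / 2) * log1p(r2 / (s^2 * df))
  }
  lq <- matrixStats_logsumexp(cbind(log(mix_w[1]) + lt_dens(scales[1]),
                                    log(mix_w[2]) + lt_dens(scales[2])))

  lp <- apply(draws, 1, log_post)
  lw <- lp - lq
  lw <- lw - max(lw)
  w <- exp(lw)
  w <- w / sum(w)
  ess <- 1 / sum(w^2)

  theta <- exp(draws[, 1] + cbind(draws[, 2:n], -rowSums(draws[, 2:n, drop = FALSE])) +
                 draws[, (n + 1):(2 * n)])
  list(theta_mean = stats::setNames(colSums(theta * w), ids),
       pp = stats::setNames(colSums((theta > 1) * w), ids),
       alpha_mean = sum(draws[, 1] * w),
       ess = ess)
}

# rowwise log-sum-exp for a two-column matrix
matrixStats_logsumexp <- function(m) {
  mx <- pmax(m[, 1], m[, 2])
  mx + log(exp(m[, 1] - mx) + exp(m[, 2] - mx))
}
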