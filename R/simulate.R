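#' Risk-model parameters for the case simulator
#'
#' Bundles the generative model the simulator shares with the smoothing
#' model: stratum baseline rates, per-stage deprivation-quintile log relative
#' risks (Q1 reference fixed at 0), a global log-offset `alpha`, and the
#' precisions of the spatially structured (`tau_u`, intrinsic CAR) and
#' unstructured (`tau_v`, i.i.d. Gaussian) log-relative-risk fields.
#'
#' Default quintile effects mirror the wealth gradient reported for melanoma
#' (strong for stage I, marginal for stage II, absent for stage III-IV); the
#' default precisions make the structured field dominate the unstructured
#' one, as observed in practice.
#'
#' @param baseline Rate table from [baseline_rates()].
#' @param quintile_log_effects Named list (by stage) of length-5 vectors of
#'   log relative risks for Q1..Q5; first element must be 0.
#' @param alpha Named numeric: per-stage global log-offset.
#' @param tau_u,tau_v Named numeric: per-stage precisions (> 0).
#'
#' @return Object of class `risk_params`.
#' @export
risk_params <- function(baseline = baseline_rates(),
                        quintile_log_effects = list(
                          "I" = c(0, 0.10, 0.10, 0.17, 0.30),
                          "II" = c(0, 0.01, 0.01, 0.02, 0.04),
                          "III-IV" = c(0, 0, 0, 0, 0)),
                        alpha = c("I" = 0, "II" = 0, "III-IV" = 0),
                        tau_u = c("I" = 50, "II" = 50, "III-IV" = 50),
                        tau_v = c("I" = 150, "II" = 150, "III-IV" = 150)) {
  stages <- stage_levels()
  stopifnot(all(stages %in% names(quintile_log_effects)),
            all(stages %in% names(alpha)),
            all(stages %in% names(tau_u)), all(stages %in% names(tau_v)),
            all(baseline$rate >= 0))
  for (s in stages) {
    q <- quintile_log_effects[[s]]
    if (length(q) != 5L || q[[1]] != 0) {
      stop("quintile effects must have length 5 with the Q1 reference fixed at 0.",
           call. = FALSE)
    }
  }
  if (any(tau_u[stages] <= 0) || any(tau_v[stages] <= 0)) {
    stop("precisions must be positive.", call. = FALSE)
  }
  structure(list(baseline = baseline,
                 quintile_log_effects = quintile_log_effects,
                 alpha = alpha, tau_u = tau_u, tau_v = tau_v),
            class = "risk_params")
}

#' Simulate an intrinsic CAR (ICAR) field on a connected graph
#'
#' Draws one realisation of the sum-to-zero constrained Gaussian with
#' generalised precision `tau * (D - W)` by eigen-decomposing the graph
#' Laplacian and sampling independently on its non-null eigenspace
#' (variance `1/(tau * lambda_j)` along eigenvector `j`). This is the
#' standard simulation convention for the intrinsic model; the null
#' (constant) direction carries no mass, so the draw sums to zero exactly.
#'
#' @param adjacency Named neighbour list (as in a `geography` object).
#' @param tau Precision (> 0).
#' @return Named numeric vector (one value per area) summing to zero.
#' @export
simulate_icar <- function(adjacency, tau) {
  stopifnot(tau > 0)
  ids <- names(adjacency)
  nb <- adjacency_index(adjacency, ids)
  if (max(graph_components(nb)) != 1L) {
    stop("ICAR simulation requires a connected adjacency graph.", call. = FALSE)
  }
  n <- length(ids)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, nb[[i]]] <- 1
  Q <- diag(rowSums(W)) - W
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  z <- stats::rnorm(sum(pos))
  u <- e$vectors[, pos, drop = FALSE] %*% (z / sqrt(tau * e$values[pos]))
  stats::setNames(drop(u) - mean(u), ids)
}

#' Simulate stage-specific case data
#'
#' The generative mirror of the BYM smoothing model. For each stage a
#' structured field `u ~ ICAR(tau_u)` (sum-to-zero) and an unstructured field
#' `v_i ~ N(0, 1/tau_v)` are drawn on the geography; stratum counts are then
#' Poisson with mean
#' `person_years * baseline_rate(sex, age, stage) * exp(alpha + quintile_effect + u_i + v_i)`
#' and expanded into one row per case.
#'
#' @param pop Population table from [generate_population()].
#' @param geo Geography whose areas cover all areas in `pop`.
#' @param params A [risk_params()] object.
#' @param seed Integer seed (whole simulation reproducible for a fixed seed).
#'
#' @return Tibble with columns `case_id`, `area_id`, `sex`, `age_group`,
#'   `year`, `stage`. The drawn fields are attached as attribute `fields`
#'   (per-stage list with `u` and `v`) for simulation studies.
#' @export
simulate_cases <- function(pop, geo, params = risk_params(), seed = 1L) {
  stopifnot(inherits(params, "risk_params"))
  ids <- geo$areas$area_id
  missing <- setdiff(unique(pop$area_id), ids)
  if (length(missing) > 0L) {
    stop("population areas missing from geography: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  quint <- stats::setNames(as.character(geo$areas$quintile), ids)
  qnum <- as.integer(substring(quint, 2))

  base <- params$baseline
  withr_seed(seed, {
    out <- vector("list", length(stage_levels()))
    fields <- list()
    for (si in seq_along(stage_levels())) {
      s <- stage_levels()[[si]]
      u <- simulate_icar(geo$adjacency, params$tau_u[[s]])
      v <- stats::rnorm(length(ids), 0, 1 / sqrt(params$tau_v[[s]]))
      names(v) <- ids
      fields[[s]] <- list(u = u, v = v)

      b <- base[base$stage == s, c("sex", "age_group", "rate")]
      tab <- dplyr::inner_join(pop, b, by = c("sex", "age_group"))
      ai <- match(tab$area_id, ids)
      qeff <- params$quintile_log_effects[[s]][qnum[ai]]
      qeff[is.na(qeff)] <- 0  # tiny geographies carry no quintile labels
      eta <- params$alpha[[s]] + qeff + u[ai] + v[ai]
      mu <- tab$person_years * tab$rate * exp(eta)
      cnt <- stats::rpois(nrow(tab), mu)
      keep <- cnt > 0L
      if (!any(keep)) { out[[si]] <- NULL; next }
      rows <- tab[rep(which(keep), cnt[keep]),
                  c("area_id", "sex", "age_group", "year")]
      rows$stage <- s
      out[[si]] <- rows
    }
  })
  cases <- dplyr::bind_rows(out)
  if (nrow(cases) == 0L) {
    cases <- tibble::tibble(area_id = character(), sex = character(),
                            age_group = factor(character(), levels = age_bands()),
                            year = integer(), stage = character())
  }
  cases$stage <- factor(cases$stage, levels = stage_levels())
  cases <- tibble::as_tibble(cases)
  cases <- cases[order(cases$area_id, cases$year, cases$stage), ]
  cases <- tibble::add_column(cases,
    case_id = sprintf("C%06d", seq_len(nrow(cases))), .before = 1)
  attr(cases, "fields") <- fields
  cases
}

#' Recode raw tumour measurements into stage at diagnosis
#'
#' Collapses the melanoma staging rules used in the analysis: any nodal or
#' distant spread is stage III-IV; otherwise a Breslow thickness of at most
#' 1.0 mm is stage I, a 1.1-2.0 mm tumour is stage I without ulceration and
#' stage II with it, and anything thicker than 2.0 mm is stage II.
#'
#' @param breslow_mm Breslow thickness in millimetres (may be `NA` when
#'   `nodal_or_distant` is `TRUE`).
#' @param ulceration Logical, tumour ulceration present.
#' @param nodal_or_distant Logical, regional nodal or distant spread.
#' @param on_unstageable `"error"` (default) to fail on a missing thickness
#'   without nodal/distant spread; `"na"` to return `NA` for such cases so
#'   callers can tally exclusions.
#'
#' @return Character vector of stages in `c("I", "II", "III-IV")`.
#' @export
recode_stage <- function(breslow_mm, ulceration, nodal_or_distant,
                         on_unstageable = c("error", "na")) {
  on_unstageable <- match.arg(on_unstageable)
  n <- max(length(breslow_mm), length(ulceration), length(nodal_or_distant))
  breslow_mm <- rep_len(breslow_mm, n)
  ulceration <- rep_len(as.logical(ulceration), n)
  nodal_or_distant <- rep_len(as.logical(nodal_or_distant), n)

  out <- rep(NA_character_, n)
  out[nodal_or_distant %in% TRUE] <- "III-IV"
  local <- !(nodal_or_distant %in% TRUE)
  bad <- local & (is.na(breslow_mm) | breslow_mm <= 0)
  if (any(bad)) {
    if (on_unstageable == "error") {
      stop(sum(bad), " case(s) unstageable: missing or non-positive Breslow ",
           "thickness without nodal/distant spread.", call. = FALSE)
    }
  }
  ok <- local & !bad
  out[ok & breslow_mm <= 1.0] <- "I"
  mid <- ok & breslow_mm > 1.0 & breslow_mm <= 2.0
  out[mid & !ulceration] <- "I"
  out[mid & ulceration] <- "II"
  out[ok & breslow_mm > 2.0] <- "II"
  out
}
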