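#' Ecological regression of smoothed incidence on deprivation quintile
#'
#' Weighted least squares of `ln(smoothed SIR)` on deprivation quintile as a
#' categorical variable (Q1 reference), with inverse posterior variances of
#' `ln(theta_i)` as weights. Exponentiated coefficients estimate the ratio
#' between average-level incidences in each quintile relative to Q1; Wald
#' 95% confidence intervals are reported. Rescaling all weights by a
#' constant leaves the fit unchanged.
#'
#' @param smoothed_sir Named numeric vector of smoothed SIRs (names = area
#'   ids), or a `bym_fit` (in which case `var_log_sir` defaults to the
#'   posterior variance of `ln(theta_i)` from the retained draws).
#' @param quintile Per-area quintile labels (`Q1`..`Q5`), named by area id or
#'   aligned with `smoothed_sir`.
#' @param var_log_sir Positive per-area variances of `ln(theta_i)` used as
#'   inverse weights. The plug-in is exposed so alternative variance
#'   estimates can be supplied.
#' @return Object of class `eco_reg`: tibble with one row per quintile
#'   (`ratio`, `ci_low`, `ci_high`; Q1 fixed at 1) plus attributes
#'   `n_areas` and `sigma` (weighted residual standard deviation).
#' @export
ecological_regression <- function(smoothed_sir, quintile, var_log_sir = NULL) {
  if (inherits(smoothed_sir, "bym_fit")) {
    fit <- smoothed_sir
    if (is.null(var_log_sir)) {
      var_log_sir <- apply(log(fit$draws$theta), 2, stats::var)
    }
    smoothed_sir <- stats::setNames(fit$summary$smoothed_sir, fit$area_id)
  }
  if (is.null(var_log_sir)) {
    stop("`var_log_sir` is required when `smoothed_sir` is a plain vector.",
         call. = FALSE)
  }
  ids <- names(smoothed_sir)
  if (!is.null(ids) && !is.null(names(quintile))) quintile <- quintile[ids]
  if (!is.null(ids) && !is.null(names(var_log_sir))) var_log_sir <- var_log_sir[ids]
  q <- factor(as.character(quintile), levels = paste0("Q", 1:5))
  stopifnot(length(q) == length(smoothed_sir),
            length(var_log_sir) == length(smoothed_sir))
  if (anyNA(q)) stop("missing or unknown quintile labels.", call. = FALSE)
  if (any(!is.finite(var_log_sir) | var_log_sir <= 0)) {
    stop("`var_log_sir` must be positive and finite.", call. = FALSE)
  }
  tab <- table(q)
  if (any(tab < 2L)) {
    stop("quintile(s) with fewer than 2 areas: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  }

  d <- data.frame(y = log(smoothed_sir), q = q, w = 1 / var_log_sir)
  fit_lm <- stats::lm(y ~ q, data = d, weights = w)
  cf <- summary(fit_lm)$coefficients
  idx <- paste0("qQ", 2:5)
  est <- unname(cf[idx, "Estimate"])
  se <- unname(cf[idx, "Std. Error"])
  out <- tibble::tibble(
    quintile = factor(paste0("Q", 1:5), levels = paste0("Q", 1:5)),
    ratio = c(1, exp(est)),
    ci_low = c(1, exp(est - 1.96 * se)),
    ci_high = c(1, exp(est + 1.96 * se)))
  attr(out, "n_areas") <- nrow(d)
  attr(out, "sigma") <- summary(fit_lm)$sigma
  class(out) <- c("eco_reg", class(out))
  out
}

#' Case-level logistic regression of late-stage odds
#'
#' Multivariable logistic regression (maximum likelihood via iteratively
#' reweighted least squares, as implemented in [stats::glm()]) of the odds
#' that a case is late-stage on age group, sex and residential deprivation
#' quintile. Reference levels follow the tabulation convention: age 30-34,
#' female, and the wealthiest quintile Q5. Wald 95% confidence intervals.
#'
#' @param cases Case table with `age_group`, `sex`, `stage` and either a
#'   `quintile` column or an `area_id` column plus a named `quintile` map.
#' @param late Late-stage definition: `"II-IV"` (default) or `"III-IV"`.
#' @param quintile Optional named map from area id to quintile label, used
#'   when `cases` has no `quintile` column.
#' @param scope Optional area ids restricting the analysis (e.g. one urban
#'   area); quintiles should already be computed within that scope.
#' @param covariates Model terms, any subset of
#'   `c("age_group", "sex", "quintile")`.
#'
#' @return Tibble with one row per term level: `term`, `level`, `or`,
#'   `ci_low`, `ci_high` (reference levels have `or = 1` and `NA`
#'   intervals). Attribute `late_definition` records the outcome used.
#' @export
late_stage_logistic <- function(cases, late = c("II-IV", "III-IV"),
                                quintile = NULL, scope = NULL,
                                covariates = c("age_group", "sex", "quintile")) {
  late <- match.arg(late)
  covariates <- match.arg(covariates, several.ok = TRUE)
  d <- as.data.frame(cases)
  if (!is.null(scope)) d <- d[d$area_id %in% scope, ]
  if (!"quintile" %in% names(d)) {
    if (is.null(quintile)) {
      if ("quintile" %in% covariates) {
        stop("supply a `quintile` column or a named area -> quintile map.",
             call. = FALSE)
      }
    } else {
      d$quintile <- quintile[d$area_id]
    }
  }
  if (anyNA(d$stage)) stop("every case must be staged.", call. = FALSE)
  d$late <- if (late == "II-IV") d$stage %in% c("II", "III-IV")
            else d$stage %in% "III-IV"
  d$age_group <- factor(as.character(d$age_group), levels = age_bands())
  d$sex <- factor(d$sex, levels = c("F", "M"))
  if ("quintile" %in% covariates) {
    d$quintile <- factor(as.character(d$quintile),
                         levels = paste0("Q", 5:1))  # Q5 reference
  }
  for (v in covariates) {
    d[[v]] <- droplevels(d[[v]])
    lev1 <- levels(d[[v]])[1]
    if (sum(d[[v]] == lev1, na.rm = TRUE) < 1L) {
      stop("no cases at the reference level of ", v, ".", call. = FALSE)
    }
  }

  form <- stats::reformulate(covariates, response = "late")
  fit <- withCallingHandlers(
    stats::glm(form, data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("complete or quasi-complete separation detected; merge sparse ",
             "levels or use a coarser grouping.", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) {
    stop("logistic regression did not converge.", call. = FALSE)
  }
  eps <- 1e-8
  if (any(stats::fitted(fit) < eps) || any(stats::fitted(fit) > 1 - eps)) {
    stop("complete or quasi-complete separation detected; merge sparse ",
         "levels or use a coarser grouping.", call. = FALSE)
  }

  cf <- summary(fit)$coefficients
  rows <- list()
  for (v in covariates) {
    levs <- levels(d[[v]])
    nm <- paste0(v, levs)
    est <- se <- rep(NA_real_, length(levs))
    hit <- nm %in% rownames(cf)
    est[hit] <- cf[nm[hit], "Estimate"]
    se[hit] <- cf[nm[hit], "Std. Error"]
    rows[[v]] <- tibble::tibble(
      term = v, level = levs,
      or = ifelse(hit, exp(est), 1),
      ci_low = exp(est - 1.96 * se),
      ci_high = exp(est + 1.96 * se))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "late_definition") <- late
  attr(out, "n_cases") <- nrow(d)
  out
}
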