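#' Five-class posterior-probability signal classification
#'
#' Converts per-area posterior probabilities `PP = Pr(SIR > 1 | data)` into
#' the five signal classes used on the maps. With the default cut-offs:
#' * `PP > 0.90`: strong elevated signal (red);
#' * `0.80 < PP <= 0.90`: moderate elevated signal (light red);
#' * `0.20 < PP <= 0.80`: neutral (yellow);
#' * `0.10 < PP <= 0.20`: moderate lowered signal (light green);
#' * `PP <= 0.10`: strong lowered signal (green).
#'
#' Boundary values belong to the lower class on each side (a PP of exactly
#' 0.90 is a moderate, not a strong, signal).
#'
#' @param pp Numeric vector (optionally named by area) of posterior
#'   probabilities in `[0, 1]`, or a `bym_fit`.
#' @param cutoffs Decreasing vector of the four cut-offs.
#' @return Tibble with `area_id`, `pp`, `class` (factor) and `colour`.
#' @export
classify_signals <- function(pp, cutoffs = c(0.90, 0.80, 0.20, 0.10)) {
  if (inherits(pp, "bym_fit")) pp <- posterior_pp(pp)
  stopifnot(length(cutoffs) == 4L, !is.unsorted(rev(cutoffs), strictly = TRUE))
  if (any(!is.finite(pp)) || any(pp < 0 | pp > 1)) {
    stop("posterior probabilities must lie in [0, 1].", call. = FALSE)
  }
  ids <- names(pp)
  if (is.null(ids)) ids <- sprintf("%06d", seq_along(pp))
  classes <- c("strong_elevated", "moderate_elevated", "neutral",
               "moderate_lowered", "strong_lowered")
  cls <- classes[5L - findInterval(pp, rev(cutoffs), left.open = TRUE)]
  tibble::tibble(
    area_id = ids,
    pp = unname(pp),
    class = factor(cls, levels = classes),
    colour = signal_colours()[cls])
}

#' Signal class colours
#'
#' Default map colours (hex) for the five signal classes.
#' @return Named character vector.
#' @export
signal_colours <- function() {
  c(strong_elevated = "#d73027", moderate_elevated = "#fc8d59",
    neutral = "#ffffbf", moderate_lowered = "#91cf60",
    strong_lowered = "#1a9850")
}

#' Cross-stage concordance of signals and smoothed SIRs
#'
#' Among areas signalling an elevated (`PP > threshold_hi`) or lowered
#' (`PP < threshold_lo`) incidence for one stage, counts how many show a
#' smoothed SIR above (elevated) or below (lowered) 1 for another stage.
#' The signal thresholds default to the combined strong + moderate bands
#' (0.80 / 0.20) and are exposed because the choice of band is a free
#' parameter of the comparison.
#'
#' @param signals_a [classify_signals()] output (or a tibble with `area_id`
#'   and `pp`) for the signalling stage.
#' @param sir_b Named numeric vector of smoothed SIRs (names = area ids), or
#'   a `bym_fit`, for the comparison stage; must cover the same areas.
#' @param direction `"elevated"` or `"lowered"`.
#' @param threshold_hi,threshold_lo PP thresholds defining the signalling
#'   sets.
#' @return List with `n_signalling`, `n_concordant` and `fraction`
#'   (`NA` with a warning when no area signals).
#' @export
concordance <- function(signals_a, sir_b, direction = c("elevated", "lowered"),
                        threshold_hi = 0.80, threshold_lo = 0.20) {
  direction <- match.arg(direction)
  if (inherits(sir_b, "bym_fit")) {
    sir_b <- stats::setNames(sir_b$summary$smoothed_sir, sir_b$summary$area_id)
  }
  missing <- setdiff(signals_a$area_id, names(sir_b))
  if (length(missing) > 0L) {
    stop("areas missing from `sir_b`: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sel <- if (direction == "elevated") signals_a$pp > threshold_hi
         else signals_a$pp < threshold_lo
  n_sig <- sum(sel)
  if (n_sig == 0L) {
    warning("no area signals in the requested direction; fraction undefined.",
            call. = FALSE)
    return(list(n_signalling = 0L, n_concordant = 0L, fraction = NA_real_))
  }
  sirs <- sir_b[signals_a$area_id[sel]]
  n_con <- if (direction == "elevated") sum(sirs > 1) else sum(sirs < 1)
  list(n_signalling = n_sig, n_concordant = as.integer(n_con),
       fraction = n_con / n_sig)
}
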