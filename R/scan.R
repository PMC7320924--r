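#' Purely spatial Poisson scan statistic
#'
#' Kulldorff-style cluster detection on small-area observed/expected counts.
#' Candidate zones are circular windows: for every area, the areas ordered by
#' centroid distance are accumulated until the window holds `max_fraction` of
#' the total expected count. Each zone's log-likelihood ratio is
#' `O_in * ln(O_in / E_in) + O_out * ln(O_out / E_out)` when the inside rate
#' exceeds the outside rate and 0 otherwise (counts conditioned on the
#' observed total, so `E` is rescaled to sum to `sum(O)`). Significance is
#' assessed by Monte Carlo: the observed maximum LLR is ranked among maxima
#' from `n_sim` multinomial redistributions of the total count with
#' probabilities proportional to `E`.
#'
#' @param sir Tibble for one stage with `area_id`, `O`, `E` (all `E > 0`).
#' @param centroids Two-column matrix or data frame of planar coordinates
#'   (rows named by or aligned with `sir$area_id`), or a `geography` object.
#' @param max_fraction Maximum share of total expected count in a window,
#'   in `(0, 0.5]`.
#' @param n_sim Monte Carlo replicates (at least 19).
#' @param seed Integer seed.
#' @param max_clusters Maximum number of non-overlapping clusters reported.
#'
#' @return Object of class `scan_result`: tibble of clusters ordered by
#'   decreasing LLR with `members` (list of area ids), `n_areas`, `O_in`,
#'   `E_in`, `rr_in` (relative risk inside vs outside) and `llr`; the
#'   Monte Carlo `p_value` (computed against the null distribution of the
#'   maximum LLR) is attached per cluster.
#' @export
kulldorff_scan <- function(sir, centroids, max_fraction = 0.5, n_sim = 999,
                           seed = 1L, max_clusters = 5L) {
  stopifnot(all(c("area_id", "O", "E") %in% names(sir)))
  if (!(max_fraction > 0 && max_fraction <= 0.5)) {
    stop("`max_fraction` must be in (0, 0.5].", call. = FALSE)
  }
  if (n_sim < 19L) {
    stop("`n_sim` must be at least 19 for any p-value resolution.",
         call. = FALSE)
  }
  if (any(sir$E <= 0)) stop("all scanned areas need E > 0.", call. = FALSE)
  ids <- sir$area_id
  n <- length(ids)
  if (inherits(centroids, "geography")) {
    xy <- as.matrix(centroids$areas[match(ids, centroids$areas$area_id),
                                    c("x", "y")])
  } else {
    xy <- as.matrix(centroids)
    if (!is.null(rownames(xy))) xy <- xy[ids, , drop = FALSE]
  }
  stopifnot(nrow(xy) == n, ncol(xy) == 2L, !anyNA(xy))

  O <- as.numeric(sir$O)
  tot_O <- sum(O)
  E <- as.numeric(sir$E) * tot_O / sum(sir$E)  # condition on total count
  tot_E <- tot_O

  # window memberships: per centre, distance-ordered areas up to max_fraction
  ord_mat <- vector("list", n)
  zone_sizes <- vector("list", n)
  seen <- new.env(hash = TRUE)
  for (i in seq_len(n)) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    ord <- order(d2, seq_len(n))
    cum_e <- cumsum(E[ord])
    k_max <- max(1L, sum(cum_e <= max_fraction * tot_E))
    ord <- ord[seq_len(k_max)]
    ord_mat[[i]] <- ord
    sizes <- integer(0)
    for (k in seq_len(k_max)) {
      key <- paste(sort(ord[seq_len(k)]), collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      sizes <- c(sizes, k)
    }
    zone_sizes[[i]] <- sizes
  }

  llr_vec <- function(o) {
    # max LLR over all zones plus per-zone LLRs for the observed data
    best <- 0
    res <- vector("list", n)
    for (i in seq_len(n)) {
      ord <- ord_mat[[i]]
      co <- cumsum(o[ord]); ce <- cumsum(E[ord])
      oi <- co[zone_sizes[[i]]]; ei <- ce[zone_sizes[[i]]]
      oo <- tot_O - oi; eo <- tot_E - ei
      ll <- ifelse(oi / ei > oo / eo,
                   ifelse(oi > 0, oi * log(oi / ei), 0) +
                     ifelse(oo > 0, oo * log(oo / eo), 0),
                   0)
      res[[i]] <- ll
      best <- max(best, ll, na.rm = TRUE)
    }
    list(best = best, per_zone = res)
  }

  obs <- llr_vec(O)

  withr_seed(seed, {
    null_max <- vapply(seq_len(n_sim), function(s) {
      o_sim <- as.numeric(stats::rmultinom(1, tot_O, prob = E))
      llr_vec(o_sim)$best
    }, numeric(1))
  })

  # rank zones, report greedily non-overlapping clusters
  zones <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(centre = i, k = zone_sizes[[i]], llr = obs$per_zone[[i]])
  }))
  zones <- zones[order(-zones[, "llr"]), , drop = FALSE]
  taken <- logical(n)
  clusters <- list()
  for (r in seq_len(nrow(zones))) {
    if (length(clusters) >= max_clusters) break
    if (zones[r, "llr"] <= 0) break
    members <- ord_mat[[zones[r, "centre"]]][seq_len(zones[r, "k"])]
    if (any(taken[members])) next
    taken[members] <- TRUE
    oi <- sum(O[members]); ei <- sum(E[members])
    oo <- tot_O - oi; eo <- tot_E - ei
    n_members <- length(members)
    clusters[[length(clusters) + 1L]] <- tibble::tibble(
      members = list(ids[members]),
      n_areas = n_members,
      O_in = oi, E_in = ei,
      rr_in = (oi / ei) / ifelse(oo > 0, oo / eo, NA_real_),
      llr = zones[r, "llr"],
      p_value = (1 + sum(null_max >= zones[r, "llr"])) / (n_sim + 1))
  }
  out <- dplyr::bind_rows(clusters)
  attr(out, "null_max") <- null_max
  attr(out, "n_sim") <- n_sim
  class(out) <- c("scan_result", class(out))
  out
}

#' Overlap between scan clusters and PP signal sets
#'
#' Compares the membership of the top scan cluster (or all reported
#' clusters) with the set of areas signalling in the same direction on a
#' classified signal map (strong + moderate elevated classes by default),
#' returning the Jaccard index and the contingency counts.
#'
#' @param scan A [kulldorff_scan()] result.
#' @param signals A [classify_signals()] output.
#' @param classes Signal classes forming the comparison set.
#' @param top_only Use only the highest-LLR cluster (default) or the union
#'   of all reported clusters.
#' @return List with `jaccard`, `n_both`, `n_scan_only`, `n_signal_only`.
#' @export
compare_signal_sets <- function(scan, signals,
                                classes = c("strong_elevated",
                                            "moderate_elevated"),
                                top_only = TRUE) {
  scan_set <- if (nrow(scan) == 0L) character(0)
              else if (top_only) scan$members[[1]]
              else unique(unlist(scan$members))
  sig_set <- signals$area_id[signals$class %in% classes]
  n_both <- length(intersect(scan_set, sig_set))
  n_union <- length(union(scan_set, sig_set))
  list(jaccard = if (n_union == 0L) NA_real_ else n_both / n_union,
       n_both = n_both,
       n_scan_only = length(setdiff(scan_set, sig_set)),
       n_signal_only = length(setdiff(sig_set, scan_set)))
}
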