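#' Generate a rectangular lattice geography with rook adjacency
#'
#' Builds a synthetic small-area geography emulating Demographic Statistics
#' Areas (DSAs): a connected `n_rows` x `n_cols` lattice of unit-square areas
#' with rook (edge-sharing) adjacency, a log-normally distributed median
#' household income per area, and an optional smooth west-to-east income
#' gradient. Region-wide deprivation quintiles (Q1 = poorest fifth of areas,
#' Q5 = wealthiest) are attached via [assign_quintiles()].
#'
#' @param n_rows,n_cols Lattice dimensions; their product (the number of
#'   areas) must be at least 4.
#' @param income_spatial_trend Strength of the spatial income gradient, in log
#'   units across the full width of the lattice. `0` gives spatially
#'   unstructured incomes; the default `1` makes deprivation spatially
#'   clustered, as observed in real urban geographies.
#' @param seed Integer seed; the same seed reproduces the same geography.
#' @param income_meanlog,income_sdlog Location and scale of the log-normal
#'   income draw (currency units; defaults give a median around 220 with a
#'   realistic spread, before the spatial trend is added on the log scale).
#'
#' @return An object of class `geography`: a list with
#'   * `areas`: tibble with `area_id`, `row`, `col`, `x`, `y` (centroids),
#'     `median_income`, `quintile`;
#'   * `adjacency`: named list mapping each `area_id` to the character vector
#'     of its neighbours.
#' @export
generate_geography <- function(n_rows, n_cols, income_spatial_trend = 1,
                               seed = 1L,
                               income_meanlog = log(220), income_sdlog = 0.25) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      !is.finite(n_rows) || !is.finite(n_cols) ||
      n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop("`n_rows` and `n_cols` must be positive integers.", call. = FALSE)
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n <- n_rows * n_cols
  if (n < 4L) stop("the lattice must contain at least 4 areas.", call. = FALSE)

  idx <- seq_len(n)
  row <- ((idx - 1L) %/% n_cols) + 1L
  col <- ((idx - 1L) %% n_cols) + 1L
  area_id <- sprintf("A%04d", idx)

  withr_seed(seed, {
    z <- stats::rnorm(n, 0, income_sdlog)
  })
  trend <- if (n_cols > 1L) {
    income_spatial_trend * (col - 1) / (n_cols - 1)
  } else {
    rep(0, n)
  }
  income <- exp(income_meanlog + trend + z)

  adjacency <- lattice_adjacency(n_rows, n_cols, area_id)

  areas <- tibble::tibble(
    area_id = area_id,
    row = row, col = col,
    x = col - 0.5, y = row - 0.5,
    median_income = income
  )
  areas$quintile <- if (n >= 5L) {
    assign_quintiles(stats::setNames(income, area_id))
  } else {
    factor(rep(NA_character_, n), levels = paste0("Q", 1:5))
  }

  structure(list(areas = areas, adjacency = adjacency), class = "geography")
}

# Rook adjacency of an n_rows x n_cols lattice as a named list of area ids.
lattice_adjacency <- function(n_rows, n_cols, area_id) {
  n <- n_rows * n_cols
  at <- function(r, c) (r - 1L) * n_cols + c
  adj <- vector("list", n)
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      nb <- integer(0)
      if (r > 1L)      nb <- c(nb, at(r - 1L, c))
      if (r < n_rows)  nb <- c(nb, at(r + 1L, c))
      if (c > 1L)      nb <- c(nb, at(r, c - 1L))
      if (c < n_cols)  nb <- c(nb, at(r, c + 1L))
      adj[[at(r, c)]] <- area_id[nb]
    }
  }
  stats::setNames(adj, area_id)
}

#' @export
print.geography <- function(x, ...) {
  cat(sprintf("<geography> %d areas, %d adjacency edges\n",
              nrow(x$areas), sum(lengths(x$adjacency)) / 2))
  print(utils::head(x$areas, 5))
  invisible(x)
}

#' Assign deprivation quintiles within a scope
#'
#' Ranks areas by median income and splits them into five near-equal groups of
#' areas (unweighted by population): Q1 is the poorest fifth, Q5 the
#' wealthiest. Group `k` consists of ranks `ceiling((k-1) n / 5) + 1` through
#' `ceiling(k n / 5)`, so group sizes differ by at most one. Ties in income
#' are broken by ascending area id.
#'
#' @param incomes Named numeric vector of median incomes (names are area ids),
#'   or an unnamed vector (positional ids are then used for tie-breaking).
#' @param scope Optional character vector of area ids restricting the
#'   grouping scope (e.g. one urban subarea); quintiles are computed within
#'   the scope only. Defaults to all areas in `incomes`.
#'
#' @return A factor with levels `Q1`..`Q5`, aligned with `incomes` (entries
#'   outside `scope` are `NA`).
#' @export
assign_quintiles <- function(incomes, scope = NULL) {
  if (!is.numeric(incomes) || length(incomes) == 0L) {
    stop("`incomes` must be a non-empty numeric vector.", call. = FALSE)
  }
  ids <- names(incomes)
  if (is.null(ids)) ids <- sprintf("%06d", seq_along(incomes))
  if (anyDuplicated(ids)) stop("area ids in `incomes` must be unique.", call. = FALSE)
  if (is.null(scope)) scope <- ids
  missing_scope <- setdiff(scope, ids)
  if (length(missing_scope) > 0L) {
    stop("scope areas without an income value: ",
         paste(utils::head(missing_scope, 5), collapse = ", "), call. = FALSE)
  }
  in_scope <- ids %in% scope
  n <- sum(in_scope)
  if (n < 5L) stop("quintile assignment needs at least 5 areas in scope.", call. = FALSE)

  sub_ids <- ids[in_scope]
  sub_inc <- incomes[in_scope]
  ord <- order(sub_inc, sub_ids)
  breaks <- ceiling(seq_len(5L) * n / 5)
  grp <- findInterval(seq_len(n), c(0L, breaks), left.open = TRUE)
  labels <- paste0("Q", grp)
  out <- rep(NA_character_, length(incomes))
  names(out) <- ids
  tmp <- out[in_scope]
  tmp[ord] <- labels
  out[in_scope] <- tmp
  f <- factor(out, levels = paste0("Q", 1:5))
  names(f) <- ids
  f
}

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Adjacency list (names = area ids) -> integer neighbour index list for a
# given ordering of area ids; validates symmetry and irreflexivity.
adjacency_index <- function(adjacency, area_id) {
  missing <- setdiff(area_id, names(adjacency))
  if (length(missing) > 0L) {
    stop("areas missing from adjacency: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  pos <- stats::setNames(seq_along(area_id), area_id)
  out <- lapply(area_id, function(a) {
    nb <- adjacency[[a]]
    nb <- nb[nb %in% area_id]
    if (a %in% nb) stop("adjacency is reflexive at area ", a, call. = FALSE)
    unname(pos[nb])
  })
  for (i in seq_along(out)) {
    for (j in out[[i]]) {
      if (!(i %in% out[[j]])) {
        stop("adjacency is not symmetric between ", area_id[i], " and ",
             area_id[j], call. = FALSE)
      }
    }
  }
  stats::setNames(out, area_id)
}

# Connected components of an adjacency index list (integer labels).
graph_components <- function(nb) {
  n <- length(nb)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0L) {
      i <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[i] != 0L) next
      comp[i] <- cur
      stack <- c(stack, nb[[i]][comp[nb[[i]]] == 0L])
    }
  }
  comp
}
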