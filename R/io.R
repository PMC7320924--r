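#' Read and validate a case table
#'
#' Reads a CSV with columns `area_id`, `sex`, `age_group`, `year` and either
#' a `stage` column or the raw tumour fields `breslow_mm`, `ulceration`,
#' `nodal_or_distant` (in which case stage is derived with [recode_stage()]).
#' Cases that cannot be staged, and cases whose `area_id` is missing or not
#' in `known_areas`, are excluded and tallied rather than failing the read;
#' the tally is attached as attribute `exclusions` and reported in a message.
#'
#' @param path CSV path (or a data frame, taken as already parsed).
#' @param known_areas Optional character vector of valid area ids; cases
#'   outside it are excluded as ungeocodable.
#' @return Tibble of analytic cases with a factor `stage`; attribute
#'   `exclusions` is a named integer vector
#'   `c(retrieved, unstageable, ungeocodable, analytic)`.
#' @export
read_cases <- function(path, known_areas = NULL) {
  d <- if (is.data.frame(path)) tibble::as_tibble(path)
       else tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("area_id", "sex", "age_group", "year")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("case table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n_retrieved <- nrow(d)

  if (!"stage" %in% names(d)) {
    raw <- c("breslow_mm", "ulceration", "nodal_or_distant")
    if (!all(raw %in% names(d))) {
      stop("case table needs either a `stage` column or the raw tumour ",
           "fields ", paste(raw, collapse = ", "), ".", call. = FALSE)
    }
    d$stage <- recode_stage(d$breslow_mm, d$ulceration, d$nodal_or_distant,
                            on_unstageable = "na")
  }
  bad_stage <- !is.na(d$stage) & !(as.character(d$stage) %in% stage_levels())
  if (any(bad_stage)) {
    stop("unknown stage label(s) at row(s): ",
         paste(utils::head(which(bad_stage), 5), collapse = ", "),
         call. = FALSE)
  }
  unstageable <- is.na(d$stage)

  ungeo <- is.na(d$area_id) | d$area_id == ""
  if (!is.null(known_areas)) ungeo <- ungeo | !(d$area_id %in% known_areas)
  ungeo <- ungeo & !unstageable  # count each exclusion once

  bad_sex <- !(d$sex %in% c("M", "F"))
  if (any(bad_sex)) {
    stop("invalid sex at row(s): ",
         paste(utils::head(which(bad_sex), 5), collapse = ", "), call. = FALSE)
  }
  bad_age <- !(as.character(d$age_group) %in% age_bands())
  if (any(bad_age)) {
    stop("invalid age band at row(s): ",
         paste(utils::head(which(bad_age), 5), collapse = ", "), call. = FALSE)
  }

  keep <- !unstageable & !ungeo
  out <- d[keep, ]
  out$stage <- factor(as.character(out$stage), levels = stage_levels())
  out$age_group <- factor(as.character(out$age_group), levels = age_bands())
  excl <- c(retrieved = n_retrieved,
            unstageable = sum(unstageable),
            ungeocodable = sum(ungeo),
            analytic = sum(keep))
  attr(out, "exclusions") <- excl
  message(sprintf(
    "read_cases: %d retrieved; %d unstageable and %d ungeocodable excluded; %d analytic.",
    excl[["retrieved"]], excl[["unstageable"]], excl[["ungeocodable"]],
    excl[["analytic"]]))
  out
}

#' Read and validate a population table
#'
#' @param path CSV path (or data frame) with `area_id`, `sex`, `age_group`,
#'   `year`, `person_years`.
#' @return Validated tibble (all 13 age bands present per area-year,
#'   non-negative person-years, no duplicate strata).
#' @export
read_population <- function(path) {
  d <- if (is.data.frame(path)) tibble::as_tibble(path)
       else tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("area_id", "sex", "age_group", "year", "person_years")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("population table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(d$person_years < 0)) stop("negative person-years.", call. = FALSE)
  if (!all(as.character(d$age_group) %in% age_bands())) {
    stop("invalid age band label in population table.", call. = FALSE)
  }
  key <- paste(d$area_id, d$sex, d$age_group, d$year)
  if (anyDuplicated(key)) {
    stop("duplicate (area, sex, age, year) strata at row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "),
         call. = FALSE)
  }
  bands_per <- tapply(as.character(d$age_group),
                      paste(d$area_id, d$sex, d$year),
                      function(x) length(unique(x)))
  if (any(bands_per < 13L)) {
    stop("area-years with missing age bands: ",
         paste(utils::head(names(bands_per)[bands_per < 13L], 3),
               collapse = "; "), call. = FALSE)
  }
  d$age_group <- factor(as.character(d$age_group), levels = age_bands())
  d
}

#' Write a geography to GeoJSON plus an adjacency CSV
#'
#' Writes areas as a GeoJSON FeatureCollection (unit-square polygons for
#' lattice geographies, centroids retained as properties) with properties
#' `area_id`, `median_income`, `quintile`, and the adjacency as a two-column
#' edge CSV (`area_id`, `neighbour_id`, each undirected edge written once).
#'
#' @param geo A `geography`.
#' @param geojson_path,adjacency_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_geography <- function(geo, geojson_path, adjacency_path) {
  a <- geo$areas
  features <- lapply(seq_len(nrow(a)), function(i) {
    ring <- cbind(c(a$x[i] - 0.5, a$x[i] + 0.5, a$x[i] + 0.5,
                    a$x[i] - 0.5, a$x[i] - 0.5),
                  c(a$y[i] - 0.5, a$y[i] - 0.5, a$y[i] + 0.5,
                    a$y[i] + 0.5, a$y[i] - 0.5))
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(apply(ring, 1, as.list,
                                                  simplify = FALSE))),
         properties = list(area_id = a$area_id[i],
                           x = a$x[i], y = a$y[i],
                           median_income = a$median_income[i],
                           quintile = as.character(a$quintile[i])))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, geojson_path, auto_unbox = TRUE, digits = NA)

  edges <- do.call(rbind, lapply(names(geo$adjacency), function(id) {
    nb <- geo$adjacency[[id]]
    nb <- nb[nb > id]
    if (length(nb) == 0L) return(NULL)
    data.frame(area_id = id, neighbour_id = nb)
  }))
  if (is.null(edges)) edges <- data.frame(area_id = character(),
                                          neighbour_id = character())
  utils::write.csv(edges, adjacency_path, row.names = FALSE)
  invisible(c(geojson_path, adjacency_path))
}

#' Read a geography from GeoJSON plus an adjacency CSV
#'
#' @param geojson_path GeoJSON FeatureCollection with `area_id`,
#'   `median_income` (and optionally `quintile`, `x`, `y`) properties.
#' @param adjacency_path Two-column edge CSV.
#' @return A `geography` object (quintiles recomputed from income when the
#'   file carries none).
#' @export
read_geography <- function(geojson_path, adjacency_path) {
  fc <- jsonlite::read_json(geojson_path)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", geojson_path, call. = FALSE)
  }
  feats <- fc$features
  props <- lapply(feats, `[[`, "properties")
  get_xy <- function(f, p, coord) {
    if (!is.null(p[[coord]])) return(as.numeric(p[[coord]]))
    g <- f$geometry
    if (is.null(g)) stop("feature with malformed geometry.", call. = FALSE)
    pts <- if (g$type == "Point") list(g$coordinates) else
      if (g$type == "Polygon") g$coordinates[[1]] else
        stop("unsupported geometry type: ", g$type, call. = FALSE)
    k <- if (coord == "x") 1L else 2L
    mean(vapply(pts, function(q) as.numeric(q[[k]]), numeric(1)))
  }
  areas <- tibble::tibble(
    area_id = vapply(props, function(p) as.character(p$area_id), character(1)),
    x = mapply(get_xy, feats, props, MoreArgs = list(coord = "x")),
    y = mapply(get_xy, feats, props, MoreArgs = list(coord = "y")),
    median_income = vapply(props, function(p) as.numeric(p$median_income),
                           numeric(1)))
  if (anyDuplicated(areas$area_id)) {
    stop("duplicate area ids in GeoJSON.", call. = FALSE)
  }
  qp <- vapply(props, function(p)
    if (is.null(p$quintile)) NA_character_ else as.character(p$quintile),
    character(1))
  areas$quintile <- if (anyNA(qp)) {
    assign_quintiles(stats::setNames(areas$median_income, areas$area_id))
  } else factor(qp, levels = paste0("Q", 1:5))

  edges <- utils::read.csv(adjacency_path, stringsAsFactors = FALSE)
  stopifnot(ncol(edges) >= 2L)
  unknown <- setdiff(unique(c(edges[[1]], edges[[2]])), areas$area_id)
  if (length(unknown) > 0L) {
    stop("adjacency references unknown area id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  adjacency <- stats::setNames(
    vector("list", nrow(areas)), areas$area_id)
  for (i in seq_along(adjacency)) adjacency[[i]] <- character(0)
  for (r in seq_len(nrow(edges))) {
    a <- edges[[1]][r]; b <- edges[[2]][r]
    adjacency[[a]] <- union(adjacency[[a]], b)
    adjacency[[b]] <- union(adjacency[[b]], a)
  }
  structure(list(areas = areas, adjacency = adjacency), class = "geography")
}

#' Write a classified signal map as GeoJSON
#'
#' Joins signal classes and colours onto a geography and writes a
#' FeatureCollection whose properties carry `pp`, `class` and the hex
#' `colour` for direct choropleth rendering.
#'
#' @param signals [classify_signals()] output.
#' @param geo Matching `geography`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signal_geojson <- function(signals, geo, path) {
  a <- geo$areas
  s <- signals[match(a$area_id, signals$area_id), ]
  features <- lapply(seq_len(nrow(a)), function(i) {
    ring <- cbind(c(a$x[i] - 0.5, a$x[i] + 0.5, a$x[i] + 0.5,
                    a$x[i] - 0.5, a$x[i] - 0.5),
                  c(a$y[i] - 0.5, a$y[i] - 0.5, a$y[i] + 0.5,
                    a$y[i] + 0.5, a$y[i] - 0.5))
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(apply(ring, 1, as.list,
                                                  simplify = FALSE))),
         properties = list(area_id = a$area_id[i],
                           pp = s$pp[i],
                           class = as.character(s$class[i]),
                           colour = unname(s$colour[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory (created if absent).
#' @param stages Stages to map.
#' @param seed Master seed recorded in the manifest and used for simulation
#'   and MCMC.
#' @param mcmc An [mcmc_control()] (its seed is overridden by `seed`).
#' @param cutoffs Signal cut-offs for [classify_signals()].
#' @param simulate List of synthetic-data settings (`n_rows`, `n_cols`,
#'   `mean_area_pop`, `n_years`, plus optional [risk_params()] as `params`),
#'   or `NULL` to read `case_path` / `population_path` / `geojson_path` /
#'   `adjacency_path`.
#' @param case_path,population_path,geojson_path,adjacency_path Input files
#'   when not simulating.
#' @param comparison Comparison scope: `"regional"` (whole study area) or a
#'   character vector of area ids (e.g. an urban subarea).
#' @param std Standard-population weights for the time-trend rates.
#' @param scan_stage Stage on which to run the scan sensitivity comparison
#'   (`NULL` to skip).
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(out_dir, stages = stage_levels(), seed = 1L,
                       mcmc = mcmc_control(n_iter = 6000, burn_in = 3000,
                                           thin = 3, n_chains = 2),
                       cutoffs = c(0.90, 0.80, 0.20, 0.10),
                       simulate = list(n_rows = 10, n_cols = 20,
                                       mean_area_pop = 1600, n_years = 9),
                       case_path = NULL, population_path = NULL,
                       geojson_path = NULL, adjacency_path = NULL,
                       comparison = "regional", std = esp2013_weights(),
                       scan_stage = "I") {
  stopifnot(all(stages %in% stage_levels()))
  if (!is.null(cutoffs)) stopifnot(length(cutoffs) == 4L)
  if (is.null(simulate)) {
    paths <- c(case_path, population_path, geojson_path, adjacency_path)
    if (length(paths) < 4L || !all(file.exists(paths))) {
      stop("without `simulate`, all four input paths must exist.",
           call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 mcmc = mcmc, cutoffs = cutoffs, simulate = simulate,
                 case_path = case_path, population_path = population_path,
                 geojson_path = geojson_path, adjacency_path = adjacency_path,
                 comparison = comparison, std = std, scan_stage = scan_stage),
            class = "run_config")
}

#' Run the full mapping pipeline
#'
#' Simulates (or reads) the inputs, then per stage: indirect standardisation,
#' BYM smoothing, signal classification; then cross-stage concordance,
#' ecological regression, the case-level late-stage logistic model, the
#' directly standardised time trends, and optionally the scan comparison.
#' All tables are written as CSV under `config$out_dir` together with a JSON
#' run manifest; reruns with the same seed produce identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`geo`, `pop`,
#'   `cases`, `sir`, `fits`, `signals`, `trends`, `ecoreg`, `logistic`,
#'   `concordance`, `scan`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest <- list(status = "failed", failed_stage = name,
                       error = conditionMessage(e), seed = config$seed)
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    geo <- step("simulate", generate_geography(
      sim$n_rows, sim$n_cols,
      income_spatial_trend = sim$income_spatial_trend %||% 1,
      seed = config$seed))
    pop <- generate_population(geo, mean_area_pop = sim$mean_area_pop,
                               n_years = sim$n_years, seed = config$seed + 1L)
    params <- sim$params %||% risk_params()
    cases <- simulate_cases(pop, geo, params, seed = config$seed + 2L)
  } else {
    geo <- step("read", read_geography(config$geojson_path,
                                       config$adjacency_path))
    pop <- read_population(config$population_path)
    cases <- read_cases(config$case_path, known_areas = geo$areas$area_id)
  }
  if (!identical(config$comparison, "regional")) {
    scope <- config$comparison
    keep <- geo$areas$area_id %in% scope
    if (!any(keep)) {
      stop("comparison scope matches no areas in the geography.",
           call. = FALSE)
    }
    geo$areas <- geo$areas[keep, ]
    geo$areas$quintile <- assign_quintiles(
      stats::setNames(geo$areas$median_income, geo$areas$area_id))
    geo$adjacency <- lapply(geo$adjacency[geo$areas$area_id],
                            function(nb) nb[nb %in% scope])
    pop <- pop[pop$area_id %in% scope, ]
    cases <- cases[cases$area_id %in% scope, ]
  }
  quint <- stats::setNames(as.character(geo$areas$quintile),
                           geo$areas$area_id)

  utils::write.csv(pop, file.path(config$out_dir, "population.csv"),
                   row.names = FALSE)
  utils::write.csv(cases, file.path(config$out_dir, "cases.csv"),
                   row.names = FALSE)
  write_geography(geo, file.path(config$out_dir, "geography.geojson"),
                  file.path(config$out_dir, "adjacency.csv"))

  trends <- step("standardise",
                 direct_standardised_rates(cases, pop, std = config$std))
  utils::write.csv(trends, file.path(config$out_dir, "trend_rates.csv"),
                   row.names = FALSE)

  fits <- list(); signals <- list(); sir_all <- list()
  for (s in config$stages) {
    sir <- step("standardise", compute_sir(expected_counts(cases, pop, s)))
    sir_all[[s]] <- sir
    fit <- step("smooth", fit_bym(
      sir, geo$adjacency, mcmc = mcmc_control(
        n_iter = config$mcmc$n_iter, burn_in = config$mcmc$burn_in,
        thin = config$mcmc$thin, n_chains = config$mcmc$n_chains,
        seed = config$seed + 10L * match(s, stage_levels()))))
    fits[[s]] <- fit
    sig <- step("classify", classify_signals(posterior_pp(fit),
                                             cutoffs = config$cutoffs))
    signals[[s]] <- sig
    utils::write.csv(fit$summary,
                     file.path(config$out_dir,
                               sprintf("smoothed_sir_stage_%s.csv",
                                       gsub("[^A-Za-z0-9]", "", s))),
                     row.names = FALSE)
    out_sig <- dplyr::left_join(sig, fit$summary[, c("area_id", "smoothed_sir")],
                                by = "area_id")
    out_sig$stage <- s
    utils::write.csv(out_sig,
                     file.path(config$out_dir,
                               sprintf("signals_stage_%s.csv",
                                       gsub("[^A-Za-z0-9]", "", s))),
                     row.names = FALSE)
    write_signal_geojson(sig, geo,
                         file.path(config$out_dir,
                                   sprintf("signals_stage_%s.geojson",
                                           gsub("[^A-Za-z0-9]", "", s))))
  }

  conc <- list()
  if (all(c("I", "II") %in% names(fits))) {
    conc$stage_II_vs_I_elevated <-
      step("concordance", concordance(signals[["II"]], fits[["I"]], "elevated"))
    conc$stage_II_vs_I_lowered <-
      step("concordance", concordance(signals[["II"]], fits[["I"]], "lowered"))
  }

  ecoreg <- list()
  for (s in names(fits)) {
    ecoreg[[s]] <- step("ecoreg", ecological_regression(fits[[s]],
                                                        quintile = quint))
    er <- ecoreg[[s]]; er$stage <- s
    utils::write.csv(er, file.path(config$out_dir,
                                   sprintf("ecoreg_stage_%s.csv",
                                           gsub("[^A-Za-z0-9]", "", s))),
                     row.names = FALSE)
  }

  logistic <- step("caseor", late_stage_logistic(cases, quintile = quint))
  utils::write.csv(logistic, file.path(config$out_dir, "late_stage_or.csv"),
                   row.names = FALSE)

  scan <- NULL
  if (!is.null(config$scan_stage) && config$scan_stage %in% names(sir_all)) {
    scan <- step("scan", kulldorff_scan(sir_all[[config$scan_stage]], geo,
                                        n_sim = 499, seed = config$seed + 99L))
    st <- scan
    st$members <- vapply(st$members, paste, character(1), collapse = ";")
    utils::write.csv(st, file.path(config$out_dir, "scan_clusters.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    status = "complete", seed = config$seed,
    stages = config$stages,
    n_areas = nrow(geo$areas), n_cases = nrow(cases),
    package_version = as.character(utils::packageVersion("stagemap")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(geo = geo, pop = pop, cases = cases, sir = sir_all,
                 fits = fits, signals = signals, trends = trends,
                 ecoreg = ecoreg, logistic = logistic, concordance = conc,
                 scan = scan, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
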