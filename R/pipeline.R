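#' Join ranges, traits and environment into the analysis table
#'
#' Inner-joins the measured range totals, the species trait table and
#' the per-species environmental summaries on species id, recodes the
#' binary traits to 0/1 columns (`habitat_epifaunal`, `mobility_mobile`,
#' `development_planktonic`; the coding table is attached as an
#' attribute), renames the annual current-speed variability, and drops
#' (with a log) rows with any missing predictor.
#'
#' @param ranges Data frame `species_id`, `total_km` (e.g.
#'   `measure_ranges()$totals`).
#' @param traits Data frame with `species_id`,
#'   `time_since_introduction`, `habitat`, `mobility`, `development`,
#'   `max_body_size_mm`.
#' @param env Data frame from [extract_env()].
#' @return Data frame sorted by species id with the response `total_km`
#'   and the predictor roster: time since introduction, three 0/1
#'   traits, body size, spring current speed mean, annual current
#'   variability, spring temperature mean, annual temperature SD, annual
#'   salinity mean and SD. Attributes: `"coding"` (trait coding table),
#'   `"dropped"` (drop log data frame), `"n"`.
#' @export
build_analysis_table <- function(ranges, traits, env) {
  for (d in list(ranges, traits, env))
    if (anyDuplicated(d$species_id))
      stop("duplicate species ids in an input table")
  need_env <- c("current_speed_spring_mean", "current_speed_annual_sd",
                "temperature_spring_mean", "temperature_annual_sd",
                "salinity_annual_mean", "salinity_annual_sd")
  miss <- setdiff(need_env, names(env))
  if (length(miss))
    stop("environment table lacks: ", paste(miss, collapse = ", "))
  m <- merge(merge(ranges[c("species_id", "total_km")], traits,
                   by = "species_id"),
             env[c("species_id", need_env)], by = "species_id")
  m$habitat_epifaunal <- as.integer(m$habitat == "epifaunal")
  m$mobility_mobile <- as.integer(m$mobility == "mobile")
  m$development_planktonic <- as.integer(m$development == "planktonic")
  m$current_variability_annual <- m$current_speed_annual_sd
  keep <- c("species_id", "total_km", "time_since_introduction",
            "habitat_epifaunal", "mobility_mobile", "max_body_size_mm",
            "development_planktonic", "current_speed_spring_mean",
            "current_variability_annual", "temperature_spring_mean",
            "temperature_annual_sd", "salinity_annual_mean",
            "salinity_annual_sd")
  miss <- setdiff(keep, names(m))
  if (length(miss))
    stop("analysis table lacks: ", paste(miss, collapse = ", "))
  m <- m[keep]
  complete <- stats::complete.cases(m)
  dropped <- m[!complete, "species_id", drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "incomplete-predictors"
  m <- m[complete, , drop = FALSE]
  m <- m[order(m$species_id), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "coding") <- data.frame(
    variable = c("habitat_epifaunal", "mobility_mobile",
                 "development_planktonic"),
    one_means = c("epifaunal", "mobile", "planktonic"),
    zero_means = c("infaunal", "sessile", "non-planktonic"))
  attr(m, "dropped") <- dropped
  attr(m, "n") <- nrow(m)
  m
}

#' The standard predictor roster as a model formula
#'
#' @return Formula regressing total range on the eleven standard
#'   predictors of [build_analysis_table()].
#' @export
analysis_formula <- function() {
  stats::as.formula(
    total_km ~ time_since_introduction + habitat_epifaunal +
      mobility_mobile + max_body_size_mm + development_planktonic +
      current_speed_spring_mean + current_variability_annual +
      temperature_spring_mean + temperature_annual_sd +
      salinity_annual_mean + salinity_annual_sd,
    env = baseenv())
}

#' Per-coast latitudinal bands with an old/young introduction flag
#'
#' Produces the table behind waterfall-style displays: one row per
#' species and coastline with the minimum and maximum occurrence
#' latitude, flagged `"Old"` when the species' first record predates the
#' dataset median year and `"Young"` otherwise (the median year itself
#' counts as Young).
#'
#' @param results Named list of [total_range()] objects (e.g.
#'   `measure_ranges()$results`).
#' @param years Data frame `species_id`, `year` (first-record year).
#' @param median_year Split year; default the median of `years$year`.
#' @return Data frame `species_id`, `coastline_id`, `lat_min`,
#'   `lat_max`, `year`, `age_class`, sorted by species then coastline.
#' @export
waterfall_export <- function(results, years, median_year = NULL) {
  if (is.null(median_year)) median_year <- stats::median(years$year)
  rows <- lapply(results, function(r) {
    if (r$no_range || !nrow(r$lat_bands)) return(NULL)
    cbind(species_id = r$species_id, r$lat_bands)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(species_id = character(0),
                      coastline_id = character(0),
                      lat_min = numeric(0), lat_max = numeric(0),
                      year = numeric(0), age_class = character(0)))
  out <- merge(out, years[c("species_id", "year")], by = "species_id")
  out$age_class <- ifelse(out$year < median_year, "Old", "Young")
  out <- out[order(out$species_id, out$coastline_id), ]
  rownames(out) <- NULL
  out
}

#' Run the full pipeline on a synthetic world
#'
#' Chains every stage: world simulation, occurrence cleaning and range
#' measurement, climatology extraction, analysis-table assembly, and the
#' all-subsets model competition. Optionally writes all tables, the
#' ranked model report and the resolved configuration (every threshold
#' echoed) to a directory; output row order is deterministic.
#'
#' @param config A [world_config()].
#' @param out_dir Optional output directory.
#' @param offshore_tol_km,archipelago_km,linkage_km,gap_km Measurement
#'   thresholds, see [measure_ranges()].
#' @param top_k Importance subset size, see [compete_ranges()].
#' @param season_convention See [season_months()].
#' @return List with `world`, `measured`, `env`, `table` (analysis
#'   table), `competition` (a [compete_ranges()] result), `waterfall`,
#'   and `paths` (when `out_dir` is given).
#' @export
run_pipeline <- function(config, out_dir = NULL, offshore_tol_km = 100,
                         archipelago_km = 1000, linkage_km = 1000,
                         gap_km = 1500, top_k = 40,
                         season_convention = "jfm") {
  world <- simulate_world(config)
  measured <- measure_ranges(world$occurrences, world$coastlines,
                             offshore_tol_km = offshore_tol_km,
                             archipelago_km = archipelago_km,
                             linkage_km = linkage_km, gap_km = gap_km,
                             isolated_km = config$isolated_km)
  env <- extract_env(measured$assignments, world$grids,
                     convention = season_convention)
  tab <- build_analysis_table(measured$totals, world$species, env)
  comp <- compete_ranges(analysis_formula(), tab, top_k = top_k)
  wf <- waterfall_export(measured$results,
                         world$species[c("species_id", "year")],
                         median_year = config$median_year)
  out <- list(world = world, measured = measured, env = env,
              table = tab, competition = comp, waterfall = wf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_world(world, file.path(out_dir, "inputs"))
    p <- function(f) file.path(out_dir, f)
    write_ranges_csv(measured, p("range_segments.csv"),
                     p("range_totals.csv"))
    utils::write.csv(measured$drops, p("drop_log.csv"),
                     row.names = FALSE)
    utils::write.csv(env, p("env_summaries.csv"), row.names = FALSE)
    utils::write.csv(tab, p("analysis_table.csv"), row.names = FALSE)
    fits <- comp$fits
    utils::write.csv(fits, p("model_table.csv"), row.names = FALSE)
    utils::write.csv(wf, p("waterfall.csv"), row.names = FALSE)
    sink(p("model_report.txt"))
    print(summary(comp))
    sink()
    resolved <- c(
      unclass(config)[!vapply(unclass(config), is.null, TRUE)],
      list(offshore_tol_km = offshore_tol_km,
           archipelago_km = archipelago_km, linkage_km = linkage_km,
           gap_km = gap_km, top_k = top_k,
           season_convention = season_convention))
    writeLines(paste0(names(resolved), " = ",
                      vapply(resolved, function(v)
                        paste(format(v), collapse = ","), "")),
               p("resolved_config.txt"))
    out$paths <- c(paths, list(out_dir = out_dir))
  }
  out
}

#' Recover the time-only regression across pipeline replicates
#'
#' The parameter-recovery experiment: for `reps` seeded replicates,
#' generate a world from `config` (seeds `config$seed + 0:(reps-1)`),
#' run occurrence placement and range measurement through the pipeline,
#' fit the single-predictor regression of measured total range on time
#' since introduction, and collect the slope, intercept and R-squared
#' estimates.
#'
#' @param config A [world_config()]; use `trait_effects = NULL` for the
#'   pure time-only generative model.
#' @param reps Number of replicates. Default 200.
#' @return Data frame with one row per replicate: `seed`, `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
recover_time_slope <- function(config, reps = 200) {
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    world <- simulate_world(cfg)
    measured <- measure_ranges(world$occurrences, world$coastlines,
                               isolated_km = cfg$isolated_km)
    d <- merge(measured$totals,
               world$species[c("species_id", "time_since_introduction")],
               by = "species_id")
    f <- stats::lm(total_km ~ time_since_introduction, data = d)
    out[[r]] <- data.frame(seed = cfg$seed,
                           slope = stats::coef(f)[[2]],
                           intercept = stats::coef(f)[[1]],
                           r_squared = summary(f)$r.squared,
                           n = nrow(d))
  }
  do.call(rbind, out)
}
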