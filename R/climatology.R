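#' Construct a one-degree monthly climatology grid
#'
#' Holds one oceanographic variable (temperature in deg C, salinity in
#' PSU, or current speed in m/s) on a regular one-degree
#' latitude-longitude grid, as twelve monthly fields plus a land mask.
#' Seasonal values are resolved at query time from each point's own
#' hemisphere (see [season_months()]), so the stored grid is
#' hemisphere-neutral.
#'
#' @param variable One of `"temperature"`, `"salinity"`,
#'   `"current_speed"`.
#' @param lat_centers,lon_centers Cell-centre coordinates; must be on a
#'   regular grid of exactly one-degree spacing.
#' @param values Numeric array `length(lat_centers) x length(lon_centers)
#'   x 12` of monthly fields; `NA` marks land/masked cells (a cell masked
#'   in any month is treated as masked).
#' @return Object of class `"climatology"`.
#' @export
climatology <- function(variable = c("temperature", "salinity",
                                     "current_speed"),
                        lat_centers, lon_centers, values) {
  variable <- match.arg(variable)
  d <- dim(values)
  if (length(d) != 3 || d[3] != 12)
    stop("values must be an nlat x nlon x 12 array")
  if (d[1] != length(lat_centers) || d[2] != length(lon_centers))
    stop("values dimensions do not match grid centres")
  for (v in list(lat_centers, lon_centers))
    if (length(v) > 1 && any(abs(diff(v) - 1) > 1e-9))
      stop("grid resolution must be exactly 1 degree")
  mask <- apply(values, c(1, 2), function(z) any(is.na(z)))
  if (all(mask)) stop("fully masked grid")
  structure(list(variable = variable, lat = as.numeric(lat_centers),
                 lon = as.numeric(lon_centers), values = values,
                 mask = mask),
            class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf("<climatology '%s'> %d x %d cells, %.0f%% masked\n",
              x$variable, length(x$lat), length(x$lon),
              100 * mean(x$mask)))
  invisible(x)
}

#' Months belonging to an oceanographic season
#'
#' Seasons are three-month blocks starting in January (winter =
#' Jan-Feb-Mar in the north), mirrored by six months in the southern
#' hemisphere; `"annual"` is all twelve months. The alternative
#' December-anchored meteorological convention (winter = Dec-Jan-Feb) is
#' available via `convention`.
#'
#' @param season `"winter"`, `"spring"`, `"summer"`, `"autumn"` or
#'   `"annual"`.
#' @param hemisphere `"N"` or `"S"`.
#' @param convention `"jfm"` (default, January-anchored blocks) or
#'   `"djf"` (December-anchored).
#' @return Integer vector of month numbers (1-12).
#' @examples
#' season_months("spring", "N")  # April, May, June
#' season_months("spring", "S")  # October, November, December
#' @export
season_months <- function(season, hemisphere = c("N", "S"),
                          convention = c("jfm", "djf")) {
  hemisphere <- match.arg(hemisphere)
  convention <- match.arg(convention)
  season <- match.arg(season,
                      c("winter", "spring", "summer", "autumn", "annual"))
  if (season == "annual") return(1:12)
  start <- c(winter = 1L, spring = 4L, summer = 7L, autumn = 10L)[season]
  if (convention == "djf") start <- start - 1L
  if (hemisphere == "S") start <- start + 6L
  ((start + 0:2 - 1L) %% 12L) + 1L
}

#' Sample a climatology grid at points
#'
#' Returns, for each point, the mean over the requested months of the
#' value of the one-degree cell containing the point. If that cell is
#' masked (land), the nearest unmasked cell centre by great-circle
#' distance within `max_search_deg` is used instead, ties broken by
#' (lat, lon) lexicographic order; beyond the search radius the value is
#' `NA`.
#'
#' @param grid A [climatology()].
#' @param lat,lon Point coordinates.
#' @param months Integer months to average over (default all twelve).
#' @param max_search_deg Nearest-unmasked search radius in degrees of
#'   great-circle arc. Default 5.
#' @return Numeric vector of sampled values (NA where unresolvable).
#' @export
sample_grid <- function(grid, lat, lon, months = 1:12,
                        max_search_deg = 5) {
  stopifnot(inherits(grid, "climatology"))
  .check_coords(lat, lon)
  if (any(months < 1 | months > 12)) stop("months must be in 1..12")
  li <- findInterval(lat, c(grid$lat - 0.5, grid$lat[length(grid$lat)] + 0.5),
                     rightmost.closed = TRUE)
  gi <- findInterval(lon, c(grid$lon - 0.5, grid$lon[length(grid$lon)] + 0.5),
                     rightmost.closed = TRUE)
  li[li < 1 | li > length(grid$lat)] <- NA
  gi[gi < 1 | gi > length(grid$lon)] <- NA
  open <- which(!grid$mask, arr.ind = TRUE)
  # unmasked centres in lexicographic (lat, lon) order for tie-breaking
  ord <- order(grid$lat[open[, 1]], grid$lon[open[, 2]])
  open <- open[ord, , drop = FALSE]
  olat <- grid$lat[open[, 1]]; olon <- grid$lon[open[, 2]]
  max_km <- max_search_deg * pi / 180 * EARTH_RADIUS_KM
  out <- rep(NA_real_, length(lat))
  for (i in seq_along(lat)) {
    ci <- li[i]; cj <- gi[i]
    if (is.na(ci) || is.na(cj) || grid$mask[ci, cj]) {
      dd <- great_circle_km(lat[i], lon[i], olat, olon)
      k <- which.min(dd)       # first minimum = lexicographic tie-break
      if (!length(k) || dd[k] > max_km) next
      ci <- open[k, 1]; cj <- open[k, 2]
    }
    out[i] <- mean(grid$values[ci, cj, months])
  }
  out
}

.ENV_SEASONS <- c("winter", "spring", "summer", "autumn", "annual")

#' Seasonal and annual climate summaries for one species
#'
#' Samples every climatology grid at a species' cleaned occurrence
#' points and computes, per variable and season, the mean, sample
#' standard deviation (n - 1 denominator), minimum and maximum across
#' points. Each point's hemisphere (latitude sign; the equator counts as
#' north) decides its own season-to-month mapping, so species straddling
#' the equator mix the two hemispheres' month blocks. For temperature
#' and salinity an annual range (annual max minus annual min) is added.
#' Points that cannot be resolved within the grid search radius are
#' excluded from that variable's statistics and logged.
#'
#' @param points Data frame of one species' cleaned points (`lat`,
#'   `lon`; a `species_id` column, if present, must be constant).
#' @param grids List of [climatology()] objects (one per variable).
#' @param convention Season convention, see [season_months()].
#' @param max_search_deg See [sample_grid()].
#' @return One-row data frame with columns `<variable>_<season>_<stat>`
#'   for stat in mean/sd/min/max, plus `temperature_annual_range` and
#'   `salinity_annual_range` when those variables are present, and an
#'   attribute `"env_log"` listing excluded points. `NULL` (with a
#'   message) for zero points.
#' @export
summarize_species_env <- function(points, grids, convention = "jfm",
                                  max_search_deg = 5) {
  if (!nrow(points)) {
    message("no cleaned points: no environmental summary")
    return(NULL)
  }
  if ("species_id" %in% names(points) &&
      length(unique(points$species_id)) > 1)
    stop("summarize_species_env expects a single species")
  hemi <- ifelse(points$lat >= 0, "N", "S")
  out <- list()
  log <- list()
  for (g in grids) {
    for (season in .ENV_SEASONS) {
      vals <- rep(NA_real_, nrow(points))
      for (h in unique(hemi)) {
        i <- hemi == h
        vals[i] <- sample_grid(g, points$lat[i], points$lon[i],
                               months = season_months(season, h, convention),
                               max_search_deg = max_search_deg)
      }
      if (anyNA(vals))
        log[[length(log) + 1]] <- data.frame(
          variable = g$variable, season = season,
          lat = points$lat[is.na(vals)], lon = points$lon[is.na(vals)])
      v <- vals[!is.na(vals)]
      pre <- paste0(g$variable, "_", season, "_")
      if (!length(v)) {
        out[paste0(pre, c("mean", "sd", "min", "max"))] <- NA_real_
      } else {
        out[[paste0(pre, "mean")]] <- mean(v)
        out[[paste0(pre, "sd")]] <- if (length(v) > 1) stats::sd(v) else 0
        out[[paste0(pre, "min")]] <- min(v)
        out[[paste0(pre, "max")]] <- max(v)
      }
    }
    if (g$variable %in% c("temperature", "salinity")) {
      out[[paste0(g$variable, "_annual_range")]] <-
        out[[paste0(g$variable, "_annual_max")]] -
        out[[paste0(g$variable, "_annual_min")]]
    }
  }
  res <- as.data.frame(out)
  attr(res, "env_log") <- if (length(log)) do.call(rbind, log) else NULL
  res
}

#' Environmental summaries for every species in a point table
#'
#' @param points Cleaned occurrence data frame with `species_id`.
#' @param grids List of [climatology()] grids.
#' @param ... Passed to [summarize_species_env()].
#' @return Data frame, one row per species (sorted by id), first column
#'   `species_id`.
#' @export
extract_env <- function(points, grids, ...) {
  ids <- sort(unique(points$species_id))
  rows <- lapply(ids, function(id) {
    r <- summarize_species_env(points[points$species_id == id, ,
                                      drop = FALSE], grids, ...)
    cbind(species_id = id, r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a climatology grid from dense CSV
#'
#' Long format with columns `lat`, `lon`, `month`, `value`; missing cells
#' (absent rows or NA values) are masked. The grid extent is inferred
#' from the coordinates present.
#'
#' @param path CSV file path.
#' @param variable Variable name for the resulting [climatology()].
#' @return A [climatology()] object.
#' @export
read_climatology_csv <- function(path, variable) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lat", "lon", "month", "value")
  if (!all(need %in% names(d)))
    stop("climatology CSV must have columns lat, lon, month, value")
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  arr <- array(NA_real_, c(length(lat), length(lon), 12))
  arr[cbind(match(d$lat, lat), match(d$lon, lon), d$month)] <- d$value
  climatology(variable, lat, lon, arr)
}

#' Write a climatology grid to dense CSV
#'
#' @param grid A [climatology()].
#' @param path Output CSV path. Masked cells are omitted.
#' @return `path`, invisibly.
#' @export
write_climatology_csv <- function(grid, path) {
  # masked cells are written with empty values so the extent survives
  # the round trip
  d <- expand.grid(month = 1:12, lon = grid$lon, lat = grid$lat)
  d <- d[c("lat", "lon", "month")]
  d$value <- grid$values[cbind(match(d$lat, grid$lat),
                               match(d$lon, grid$lon), d$month)]
  d <- d[order(d$lat, d$lon, d$month), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
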