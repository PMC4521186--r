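#' Read an occurrence table
#'
#' Reads a CSV of species occurrence points. Darwin-Core style column
#' names (`decimalLatitude`, `decimalLongitude`) and plain `lat`/`lon` are
#' both accepted; a missing `source` column defaults to `"gbif"`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `species_id`, `lat`, `lon`, `source`.
#' @export
read_occurrences <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(decimalLatitude = "lat", decimalLongitude = "lon",
           scientificName = "species_id", species = "species_id")
  for (nm in names(ren)) if (nm %in% names(d) && !(ren[[nm]] %in% names(d)))
    names(d)[names(d) == nm] <- ren[[nm]]
  need <- c("species_id", "lat", "lon")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("occurrence file lacks column(s): ", paste(miss, collapse = ", "))
  if (!"source" %in% names(d)) d$source <- "gbif"
  d[c("species_id", "lat", "lon", "source")]
}

#' Clean occurrence points
#'
#' Applies the coordinate-hygiene rules used before any range measurement:
#' points at exactly (0, 0) are treated as data-entry artifacts; points
#' farther than `offshore_tol_km` from every coastline are implausible for
#' coastal benthic species (inland records, misplaced museum specimens);
#' exact duplicate coordinates within a species are collapsed. Every
#' removal is logged with a reason code.
#'
#' @param points Data frame with `species_id`, `lat`, `lon` (and
#'   optionally `source`).
#' @param coastlines A [coastline()] or list of coastlines.
#' @param offshore_tol_km Maximum plausible distance from any coastline,
#'   km. Default 100, the scale of a one-degree grid cell.
#' @return A list with `points` (the retained rows, plus `offshore_km` and
#'   `nearest_coast`) and `drops` (one row per removed record:
#'   `species_id`, `lat`, `lon`, `reason` in
#'   `{"zero-zero", "bad-coordinate", "off-coast", "duplicate"}`).
#' @export
clean_occurrences <- function(points, coastlines, offshore_tol_km = 100) {
  coastlines <- .as_coastline_list(coastlines)
  stopifnot(all(c("species_id", "lat", "lon") %in% names(points)))
  if (!"source" %in% names(points)) points$source <- "gbif"
  drops <- points[0, c("species_id", "lat", "lon")]
  drops$reason <- character(0)
  log_drop <- function(rows, reason) {
    if (!nrow(rows)) return(invisible())
    d <- rows[c("species_id", "lat", "lon")]
    d$reason <- reason
    drops <<- rbind(drops, d)
  }

  bad <- !is.finite(points$lat) | !is.finite(points$lon) |
    points$lat < -90 | points$lat > 90 |
    points$lon < -180 | points$lon >= 360
  log_drop(points[bad, ], "bad-coordinate")
  points <- points[!bad, ]

  zz <- points$lat == 0 & points$lon == 0
  log_drop(points[zz, ], "zero-zero")
  points <- points[!zz, ]

  dup <- duplicated(points[c("species_id", "lat", "lon")])
  log_drop(points[dup, ], "duplicate")
  points <- points[!dup, ]

  if (nrow(points)) {
    dmat <- vapply(coastlines, function(cc)
      coast_project(cc, points$lat, points$lon)$offshore_km,
      numeric(nrow(points)))
    dmat <- matrix(dmat, nrow = nrow(points))
    nearest <- max.col(-dmat, ties.method = "first")
    dmin <- dmat[cbind(seq_len(nrow(points)), nearest)]
    off <- dmin > offshore_tol_km
    log_drop(points[off, ], "off-coast")
    points$offshore_km <- dmin
    points$nearest_coast <- names(coastlines)[nearest]
    points <- points[!off, ]
  } else {
    points$offshore_km <- numeric(0)
    points$nearest_coast <- character(0)
  }
  rownames(points) <- NULL
  rownames(drops) <- NULL
  list(points = points, drops = drops)
}

#' Assign cleaned points to coastlines or archipelago clusters
#'
#' Each point is attached to its nearest coastline (any type) with its
#' along-coast position `s`. Points farther than `archipelago_km` from
#' every continental coastline are flagged as archipelago points and
#' grouped into clusters by single-linkage agglomeration at
#' `linkage_km`: islands whose occurrences chain together within that
#' radius form one distribution, measured later as a straight-line span
#' rather than along a coast.
#'
#' @param points Cleaned occurrence data frame (`species_id`, `lat`, `lon`).
#' @param coastlines A [coastline()] or list of coastlines; at least one.
#' @param archipelago_km Distance from all continental coastlines beyond
#'   which occurrences count as oceanic-archipelago records. Default 1000.
#' @param linkage_km Single-linkage radius for grouping archipelago points
#'   into clusters. Default 1000, reusing the only island-scale constant
#'   of the measurement rules.
#' @return Data frame: input columns plus `coastline_id`, `s`,
#'   `offshore_km`, `is_archipelago`, `archipelago_id` (NA for coastal
#'   points; `"<species>arc<k>"` per species cluster otherwise).
#' @export
assign_points <- function(points, coastlines, archipelago_km = 1000,
                          linkage_km = 1000) {
  coastlines <- .as_coastline_list(coastlines)
  n <- nrow(points)
  if (!length(coastlines)) stop("no coastlines supplied")
  if (!n) {
    points$coastline_id <- character(0); points$s <- numeric(0)
    points$offshore_km <- numeric(0)
    points$is_archipelago <- logical(0)
    points$archipelago_id <- character(0)
    return(points)
  }
  proj <- lapply(coastlines, coast_project, lat = points$lat,
                 lon = points$lon)
  dmat <- vapply(proj, `[[`, numeric(n), "offshore_km")
  dmat <- matrix(dmat, nrow = n)
  nearest <- max.col(-dmat, ties.method = "first")
  points$coastline_id <- names(coastlines)[nearest]
  points$s <- vapply(seq_len(n), function(i) proj[[nearest[i]]]$s[i], 0)
  points$offshore_km <- dmat[cbind(seq_len(n), nearest)]

  cont <- vapply(coastlines, `[[`, TRUE, "is_continental")
  if (any(cont)) {
    dcont <- apply(dmat[, cont, drop = FALSE], 1, min)
  } else {
    dcont <- rep(Inf, n)
  }
  points$is_archipelago <- dcont > archipelago_km
  points$archipelago_id <- NA_character_

  arc <- which(points$is_archipelago)
  if (length(arc)) {
    for (sp in unique(points$species_id[arc])) {
      i <- arc[points$species_id[arc] == sp]
      if (length(i) == 1) {
        points$archipelago_id[i] <- paste0(sp, "arc1")
      } else {
        dd <- outer(i, i, function(a, b)
          great_circle_km(points$lat[a], points$lon[a],
                          points$lat[b], points$lon[b]))
        cl <- stats::cutree(stats::hclust(stats::as.dist(dd),
                                          method = "single"),
                            h = linkage_km)
        points$archipelago_id[i] <- paste0(sp, "arc", cl)
      }
    }
  }
  points
}
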