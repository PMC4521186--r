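#' Segment along-coast positions into disjoint range pieces
#'
#' Implements the two core measurement rules on a single coastline: the
#' range is split wherever two neighbouring occurrences are more than
#' `gap_km` apart along the coast (strictly greater), and every resulting
#' single-point group is scored with the fixed isolated-point length
#' `isolated_km` rather than zero.
#'
#' @param s Numeric vector of along-coast positions (km) on one coastline;
#'   order is irrelevant.
#' @param gap_km Along-coast separation beyond which a range is not
#'   considered continuous. Default 1500.
#' @param isolated_km Length credited to an isolated single occurrence.
#'   Default 50.
#' @return Data frame with one row per disjoint segment: `s_start`,
#'   `s_end`, `length_km`, `n_points`, `is_isolated`. Empty input gives
#'   zero rows.
#' @examples
#' segment_coast_positions(c(100, 300))        # one 200 km segment
#' segment_coast_positions(c(100, 1700))       # two isolated points
#' @export
segment_coast_positions <- function(s, gap_km = 1500, isolated_km = 50) {
  empty <- data.frame(s_start = numeric(0), s_end = numeric(0),
                      length_km = numeric(0), n_points = integer(0),
                      is_isolated = logical(0))
  if (!length(s)) return(empty)
  if (any(!is.finite(s))) stop("non-finite along-coast position")
  s <- sort(s)
  grp <- cumsum(c(1, as.integer(diff(s) > gap_km)))
  res <- lapply(split(s, grp), function(g) {
    # coincident records at one locality are still one isolated point
    iso <- g[length(g)] == g[1]
    data.frame(s_start = g[1], s_end = g[length(g)],
               length_km = if (iso) isolated_km else g[length(g)] - g[1],
               n_points = length(g), is_isolated = iso)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Straight-line span of an archipelago occurrence cluster
#'
#' Oceanic-archipelago clusters have no coastline axis; their range is the
#' straight line through the cluster, taken as the great-circle distance
#' between the two most separated members. A singleton cluster scores the
#' isolated-point length.
#'
#' @param lat,lon Cluster member coordinates; at least one point.
#' @param isolated_km Length credited to a single isolated point.
#' @return Span in km.
#' @export
archipelago_range <- function(lat, lon, isolated_km = 50) {
  if (!length(lat)) stop("empty archipelago cluster")
  if (length(lat) == 1) return(isolated_km)
  dd <- outer(seq_along(lat), seq_along(lat), function(a, b)
    great_circle_km(lat[a], lon[a], lat[b], lon[b]))
  # coincident records collapse to one isolated locality
  if (max(dd) == 0) isolated_km else max(dd)
}

#' Total non-native range of one species
#'
#' Composes the measurement rules over a species' assigned points: each
#' coastline's positions are segmented with [segment_coast_positions()],
#' each archipelago cluster is spanned with [archipelago_range()], and all
#' segment lengths are summed across coasts and islands into the species'
#' total range in km. Latitudinal bands (min/max occurrence latitude per
#' coastline) are recorded for waterfall-style summaries.
#'
#' @param species_id Species label.
#' @param assignments Output of [assign_points()] (any species mix; rows
#'   for `species_id` are used).
#' @param gap_km,isolated_km See [segment_coast_positions()].
#' @return An object of class `"range_result"`: list with `species_id`,
#'   `segments` (data frame: `coastline_id`, `s_start`, `s_end`,
#'   `length_km`, `n_points`, `is_isolated`, `is_archipelago`),
#'   `total_km`, `lat_bands` (data frame `coastline_id`, `lat_min`,
#'   `lat_max`), and `no_range` (TRUE when the species has no cleaned
#'   points; `total_km` is then NA, not 0).
#' @export
total_range <- function(species_id, assignments, gap_km = 1500,
                        isolated_km = 50) {
  a <- assignments[assignments$species_id == species_id, , drop = FALSE]
  if (!nrow(a)) {
    return(structure(list(species_id = species_id,
                          segments = data.frame(), total_km = NA_real_,
                          lat_bands = data.frame(), no_range = TRUE),
                     class = "range_result"))
  }
  segs <- list()
  coastal <- a[!a$is_archipelago, , drop = FALSE]
  for (cid in unique(coastal$coastline_id)) {
    g <- segment_coast_positions(coastal$s[coastal$coastline_id == cid],
                                 gap_km = gap_km, isolated_km = isolated_km)
    if (nrow(g)) {
      g <- cbind(coastline_id = cid, g, is_archipelago = FALSE)
      segs[[length(segs) + 1]] <- g
    }
  }
  arc <- a[a$is_archipelago, , drop = FALSE]
  for (aid in unique(arc$archipelago_id)) {
    g <- arc[arc$archipelago_id == aid, , drop = FALSE]
    segs[[length(segs) + 1]] <- data.frame(
      coastline_id = aid, s_start = NA_real_, s_end = NA_real_,
      length_km = archipelago_range(g$lat, g$lon, isolated_km),
      n_points = nrow(g), is_isolated = nrow(g) == 1,
      is_archipelago = TRUE)
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  bands <- do.call(rbind, lapply(split(coastal, coastal$coastline_id),
                                 function(g) data.frame(
                                   coastline_id = g$coastline_id[1],
                                   lat_min = min(g$lat),
                                   lat_max = max(g$lat))))
  if (is.null(bands)) bands <- data.frame()
  rownames(bands) <- NULL
  structure(list(species_id = species_id, segments = segments,
                 total_km = sum(segments$length_km), lat_bands = bands,
                 no_range = FALSE),
            class = "range_result")
}

#' @export
print.range_result <- function(x, ...) {
  if (x$no_range) {
    cat(sprintf("<range_result '%s'> no cleaned occurrences\n",
                x$species_id))
    return(invisible(x))
  }
  cat(sprintf("<range_result '%s'> total %.1f km over %d segment(s)\n",
              x$species_id, x$total_km, nrow(x$segments)))
  invisible(x)
}

#' Discretise a reported locale into coastline points
#'
#' Literature records often give only a stretch of coast ("coast of X").
#' Such a locale, expressed as an along-coast interval, is converted into
#' occurrence points every `step_km` along the coastline, with the
#' interval end always included so the realised span equals the reported
#' extent.
#'
#' @param coast A [coastline()].
#' @param s_start,s_end Interval bounds, km, `0 <= s_start <= s_end <=`
#'   coastline length.
#' @param step_km Spacing between generated coordinates. Default 200.
#' @param species_id Label stamped on the generated points.
#' @return Data frame `species_id`, `lat`, `lon`, `source = "literature"`,
#'   `s`.
#' @export
locale_to_points <- function(coast, s_start, s_end, step_km = 200,
                             species_id = "literature-locale") {
  stopifnot(.is_coastline(coast))
  if (s_start > s_end) stop("inverted locale interval")
  if (s_start < 0 || s_end > coast$length_km)
    stop("locale interval outside coastline")
  s <- unique(c(seq(s_start, s_end, by = step_km), s_end))
  ll <- coast_point_at(coast, s)
  data.frame(species_id = species_id, lat = ll[, "lat"], lon = ll[, "lon"],
             source = "literature", s = s)
}

#' Measure total ranges for every species in an occurrence table
#'
#' End-to-end range quantification: cleaning, coastline assignment,
#' per-coast segmenting, archipelago spans, and cross-coast summation.
#'
#' @param points Occurrence data frame (`species_id`, `lat`, `lon`, and
#'   optionally `source`), e.g. from [read_occurrences()].
#' @param coastlines A [coastline()] or list of coastlines.
#' @param offshore_tol_km Cleaning tolerance, see [clean_occurrences()].
#' @param archipelago_km,linkage_km See [assign_points()].
#' @param gap_km,isolated_km See [segment_coast_positions()].
#' @return A list with `totals` (data frame `species_id`, `total_km`,
#'   `n_points`, `n_segments`, sorted by species id), `results` (named
#'   list of [total_range()] objects), `segments` (row-bound segment
#'   table), `drops` (cleaning log), `assignments`.
#' @export
measure_ranges <- function(points, coastlines, offshore_tol_km = 100,
                           archipelago_km = 1000, linkage_km = 1000,
                           gap_km = 1500, isolated_km = 50) {
  cl <- clean_occurrences(points, coastlines, offshore_tol_km)
  asg <- assign_points(cl$points, coastlines, archipelago_km, linkage_km)
  ids <- sort(unique(points$species_id))
  results <- lapply(ids, total_range, assignments = asg,
                    gap_km = gap_km, isolated_km = isolated_km)
  names(results) <- ids
  totals <- data.frame(
    species_id = ids,
    total_km = vapply(results, `[[`, 0, "total_km"),
    n_points = vapply(ids, function(i) sum(asg$species_id == i), 0L),
    n_segments = vapply(results, function(r)
      if (r$no_range) 0L else nrow(r$segments), 0L),
    row.names = NULL)
  segments <- do.call(rbind, lapply(results, function(r) {
    if (r$no_range || !nrow(r$segments)) return(NULL)
    cbind(species_id = r$species_id, r$segments)
  }))
  rownames(segments) <- NULL
  list(totals = totals, results = results, segments = segments,
       drops = cl$drops, assignments = asg)
}

#' Export measured range segments and totals to CSV
#'
#' @param measured Result of [measure_ranges()].
#' @param segments_path,totals_path Output CSV paths (either may be NULL
#'   to skip).
#' @return Invisibly, the list of written paths.
#' @export
write_ranges_csv <- function(measured, segments_path = NULL,
                             totals_path = NULL) {
  written <- list()
  if (!is.null(segments_path)) {
    seg <- measured$segments
    seg <- seg[order(seg$species_id, seg$coastline_id, seg$s_start), ]
    utils::write.csv(seg, segments_path, row.names = FALSE)
    written$segments <- segments_path
  }
  if (!is.null(totals_path)) {
    utils::write.csv(measured$totals, totals_path, row.names = FALSE)
    written$totals <- totals_path
  }
  invisible(written)
}
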