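#' Construct a coastline
#'
#' A coastline is an ordered, directed polyline of geographic vertices with
#' a cumulative along-coast arc length (`cum_s`, km) at every vertex. It is
#' the one-dimensional axis along which species ranges are measured: a
#' position on a coastline is a single number `s`, the distance in km from
#' the first stored vertex. The direction convention is file-level: `s`
#' increases from the first vertex in the order the vertices are supplied.
#'
#' @param lat,lon Vertex coordinates in decimal degrees, equal length >= 2.
#' @param id Coastline label, e.g. `"NE-Pacific"`.
#' @param basin Ocean basin label.
#' @param hemisphere `"N"` or `"S"`; the dominant hemisphere, used only as
#'   metadata (per-point season resolution uses each point's own latitude).
#' @param is_continental Logical; continental coastlines define the
#'   archipelago rule (clusters more than `archipelago_km` from every
#'   continental coastline are measured as straight-line spans).
#' @return An object of class `"coastline"`: a list with fields `id`,
#'   `basin`, `hemisphere`, `is_continental`, `lat`, `lon`, `cum_s` and the
#'   total `length_km`.
#' @seealso [coast_project()], [coast_point_at()], [read_coastlines_geojson()]
#' @export
coastline <- function(lat, lon, id = "coast", basin = "basin",
                      hemisphere = c("N", "S"), is_continental = TRUE) {
  hemisphere <- match.arg(hemisphere)
  lat <- unname(as.numeric(lat)); lon <- unname(as.numeric(lon))
  if (length(lat) != length(lon)) stop("lat and lon lengths differ")
  if (length(lat) < 2) stop("a coastline needs at least 2 vertices")
  .check_coords(lat, lon)
  seg <- great_circle_km(lat[-length(lat)], lon[-length(lon)],
                         lat[-1], lon[-1])
  if (any(seg <= 0)) stop("coastline has coincident consecutive vertices")
  cum_s <- c(0, cumsum(seg))
  structure(list(id = id, basin = basin, hemisphere = hemisphere,
                 is_continental = isTRUE(is_continental),
                 lat = lat, lon = lon, cum_s = unname(cum_s),
                 length_km = unname(cum_s[length(cum_s)])),
            class = "coastline")
}

#' @export
print.coastline <- function(x, ...) {
  cat(sprintf("<coastline '%s'> basin %s, hemisphere %s, %s\n", x$id,
              x$basin, x$hemisphere,
              if (x$is_continental) "continental" else "non-continental"))
  cat(sprintf("  %d vertices, length %.1f km\n", length(x$lat), x$length_km))
  invisible(x)
}

.is_coastline <- function(x) inherits(x, "coastline")

.as_coastline_list <- function(coastlines) {
  if (.is_coastline(coastlines)) coastlines <- list(coastlines)
  if (!length(coastlines) || !all(vapply(coastlines, .is_coastline, TRUE)))
    stop("expected a coastline or a list of coastlines", call. = FALSE)
  nm <- vapply(coastlines, `[[`, "", "id")
  stats::setNames(coastlines, nm)
}

#' Position along a coastline at given arc lengths
#'
#' Inverse of projection: interpolates the vertex polyline at arc length
#' `s` (km from the first vertex) using chord-parameterised interpolation
#' on the unit sphere, the same parameterisation [coast_project()] uses, so
#' placing a point at `s` and projecting it back recovers `s`.
#'
#' @param coast A [coastline()].
#' @param s Numeric vector of along-coast positions in km, within
#'   `[0, coast$length_km]`.
#' @return Matrix with columns `lat`, `lon`.
#' @export
coast_point_at <- function(coast, s) {
  stopifnot(.is_coastline(coast))
  if (any(s < -1e-9 | s > coast$length_km + 1e-9))
    stop("s outside [0, coastline length]")
  s <- pmin(pmax(s, 0), coast$length_km)
  i <- findInterval(s, coast$cum_s, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), length(coast$cum_s) - 1)
  u <- (s - coast$cum_s[i]) / (coast$cum_s[i + 1] - coast$cum_s[i])
  xyz <- .to_xyz(coast$lat, coast$lon)
  a <- xyz[i, , drop = FALSE]; b <- xyz[i + 1, , drop = FALSE]
  .to_latlon(a + u * (b - a))
}

#' Project points onto a coastline
#'
#' Finds, for each point, the nearest location on the coastline polyline
#' under the great-circle metric with chord-parameterised interpolation
#' within each segment. Positions beyond the terminal vertices clamp to the
#' terminus.
#'
#' @param coast A [coastline()].
#' @param lat,lon Point coordinates, decimal degrees.
#' @return A data frame with one row per point: `s` (along-coast position,
#'   km), `offshore_km` (great-circle distance from the point to its
#'   projection, km), `lat`, `lon`.
#' @export
coast_project <- function(coast, lat, lon) {
  stopifnot(.is_coastline(coast))
  .check_coords(lat, lon)
  p <- .to_xyz(lat, lon)
  v <- .to_xyz(coast$lat, coast$lon)
  nseg <- nrow(v) - 1
  a <- v[-nrow(v), , drop = FALSE]
  d <- v[-1, , drop = FALSE] - a             # segment chord vectors
  dd <- rowSums(d^2)
  npt <- nrow(p)
  out_s <- numeric(npt); out_d <- numeric(npt)
  # blockwise over points to bound memory at nseg x block doubles
  block <- max(1L, as.integer(2e6 / nseg))
  ad <- rowSums(d * a)
  for (b0 in seq(1L, npt, by = block)) {
    idx <- b0:min(b0 + block - 1L, npt)
    pb <- p[idx, , drop = FALSE]
    nb <- length(idx)
    # u[j, k]: chord parameter of point j on segment k, clamped to [0,1]
    u <- (tcrossprod(pb, d) - rep(ad, each = nb)) / rep(dd, each = nb)
    u[u < 0] <- 0; u[u > 1] <- 1
    q2 <- 0; qdot <- 0                        # |q|^2 and q . p
    for (k in 1:3) {
      qk <- rep(a[, k], each = nb) + u * rep(d[, k], each = nb)
      q2 <- q2 + qk * qk
      qdot <- qdot + qk * pb[, k]
    }
    # chord^2 between p and q/|q| : 2 - 2 (q.p)/|q|
    chord2 <- 2 - 2 * qdot / sqrt(q2)
    chord2[chord2 < 0] <- 0
    best <- max.col(-chord2, ties.method = "first")
    j <- cbind(seq_len(nb), best)
    out_s[idx] <- coast$cum_s[best] +
      u[j] * (coast$cum_s[best + 1] - coast$cum_s[best])
    out_d[idx] <- EARTH_RADIUS_KM * .chord_angle(sqrt(chord2[j]))
  }
  data.frame(s = out_s, offshore_km = out_d, lat = lat, lon = lon)
}

#' Read coastlines from GeoJSON
#'
#' Accepts a FeatureCollection of LineString features with properties
#' `id`, `basin`, `hemisphere`, `is_continental`.
#'
#' @param path GeoJSON file path.
#' @return Named list of [coastline()] objects.
#' @export
read_coastlines_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection")
  coasts <- lapply(g$features, function(f) {
    if (!identical(f$geometry$type, "LineString"))
      stop("coastline features must be LineString")
    xy <- do.call(rbind, lapply(f$geometry$coordinates,
                                function(c) c(c[[1]], c[[2]])))
    pr <- f$properties
    coastline(lat = xy[, 2], lon = xy[, 1],
              id = pr$id %||% "coast", basin = pr$basin %||% "basin",
              hemisphere = pr$hemisphere %||% "N",
              is_continental = isTRUE(pr$is_continental))
  })
  .as_coastline_list(coasts)
}

#' Write coastlines to GeoJSON
#'
#' @param coastlines A coastline or list of coastlines.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coastlines_geojson <- function(coastlines, path) {
  coastlines <- .as_coastline_list(coastlines)
  feats <- lapply(coastlines, function(cc) {
    list(type = "Feature",
         properties = list(id = cc$id, basin = cc$basin,
                           hemisphere = cc$hemisphere,
                           is_continental = cc$is_continental),
         geometry = list(type = "LineString",
                         coordinates = Map(function(lo, la) c(lo, la),
                                           cc$lon, cc$lat)))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read coastlines from a vertex CSV
#'
#' Long-format alternative to GeoJSON: columns `id`, `order`, `lat`, `lon`
#' and optionally `basin`, `hemisphere`, `is_continental`.
#'
#' @param path CSV file path.
#' @return Named list of [coastline()] objects.
#' @export
read_coastlines_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "order", "lat", "lon")
  if (!all(need %in% names(d)))
    stop("coastline CSV must have columns id, order, lat, lon")
  coasts <- lapply(split(d, d$id), function(g) {
    g <- g[order(g$order), ]
    coastline(g$lat, g$lon, id = g$id[1],
              basin = if ("basin" %in% names(g)) g$basin[1] else "basin",
              hemisphere = if ("hemisphere" %in% names(g)) g$hemisphere[1] else "N",
              is_continental = if ("is_continental" %in% names(g))
                as.logical(g$is_continental[1]) else TRUE)
  })
  .as_coastline_list(coasts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
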