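# Geospatial validation of occurrence coordinates against documented-country
# polygons: point-in-country agreement, neighbouring-country tolerance, and
# coastline tolerance, all with great-circle distances on a sphere of mean
# radius 6371.0088 km.

EARTH_RADIUS_KM <- 6371.0088

haversine_km <- function(p, pts) {
  geosphere::distHaversine(p, pts, r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Build a country polygon set
#'
#' @param polygons named list (ISO-3166 alpha-3 codes) where each element is
#'   a list of rings; each ring is a 2-column matrix of (lon, lat) vertices
#'   in WGS84. Rings are closed automatically. Holes are supported through
#'   the even-odd containment rule.
#' @param adjacency optional named list of character vectors giving, for
#'   each country, the codes of countries sharing at least one border
#'   segment. When `NULL` it is computed from shared ring edges (vertex
#'   coordinates rounded to 1e-6 degrees), which is exact for tessellated
#'   polygon sets built from a common vertex grid.
#' @return A `country_polygon_set` object.
#' @export
country_polygon_set <- function(polygons, adjacency = NULL) {
  stopifnot(is.list(polygons), length(polygons) >= 1, !is.null(names(polygons)))
  polygons <- lapply(polygons, function(rings) {
    if (is.matrix(rings)) rings <- list(rings)
    lapply(rings, function(r) {
      r <- as.matrix(r)
      stopifnot(ncol(r) == 2, nrow(r) >= 3)
      colnames(r) <- c("lon", "lat")
      if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
      r
    })
  })
  if (is.null(adjacency)) adjacency <- adjacency_from_shared_edges(polygons)
  for (iso in names(adjacency)) {     # adjacency must be symmetric
    for (nb in adjacency[[iso]]) {
      adjacency[[nb]] <- union(adjacency[[nb]], iso)
    }
  }
  structure(list(polygons = polygons, adjacency = adjacency,
                 cache = new.env(parent = emptyenv())),
            class = "country_polygon_set")
}

adjacency_from_shared_edges <- function(polygons) {
  edge_keys <- lapply(polygons, function(rings) {
    keys <- character(0)
    for (r in rings) {
      a <- sprintf("%.6f,%.6f", r[-nrow(r), 1], r[-nrow(r), 2])
      b <- sprintf("%.6f,%.6f", r[-1, 1], r[-1, 2])
      keys <- c(keys, paste(pmin(a, b), pmax(a, b)))
    }
    unique(keys)
  })
  isos <- names(polygons)
  adjacency <- stats::setNames(vector("list", length(isos)), isos)
  for (i in seq_along(isos)) adjacency[[i]] <- character(0)
  if (length(isos) > 1) {
    for (i in seq_len(length(isos) - 1)) {
      for (j in seq(i + 1, length(isos))) {
        if (length(intersect(edge_keys[[i]], edge_keys[[j]]))) {
          adjacency[[isos[i]]] <- c(adjacency[[isos[i]]], isos[j])
          adjacency[[isos[j]]] <- c(adjacency[[isos[j]]], isos[i])
        }
      }
    }
  }
  adjacency
}

#' @export
print.country_polygon_set <- function(x, ...) {
  cat(sprintf("<country_polygon_set: %d countries (%s)>\n",
              length(x$polygons),
              paste(utils::head(names(x$polygons), 6), collapse = ", ")))
  invisible(x)
}

#' Read country polygons from a GeoJSON file
#'
#' Accepts an RFC 7946 FeatureCollection of Polygon/MultiPolygon features in
#' lon/lat order. The country code is taken from the feature `id` or from
#' the first of the `iso_a3` / `ISO_A3` / `iso3` / `ADM0_A3` properties.
#'
#' @param path GeoJSON file.
#' @inheritParams country_polygon_set
#' @return A `country_polygon_set`.
#' @export
read_country_polygons <- function(path, adjacency = NULL) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  polys <- list()
  for (feat in gj$features) {
    iso <- feat$id
    for (key in c("iso_a3", "ISO_A3", "iso3", "ADM0_A3")) {
      if (is.null(iso)) iso <- feat$properties[[key]]
    }
    if (is.null(iso)) stop("feature without a country code property")
    geom <- feat$geometry
    rings <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop("unsupported geometry type: ", geom$type))
    polys[[as.character(iso)]] <- lapply(rings, function(r) {
      do.call(rbind, lapply(r, function(xy) c(xy[[1]], xy[[2]])))
    })
  }
  country_polygon_set(polys, adjacency)
}

# ---- point-in-polygon ------------------------------------------------------

point_on_ring <- function(lon, lat, ring, eps = 1e-9) {
  x1 <- ring[-nrow(ring), 1]; y1 <- ring[-nrow(ring), 2]
  x2 <- ring[-1, 1];          y2 <- ring[-1, 2]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((lon - x1) * dx + (lat - y1) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  d2 <- (lon - (x1 + t * dx))^2 + (lat - (y1 + t * dy))^2
  any(d2 <= eps^2)
}

ring_crossings <- function(lon, lat, ring) {
  x1 <- ring[-nrow(ring), 1]; y1 <- ring[-nrow(ring), 2]
  x2 <- ring[-1, 1];          y2 <- ring[-1, 2]
  straddle <- (y1 > lat) != (y2 > lat)
  if (!any(straddle)) return(0L)
  xint <- x1[straddle] + (lat - y1[straddle]) *
    (x2[straddle] - x1[straddle]) / (y2[straddle] - y1[straddle])
  sum(lon < xint)
}

#' Point-in-country test (even-odd rule, boundary counts as inside)
#'
#' @param lon,lat point coordinates, decimal degrees.
#' @param polyset a [country_polygon_set()].
#' @param iso country code.
#' @return `TRUE` if the point lies inside (or exactly on the boundary of)
#'   the country's polygons, under the even-odd rule across all rings.
#' @export
point_in_country <- function(lon, lat, polyset, iso) {
  rings <- polyset$polygons[[iso]]
  if (is.null(rings)) stop("unknown country code: ", iso)
  for (r in rings) if (point_on_ring(lon, lat, r)) return(TRUE)
  crossings <- sum(vapply(rings, function(r) ring_crossings(lon, lat, r),
                          integer(1)))
  crossings %% 2L == 1L
}

#' Find which country (if any) contains a point
#'
#' @inheritParams point_in_country
#' @param prefer country code tested first (ties on shared borders resolve
#'   in its favour).
#' @return A country code, or `NA_character_` for points in no polygon
#'   (open sea).
#' @export
locate_country <- function(lon, lat, polyset, prefer = NULL) {
  isos <- names(polyset$polygons)
  if (!is.null(prefer) && prefer %in% isos) {
    isos <- c(prefer, setdiff(isos, prefer))
  }
  for (iso in isos) {
    if (point_in_country(lon, lat, polyset, iso)) return(iso)
  }
  NA_character_
}

# ---- boundary distance -----------------------------------------------------

densify_ring <- function(ring, max_segment_km = 1) {
  pts <- list()
  for (i in seq_len(nrow(ring) - 1)) {
    a <- ring[i, ]; b <- ring[i + 1, ]
    d <- haversine_km(a, b)
    n <- max(1L, ceiling(d / max_segment_km))
    t <- seq(0, 1, length.out = n + 1)[-(n + 1)]
    pts[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  rbind(do.call(rbind, pts), ring[nrow(ring), , drop = FALSE])
}

country_boundary_rings <- function(polyset, iso, max_segment_km = 1) {
  key <- paste0(iso, "@", max_segment_km)
  if (!is.null(polyset$cache[[key]])) return(polyset$cache[[key]])
  rings <- lapply(polyset$polygons[[iso]], densify_ring,
                  max_segment_km = max_segment_km)
  polyset$cache[[key]] <- rings
  rings
}

# exact nearest distance from p to one densified ring: vertex sweep to
# locate the closest region, then point-to-segment refinement in a local
# equirectangular frame (the foot point is then measured by haversine, so
# the refinement is spherical-accurate at the sub-kilometre scale involved)
ring_distance_km <- function(p, ring) {
  dv <- haversine_km(p, ring)
  i <- which.min(dv)
  best <- dv[i]
  n <- nrow(ring)
  cosphi <- cos(p[2] * pi / 180)
  segs <- unique(pmax(1, pmin(n - 1, c(i - 2, i - 1, i, i + 1))))
  for (s in segs) {
    a <- ring[s, ]; b <- ring[s + 1, ]
    ax <- (a[1] - p[1]) * cosphi; ay <- a[2] - p[2]
    bx <- (b[1] - p[1]) * cosphi; by <- b[2] - p[2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) next
    t <- min(1, max(0, -(ax * dx + ay * dy) / len2))
    foot <- c(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    best <- min(best, haversine_km(p, foot))
  }
  best
}

#' Great-circle distance from a point to a country boundary
#'
#' The boundary polyline is densified so that no segment exceeds
#' `max_segment_km`; the minimum great-circle distance (sphere radius
#' 6371.0088 km) from the point to the polyline is found by a vertex sweep
#' followed by a point-to-segment refinement around the nearest vertex.
#'
#' @param point numeric `c(lon, lat)`.
#' @param boundary a ring matrix, a list of rings, or a
#'   [country_polygon_set()] together with `iso`.
#' @param iso country code, required when `boundary` is a polygon set.
#' @param max_segment_km densification step.
#' @return Distance in km (0 if the point lies on the boundary).
#' @export
nearest_border_distance_km <- function(point, boundary, iso = NULL,
                                       max_segment_km = 1) {
  if (inherits(boundary, "country_polygon_set")) {
    stopifnot(!is.null(iso))
    rings <- country_boundary_rings(boundary, iso, max_segment_km)
  } else {
    if (is.matrix(boundary)) boundary <- list(boundary)
    if (!length(boundary) || !nrow(boundary[[1]])) stop("empty boundary")
    rings <- lapply(boundary, function(r) {
      if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
      densify_ring(r, max_segment_km)
    })
  }
  min(vapply(rings, function(r) ring_distance_km(point, r), numeric(1)))
}

# ---- classification --------------------------------------------------------

geo_classes <- function() {
  c("Match", "Neighbour", "Sea", "Error", "NoCoordinates", "NoCountry")
}

geo_result <- function(record_id, classification, distance_km, verdict) {
  data.frame(record_id = record_id, classification = classification,
             distance_km = distance_km, verdict = verdict,
             stringsAsFactors = FALSE)
}

classify_point <- function(record_id, lon, lat, iso, polyset, tolerance_km,
                           no_country_verdict = "keep") {
  if (is.na(lon) || is.na(lat)) {
    return(geo_result(record_id, "NoCoordinates", NA_real_, "keep"))
  }
  if (is.na(iso) || !iso %in% names(polyset$polygons)) {
    containing <- locate_country(lon, lat, polyset)
    if (is.na(containing)) {
      # at sea with no documented country: nothing to measure against
      return(geo_result(record_id, "Sea", NA_real_, "discard"))
    }
    return(geo_result(record_id, "NoCountry", NA_real_, no_country_verdict))
  }
  if (point_in_country(lon, lat, polyset, iso)) {
    return(geo_result(record_id, "Match", NA_real_, "keep"))
  }
  containing <- locate_country(lon, lat, polyset)
  d <- nearest_border_distance_km(c(lon, lat), polyset, iso = iso)
  if (is.na(containing)) {
    return(geo_result(record_id, "Sea", d,
                      if (d <= tolerance_km) "keep" else "discard"))
  }
  if (containing %in% polyset$adjacency[[iso]]) {
    return(geo_result(record_id, "Neighbour", d,
                      if (d <= tolerance_km) "keep" else "discard"))
  }
  geo_result(record_id, "Error", NA_real_, "discard")
}

#' Validate one record's coordinates against its documented country
#'
#' Classifies a georeferenced record following the documented-country check:
#' `Match` (point inside the documented country — a point exactly on the
#' border counts as inside), `Neighbour` (point in an adjacent country;
#' the nearest great-circle distance to the documented country's border is
#' computed and the record is kept iff it is within `tolerance_km`),
#' `Error` (point in a non-adjacent country; discarded), or `Sea` (point in
#' no polygon; see [validate_coastline()]).
#'
#' @param record a single-row `occ_records` table (or list with
#'   `record_id`, `longitude`, `latitude`, `country_code`).
#' @param polygons a [country_polygon_set()].
#' @param tolerance_km retention tolerance in km; distances exactly equal to
#'   the tolerance are kept.
#' @return One-row data.frame: `record_id`, `classification`, `distance_km`,
#'   `verdict`.
#' @export
validate_country <- function(record, polygons, tolerance_km = 5) {
  classify_point(as.character(record$record_id[1]),
                 record$longitude[1], record$latitude[1],
                 record$country_code[1], polygons, tolerance_km)
}

#' Validate a record whose coordinates fall in the ocean
#'
#' For a point lying in no country polygon, the nearest great-circle
#' distance to the documented country's coastline is computed; the record is
#' kept iff the distance is within `tolerance_km`. A point at sea with no
#' documented country cannot be rescued and is discarded.
#'
#' @inheritParams validate_country
#' @return One-row data.frame as in [validate_country()], with
#'   classification `Sea`.
#' @export
validate_coastline <- function(record, polygons, tolerance_km = 5) {
  validate_country(record, polygons, tolerance_km)
}

#' Validate all records against country polygons
#'
#' Vectorized driver applying [validate_country()] /
#' [validate_coastline()] to every record. Records without usable
#' coordinates are classified `NoCoordinates`; records with coordinates but
#' no documented country are `NoCountry` (kept by default, with a warning).
#' Every record receives exactly one classification and a keep/discard
#' verdict; discards get audit entries.
#'
#' @param records an `occ_records` table.
#' @param polygons a [country_polygon_set()].
#' @param tolerance_km retention tolerance (km), default 5.
#' @param no_country_verdict verdict for on-land records lacking a
#'   documented country: `"keep"` (default) or `"discard"`.
#' @return List with `results` (one row per record), `records` (kept
#'   records), `discarded` (discarded records), `audit`.
#' @export
geo_validate <- function(records, polygons, tolerance_km = 5,
                         no_country_verdict = c("keep", "discard")) {
  no_country_verdict <- match.arg(no_country_verdict)
  res <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    lon <- if (records$coord_valid[i]) records$longitude[i] else NA_real_
    lat <- if (records$coord_valid[i]) records$latitude[i] else NA_real_
    res[[i]] <- classify_point(records$record_id[i], lon, lat,
                               records$country_code[i], polygons,
                               tolerance_km, no_country_verdict)
  }
  results <- do.call(rbind, res)
  if (any(results$classification == "NoCountry")) {
    warning(sum(results$classification == "NoCountry"),
            " record(s) have coordinates but no documented country")
  }
  drop <- results$verdict == "discard"
  audit <- audit_entries(results$record_id[drop], "geo", "discarded",
                         paste0("geo check: ", results$classification[drop]))
  kept <- records[!drop, , drop = FALSE]
  discarded <- records[drop, , drop = FALSE]
  class(kept) <- class(records); class(discarded) <- class(records)
  kept <- set_audit(kept, bind_audit(occ_audit(records), audit))
  list(results = results, records = kept, discarded = discarded,
       audit = audit)
}

# ---- density grid ----------------------------------------------------------

#' Record density on a regular degree grid
#'
#' Counts records with valid coordinates per `cell_degrees` x `cell_degrees`
#' cell. Cells are aligned to multiples of the cell size and half-open,
#' `[lower, upper)`, so a record exactly on a cell edge belongs to the cell
#' whose lower edge it sits on.
#'
#' @param records an `occ_records` table.
#' @param cell_degrees cell size in degrees (default 2).
#' @return data.frame `cell_lon`, `cell_lat` (lower-left corners), `count`;
#'   total count equals the number of records with valid coordinates.
#' @export
density_grid <- function(records, cell_degrees = 2) {
  if (!is.numeric(cell_degrees) || cell_degrees <= 0) {
    stop("cell_degrees must be positive")
  }
  ok <- records$coord_valid
  lon <- floor(records$longitude[ok] / cell_degrees) * cell_degrees
  lat <- floor(records$latitude[ok] / cell_degrees) * cell_degrees
  if (!length(lon)) {
    return(data.frame(cell_lon = numeric(), cell_lat = numeric(),
                      count = integer()))
  }
  tab <- stats::aggregate(list(count = rep(1L, length(lon))),
                          by = list(cell_lon = lon, cell_lat = lat), FUN = sum)
  tab <- tab[order(tab$cell_lon, tab$cell_lat), ]
  rownames(tab) <- NULL
  attr(tab, "cell_degrees") <- cell_degrees
  tab
}
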