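# Shared in-code fixtures for the test suite.

KM_DEG <- 111.19493  # great-circle km per degree at R = 6371.0088 km

# three countries in a row (ZAA-ZAB-ZAC), ocean all around; ZAA and ZAC do
# not share a border
row3_polygons <- function() {
  make_polygons(3, origin = c(10, -2), cell_degrees = 2, ncols = 3)
}

# offset a longitude by a ground distance (km) at a given latitude
lon_offset <- function(lon, km, lat) lon + km / (KM_DEG * cos(lat * pi / 180))

make_test_records <- function(df) {
  defaults <- list(source_id = "SRC", source_kind = "institutional",
                   genus = "Acacia", species = "adenocalyx")
  for (f in names(defaults)) {
    if (!f %in% names(df)) df[[f]] <- defaults[[f]]
  }
  as_occ_records(df)
}

tiny_backbone <- function() {
  read_backbone(data.frame(
    name_id = c("a1", "a2", "a3", "s1", "s2"),
    name = c("Acacia adenocalyx", "Acacia seyal", "Milicia excelsa",
             "Acacia gloriosa", "Chlorophora excelsa"),
    rank = "species",
    status = c("accepted", "accepted", "accepted", "synonym", "synonym"),
    accepted_name_id = c("a1", "a2", "a3", "a2", "a3"),
    stringsAsFactors = FALSE))
}

# independent point-in-polygon oracle: sp's C implementation when present,
# else a winding-number angle sum (different algorithm from the package's
# even-odd crossing count)
pip_oracle <- function(lon, lat, ring) {
  if (requireNamespace("sp", quietly = TRUE)) {
    return(sp::point.in.polygon(lon, lat, ring[, 1], ring[, 2]) > 0)
  }
  x <- ring[-nrow(ring), 1] - lon; y <- ring[-nrow(ring), 2] - lat
  x2 <- ring[-1, 1] - lon; y2 <- ring[-1, 2] - lat
  ang <- atan2(x * y2 - y * x2, x * x2 + y * y2)
  abs(sum(ang)) > pi
}

# brute-force great-circle minimum over a finely densified boundary,
# independent of the package's densification path
brute_border_km <- function(point, ring, step_deg = 2e-4) {
  pts <- list()
  for (i in seq_len(nrow(ring) - 1)) {
    a <- ring[i, ]; b <- ring[i + 1, ]
    n <- max(1, ceiling(max(abs(b - a)) / step_deg))
    t <- seq(0, 1, length.out = n + 1)
    pts[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  pts <- do.call(rbind, pts)
  min(geosphere::distHaversine(point, pts, r = 6371008.8)) / 1000
}
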