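test_that("documented-country check classifies Match/Neighbour/Error correctly", {
  ps <- row3_polygons()   # ZAA [10,12], ZAB [12,14], ZAC [14,16], lat [-2,0]
  lat <- -1
  inside <- data.frame(record_id = "a", longitude = 11, latitude = lat,
                       country_code = "ZAA")
  expect_equal(validate_country(inside, ps)$classification, "Match")
  expect_equal(validate_country(inside, ps)$verdict, "keep")
  expect_true(is.na(validate_country(inside, ps)$distance_km))

  near <- data.frame(record_id = "b", longitude = lon_offset(12, 3, lat),
                     latitude = lat, country_code = "ZAA")
  res <- validate_country(near, ps)
  expect_equal(res$classification, "Neighbour")
  expect_equal(res$verdict, "keep")
  expect_equal(res$distance_km, 3, tolerance = 0.01)

  far <- data.frame(record_id = "c", longitude = lon_offset(12, 7, lat),
                    latitude = lat, country_code = "ZAA")
  res <- validate_country(far, ps)
  expect_equal(res$classification, "Neighbour")
  expect_equal(res$verdict, "discard")
  expect_equal(res$distance_km, brute_border_km(
    c(lon_offset(12, 7, lat), lat), ps$polygons$ZAA[[1]]), tolerance = 1e-3)

  nonadj <- data.frame(record_id = "d", longitude = 15, latitude = lat,
                       country_code = "ZAA")
  res <- validate_country(nonadj, ps)
  expect_equal(res$classification, "Error")
  expect_equal(res$verdict, "discard")
})

test_that("coastline check keeps nearshore points and discards far offshore ones", {
  ps <- row3_polygons()
  lat <- -1
  near <- data.frame(record_id = "s1", longitude = lon_offset(10, -2, lat),
                     latitude = lat, country_code = "ZAA")
  res <- validate_coastline(near, ps)
  expect_equal(res$classification, "Sea")
  expect_equal(res$verdict, "keep")
  expect_equal(res$distance_km, 2, tolerance = 0.01)

  far <- data.frame(record_id = "s2", longitude = lon_offset(10, -40, lat),
                    latitude = lat, country_code = "ZAA")
  res <- validate_coastline(far, ps)
  expect_equal(res$classification, "Sea")
  expect_equal(res$verdict, "discard")

  lost <- data.frame(record_id = "s3", longitude = lon_offset(10, -2, lat),
                     latitude = lat, country_code = NA_character_)
  expect_equal(validate_coastline(lost, ps)$verdict, "discard")
})

test_that("distance exactly at the tolerance is kept, and on-border points Match", {
  ps <- row3_polygons()
  at5 <- data.frame(record_id = "e1", longitude = lon_offset(12, 5, -1),
                    latitude = -1, country_code = "ZAA")
  d <- validate_country(at5, ps)$distance_km
  # setting the tolerance to the measured distance itself must keep the
  # record: the retention rule is inclusive (distance <= tolerance)
  expect_equal(validate_country(at5, ps, tolerance_km = d)$verdict, "keep")
  expect_equal(validate_country(at5, ps, tolerance_km = d - 1e-6)$verdict,
               "discard")
  on_border <- data.frame(record_id = "e2", longitude = 12, latitude = -1,
                          country_code = "ZAA")
  res <- validate_country(on_border, ps)
  expect_equal(res$classification, "Match")  # tie-break favours retention
  expect_equal(res$verdict, "keep")
})

test_that("shrinking the tolerance never converts a discard into a keep", {
  ps <- row3_polygons()
  set.seed(42)
  tols <- c(10, 5, 2, 1, 0.5)
  for (i in 1:40) {
    lat <- runif(1, -1.9, -0.1)
    km <- runif(1, 0.2, 12)
    rec <- data.frame(record_id = "m",
                      longitude = lon_offset(12, km, lat),
                      latitude = lat, country_code = "ZAA")
    verdicts <- vapply(tols, function(tol)
      validate_country(rec, ps, tolerance_km = tol)$verdict, character(1))
    keeps <- verdicts == "keep"
    # keep flags are monotone non-increasing as the tolerance shrinks
    expect_true(all(diff(as.integer(keeps)) <= 0))
  }
})

test_that("point-in-polygon agrees with an independent oracle on random polygons", {
  set.seed(7)
  for (rep in 1:15) {
    k <- sample(4:9, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, 0.5, 2)
    ring <- cbind(10 + rad * cos(ang), 5 + rad * sin(ang))
    ring <- rbind(ring, ring[1, ])
    ps <- country_polygon_set(list(XXX = list(ring)))
    pts <- cbind(runif(40, 7, 13), runif(40, 2, 8))
    mine <- vapply(seq_len(nrow(pts)), function(i)
      point_in_country(pts[i, 1], pts[i, 2], ps, "XXX"), logical(1))
    oracle <- vapply(seq_len(nrow(pts)), function(i)
      pip_oracle(pts[i, 1], pts[i, 2], ring), logical(1))
    expect_equal(mine, oracle)
  }
})

test_that("border distance matches closed-form and brute-force oracles", {
  # meridian border segment on the equator: 1 degree of arc = 111.19 km
  ring <- rbind(c(0, -1), c(0, 1), c(-1, 1), c(-1, -1), c(0, -1))
  d <- nearest_border_distance_km(c(1, 0), ring)
  expect_equal(d, 111.19, tolerance = 0.01)
  # point on a polygon vertex
  expect_equal(nearest_border_distance_km(c(0, 1), ring), 0)
  # random points vs independent brute-force sweep, within 0.1%
  set.seed(13)
  for (i in 1:12) {
    p <- c(runif(1, -3, 3), runif(1, -3, 3))
    expect_equal(nearest_border_distance_km(p, ring),
                 brute_border_km(p, ring), tolerance = 1e-3)
  }
  expect_error(nearest_border_distance_km(c(0, 0), list()), "empty")
})

test_that("border distance is invariant under a common longitude shift", {
  ring <- rbind(c(0, -1), c(0, 1), c(-1, 1), c(-1, -1), c(0, -1))
  set.seed(5)
  for (i in 1:8) {
    p <- c(runif(1, -3, 3), runif(1, -2, 2))
    shift <- runif(1, -30, 30)
    shifted <- ring; shifted[, 1] <- shifted[, 1] + shift
    expect_equal(nearest_border_distance_km(p, ring),
                 nearest_border_distance_km(c(p[1] + shift, p[2]), shifted),
                 tolerance = 1e-6)
  }
})

test_that("geo_validate partitions records and audits every discard", {
  fx <- make_records(fixture_spec(
    n_countries = 4, n_species = 15, n_records = 150,
    error_rates = list(border_swap = 0.1, sea_point = 0.1, far_error = 0.1),
    seed = 3))
  gv <- geo_validate(fx$records, fx$polygons)
  expect_equal(nrow(gv$results), nrow(fx$records))
  expect_equal(nrow(gv$records) + nrow(gv$discarded), nrow(fx$records))
  expect_true(all(table(gv$results$record_id) == 1))
  expect_setequal(gv$audit$record_id, gv$discarded$record_id)
  expect_true(all(gv$audit$action == "discarded"))
})

test_that("records lacking coordinates or country are flagged, not dropped", {
  ps <- row3_polygons()
  recs <- make_test_records(data.frame(
    record_id = c("n1", "n2"),
    latitude = c(NA, -1), longitude = c(NA, 11),
    country_code = c("ZAA", NA)))
  expect_warning(gv <- geo_validate(recs, ps), "no documented country")
  expect_equal(gv$results$classification, c("NoCoordinates", "NoCountry"))
  expect_equal(gv$results$verdict, c("keep", "keep"))
})

test_that("density grid conserves counts and uses half-open cells", {
  recs <- make_test_records(data.frame(
    record_id = sprintf("r%02d", 1:10),
    latitude = rep(0.5, 10), longitude = rep(10.5, 10)))
  g <- density_grid(recs, 2)
  expect_equal(nrow(g), 1)
  expect_equal(g$count, 10L)
  # a record exactly on a cell edge goes to the cell it is the lower edge of
  edge <- make_test_records(data.frame(record_id = "e", latitude = 2,
                                       longitude = 4))
  ge <- density_grid(edge, 2)
  expect_equal(c(ge$cell_lon, ge$cell_lat), c(4, 2))
  set.seed(20)
  many <- make_test_records(data.frame(
    record_id = sprintf("u%04d", 1:1000),
    latitude = runif(1000, -30, 30), longitude = runif(1000, -20, 40)))
  expect_equal(sum(density_grid(many, 2)$count), 1000L)
  expect_error(density_grid(recs, 0), "positive")
})

test_that("GeoJSON polygons round-trip and adjacency is symmetric", {
  ps <- make_polygons(6, ncols = 3)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_polygons_geojson(ps, path)
  back <- read_country_polygons(path)
  expect_setequal(names(back$polygons), names(ps$polygons))
  for (iso in names(ps$adjacency)) {
    expect_setequal(back$adjacency[[iso]], ps$adjacency[[iso]])
    for (nb in back$adjacency[[iso]]) {
      expect_true(iso %in% back$adjacency[[nb]])
    }
  }
})
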