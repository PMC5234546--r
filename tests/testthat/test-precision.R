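# Independent oracle for decimal inference: expected code by exhaustive
# divisibility check over the eight granularities expressed in degrees.
oracle_code <- function(lat, lon) {
  gran <- c(1, 15 / 60, 5 / 60, 2 / 60, 1 / 60, 0.1 / 60, 0.01 / 60,
            0.001 / 60)
  for (code in 1:8) {
    r1 <- abs(lat) / gran[code]; r2 <- abs(lon) / gran[code]
    if (abs(r1 - round(r1)) < 1e-6 && abs(r2 - round(r2)) < 1e-6) {
      return(code)
    }
  }
  8L
}

test_that("verbatim sexagesimal granularity maps to the 1-8 accuracy codes", {
  expect_equal(assign_precision("4N 12E"), 1L, ignore_attr = TRUE)
  expect_equal(assign_precision("4°15'N 12°45'E"), 2L,
               ignore_attr = TRUE)                       # quarter-degree
  expect_equal(assign_precision("4°10'N 12°35'E"), 3L,
               ignore_attr = TRUE)                       # 5-minute
  expect_equal(assign_precision("4°14'N 12°32'E"), 4L,
               ignore_attr = TRUE)                       # 2-minute
  expect_equal(assign_precision("4°15'N 12°33'E"), 5L,
               ignore_attr = TRUE)                       # whole minute
  expect_equal(assign_precision("4°15.1'N 12°33.4'E"), 6L,
               ignore_attr = TRUE)
  expect_equal(assign_precision("4°15.12'N 12°33.45'E"), 7L,
               ignore_attr = TRUE)
  expect_equal(assign_precision("4°15.123'N 12°33.456'E"), 8L,
               ignore_attr = TRUE)
  # southern/western hemispheres and comma separators parse too
  expect_equal(assign_precision("4°15'S, 12°33'W"), 5L,
               ignore_attr = TRUE)
})

test_that("the record code is the granularity needed by both components", {
  # one component at quarter-degree, the other needing whole minutes
  expect_equal(assign_precision("4°15'N 12°33'E"), 5L,
               ignore_attr = TRUE)
  expect_equal(assign_precision("4°0'N 12°0'E"), 1L,
               ignore_attr = TRUE)   # explicit zero minutes = whole degrees
})

test_that("decimal inference matches the brute-force divisibility oracle", {
  expect_equal(assign_precision(lat = 4.0, lon = 12.0), 1L,
               ignore_attr = TRUE)
  expect_equal(assign_precision(lat = 4.2575, lon = 12.5503),
               oracle_code(4.2575, 12.5503), ignore_attr = TRUE)
  set.seed(31)
  gran <- c(1, 15 / 60, 5 / 60, 2 / 60, 1 / 60, 0.1 / 60, 0.01 / 60,
            0.001 / 60)
  for (i in 1:60) {
    code <- sample(1:8, 1)
    lat <- sample(0:5000, 1) * gran[code]
    lon <- sample(0:9000, 1) * gran[code]
    expect_equal(assign_precision(lat = lat, lon = lon),
                 oracle_code(lat, lon), ignore_attr = TRUE)
  }
  # coordinates matching no granularity are at least 1/1000-minute precise
  expect_equal(assign_precision(lat = 4.1234567, lon = 12.7654321), 8L,
               ignore_attr = TRUE)
})

test_that("precision coding is deterministic, idempotent and refinement-monotone", {
  v <- "4°15'N 12°33'E"
  expect_identical(assign_precision(v), assign_precision(v))
  # refining a coordinate (decimals of minutes added) never lowers the code
  chain <- c("4°15'N 12°30'E", "4°15.1'N 12°30.2'E",
             "4°15.12'N 12°30.24'E",
             "4°15.123'N 12°30.246'E")
  codes <- vapply(chain, function(s) as.integer(assign_precision(s)),
                  integer(1), USE.NAMES = FALSE)
  expect_true(all(diff(codes) >= 0))
  # the same holds on the decimal path
  dec_chain <- c(4, 4.25, 4 + 15 / 60 + 0.123 / 60)
  dec_codes <- vapply(dec_chain, function(x)
    as.integer(assign_precision(lat = x, lon = x)), integer(1))
  expect_true(all(diff(dec_codes) >= 0))
})

test_that("unparseable verbatim strings fall back to decimal inference with a warning", {
  expect_warning(code <- assign_precision("four north twelve east",
                                          lat = 4.25, lon = 12.25),
                 "falling back")
  expect_equal(as.integer(code), 2L)
  expect_error(suppressWarnings(assign_precision("four north")),
               "no usable coordinates")
})

test_that("per-record coding handles missing coordinates", {
  recs <- make_test_records(data.frame(
    record_id = c("p1", "p2", "p3"),
    latitude = c(4.25, NA, 4.5), longitude = c(12.25, NA, 12.55),
    verbatim_coordinates = c(NA, NA, "4°30'N 12°33'E")))
  out <- assign_precision_codes(recs)
  expect_equal(out$precision_code, c(2L, NA_integer_, 5L))
  expect_identical(assign_precision_codes(out)$precision_code,
                   out$precision_code)
})

test_that("codes map to the documented uncertainty scale", {
  expect_equal(precision_uncertainty_km(c(1, 5, 8)), c(110, 2, 0.002))
})
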