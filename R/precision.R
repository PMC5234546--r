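# Ordinal coordinate-accuracy coding. Codes 1-8 describe the granularity at
# which a coordinate pair was recorded, from whole degrees (~110 km) down to
# 1/1000 of a decimal minute (~2 m):
#
#   1  accurate to degree only        (~110 km)
#   2  15 minutes precision           (~30 km)
#   3  5 minutes precision            (~10 km)
#   4  2 minutes precision            (~4 km)
#   5  minute is exact                (~2 km)
#   6  1/10 decimal minute exact      (~200 m)
#   7  1/100 decimal minute exact     (~20 m)
#   8  1/1000 decimal minute exact    (~2 m)

# granularities in 1/1000 of a minute (integers, so divisibility is exact)
PRECISION_GRANULARITY_MILLIMIN <- c(60000, 15000, 5000, 2000, 1000, 100, 10, 1)

#' Approximate ground uncertainty of each precision code
#'
#' @param code integer vector of codes 1-8.
#' @return Uncertainty in km (110, 30, 10, 4, 2, 0.2, 0.02, 0.002).
#' @export
precision_uncertainty_km <- function(code) {
  stopifnot(all(is.na(code) | (code %in% 1:8)))
  c(110, 30, 10, 4, 2, 0.2, 0.02, 0.002)[code]
}

# Coarsest code (lowest number) whose granularity divides the value, values
# expressed in thousandths of a minute. NA when the value is not
# representable at 1/1000' (true decimal-degree data).
millimin_value <- function(deg) {
  v <- round(deg, 10) * 60000
  vi <- round(v)
  if (abs(v - vi) > 1e-3) return(NA_real_)
  vi
}

code_for_values <- function(values, max_code = 8L) {
  vs <- vapply(values, millimin_value, numeric(1))
  if (anyNA(vs)) return(8L)  # finer than 1/1000': no coarser class fits
  for (code in seq_len(max_code)) {
    if (all(vs %% PRECISION_GRANULARITY_MILLIMIN[code] == 0)) return(code)
  }
  8L
}

# ---- verbatim parsing ------------------------------------------------------

#' Parse a verbatim sexagesimal coordinate pair
#'
#' Accepts forms like `"4N 12E"`, `"4°15'N 12°33'E"`,
#' `"4°15.123'N, 12°33.456'E"`, with optional seconds. Hemisphere
#' letters are required to pair the two components.
#'
#' @param verbatim coordinate string.
#' @return List with `lat` and `lon` components, each a list
#'   (`degrees`, `minutes`, `minute_decimals`, `seconds`, `hemisphere`,
#'   `decimal_degrees`), or `NULL` if the string cannot be parsed.
#' @export
parse_verbatim_coordinates <- function(verbatim) {
  if (is.na(verbatim) || !nzchar(trimws(verbatim))) return(NULL)
  pat <- paste0(
    "(\\d+(?:\\.\\d+)?)\\s*(?:°|d\\b)?\\s*",          # degrees
    "(?:(\\d+(?:\\.\\d+)?)\\s*(?:'|′|m\\b)?\\s*)?",   # minutes
    "(?:(\\d+(?:\\.\\d+)?)\\s*(?:\"|″|s\\b)?\\s*)?",  # seconds
    "([NSEW])")
  m <- gregexpr(pat, verbatim, perl = TRUE)[[1]]
  if (length(m) != 2 || m[1] == -1) return(NULL)
  comps <- lapply(regmatches(verbatim, gregexpr(pat, verbatim, perl = TRUE))[[1]],
                  function(s) {
    g <- regmatches(s, regexec(pat, s, perl = TRUE))[[1]]
    deg_s <- g[2]; min_s <- g[3]; sec_s <- g[4]; hemi <- g[5]
    if (grepl("\\.", deg_s) && nzchar(min_s)) return(NULL)
    deg <- as.numeric(deg_s)
    mins <- if (nzchar(min_s)) as.numeric(min_s) else NA_real_
    secs <- if (nzchar(sec_s)) as.numeric(sec_s) else NA_real_
    mdec <- if (nzchar(min_s) && grepl("\\.", min_s)) {
      nchar(sub("^[^.]*\\.", "", min_s))
    } else 0L
    dd <- deg + (if (is.na(mins)) 0 else mins / 60) +
      (if (is.na(secs)) 0 else secs / 3600)
    if (hemi %in% c("S", "W")) dd <- -dd
    list(degrees = deg, minutes = mins, minute_decimals = mdec,
         seconds = secs, hemisphere = hemi, decimal_degrees = dd)
  })
  if (any(vapply(comps, is.null, logical(1)))) return(NULL)
  hemis <- vapply(comps, `[[`, character(1), "hemisphere")
  lat_i <- which(hemis %in% c("N", "S"))
  lon_i <- which(hemis %in% c("E", "W"))
  if (length(lat_i) != 1 || length(lon_i) != 1) return(NULL)
  list(lat = comps[[lat_i]], lon = comps[[lon_i]])
}

verbatim_component_code <- function(comp) {
  # degrees only -> candidate code 1; integer minutes -> codes 1-5 by
  # divisibility; decimal minutes -> code 5 + number of stated decimals
  if (is.na(comp$minutes) && is.na(comp$seconds)) {
    if (comp$degrees == floor(comp$degrees)) return(1L)
    return(code_for_values(abs(comp$decimal_degrees)))  # decimal degrees
  }
  if (comp$minute_decimals > 0 || !is.na(comp$seconds)) {
    v <- (if (is.na(comp$minutes)) 0 else comp$minutes) +
      (if (is.na(comp$seconds)) 0 else comp$seconds / 60)
    d <- comp$minute_decimals
    if (!is.na(comp$seconds)) {
      # seconds restated as decimal minutes: count the decimals they need
      for (k in 0:3) if (abs(v * 10^k - round(v * 10^k)) < 1e-9) break
      d <- max(d, k)
    }
    if (d == 0) return(code_for_values(abs(comp$decimal_degrees), 5L))
    return(as.integer(min(5L + d, 8L)))
  }
  code_for_values(abs(comp$decimal_degrees), 5L)
}

# ---- assignment ------------------------------------------------------------

#' Assign a coordinate precision code (1-8)
#'
#' When a parseable verbatim sexagesimal string is available the code is
#' derived from its stated granularity: degrees only give code 1; integer
#' minutes give codes 2-5 depending on whether the minutes are multiples of
#' 15, 5 or 2; decimal minutes with 1, 2 or 3 decimals give codes 6-8. The
#' record's code is the finer (larger) of the two component codes, i.e. the
#' granularity actually needed to write both components down.
#'
#' Without a usable verbatim string the code is inferred from the decimal
#' degrees: scanning from coarse to fine, the first granularity of which
#' both latitude and longitude are integer multiples (tolerance 1e-9 after
#' rounding to 10 decimals) determines the code; coordinates matching no
#' granularity are treated as at least as precise as 1/1000 minute (code 8).
#'
#' @param verbatim verbatim coordinate string, or `NA`.
#' @param lat,lon decimal coordinates (required when `verbatim` is absent
#'   or unparseable).
#' @return Integer code in 1-8, with the approximate uncertainty in km as
#'   attribute `uncertainty_km`.
#' @export
assign_precision <- function(verbatim = NA_character_, lat = NA_real_,
                             lon = NA_real_) {
  code <- NA_integer_
  if (!is.na(verbatim) && nzchar(trimws(verbatim))) {
    parsed <- parse_verbatim_coordinates(verbatim)
    if (!is.null(parsed)) {
      code <- max(verbatim_component_code(parsed$lat),
                  verbatim_component_code(parsed$lon))
    } else {
      warning("unparseable verbatim coordinates: ", verbatim,
              " - falling back to decimal inference")
    }
  }
  if (is.na(code)) {
    if (is.na(lat) || is.na(lon)) stop("no usable coordinates to code")
    code <- code_for_values(c(abs(lat), abs(lon)))
  }
  structure(as.integer(code), uncertainty_km = precision_uncertainty_km(code))
}

#' Assign precision codes to every record
#'
#' @param records an `occ_records` table.
#' @return The records with an integer `precision_code` column added
#'   (`NA` for records without usable coordinates).
#' @export
assign_precision_codes <- function(records) {
  codes <- rep(NA_integer_, nrow(records))
  for (i in seq_len(nrow(records))) {
    has_vb <- !is.na(records$verbatim_coordinates[i])
    if (!records$coord_valid[i] && !has_vb) next
    codes[i] <- tryCatch(
      suppressWarnings(assign_precision(
        records$verbatim_coordinates[i],
        records$latitude[i], records$longitude[i])),
      error = function(e) NA_integer_)
  }
  records$precision_code <- codes
  records
}
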