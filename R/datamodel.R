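#' Canonical occurrence-record fields
#'
#' Column names (and order) of the canonical occurrence table used by every
#' stage of the pipeline. Taxon names are stored structured (family, genus,
#' species epithet, infraspecific rank + epithet, authorship); coordinates
#' are decimal degrees on WGS84; dates are `Date` or `NA`.
#'
#' @return Character vector of canonical column names.
#' @export
occ_fields <- function() {
  c("record_id", "source_id", "source_kind",
    "family", "genus", "species", "infra_rank", "infra_epithet", "authorship",
    "identification_date", "country_code",
    "latitude", "longitude", "verbatim_coordinates",
    "locality", "description",
    "collector", "collector_number", "collection_date")
}

occ_source_kinds <- function() c("institutional", "personal", "silica", "plot")

audit_stages <- function() c("geo", "taxonomy", "dedup", "flags", "habit")
audit_actions <- function() c("kept", "discarded", "modified", "merged")

#' Column mapping from a source CSV to the canonical fields
#'
#' Returns a named character vector mapping canonical field names to column
#' names in the input file. Defaults cover the canonical names themselves
#' plus common Darwin Core terms (`decimalLatitude`, `recordedBy`,
#' `recordNumber`, ...). Override any entry by name, e.g.
#' `occ_column_mapping(latitude = "LAT", collector = "leg")`.
#'
#' @param ... named overrides, `canonical_field = "source column"`.
#' @return Named list: each canonical field maps to a character vector of
#'   accepted source column names (first match wins).
#' @export
occ_column_mapping <- function(...) {
  mapping <- list(
    record_id            = c("record_id", "occurrenceID", "id"),
    source_id            = c("source_id", "datasetID", "institutionCode"),
    source_kind          = c("source_kind", "basisOfRecord"),
    family               = c("family"),
    genus                = c("genus"),
    species              = c("species", "specificEpithet"),
    infra_rank           = c("infra_rank", "taxonRank"),
    infra_epithet        = c("infra_epithet", "infraspecificEpithet"),
    authorship           = c("authorship", "scientificNameAuthorship"),
    identification_date  = c("identification_date", "dateIdentified"),
    country_code         = c("country_code", "countryCode", "country"),
    latitude             = c("latitude", "decimalLatitude"),
    longitude            = c("longitude", "decimalLongitude"),
    verbatim_coordinates = c("verbatim_coordinates", "verbatimCoordinates"),
    locality             = c("locality", "verbatimLocality"),
    description          = c("description", "occurrenceRemarks"),
    collector            = c("collector", "recordedBy"),
    collector_number     = c("collector_number", "recordNumber"),
    collection_date      = c("collection_date", "eventDate")
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(mapping))
    if (length(bad)) stop("unknown canonical field(s): ", paste(bad, collapse = ", "))
    mapping[names(dots)] <- lapply(dots, as.character)
  }
  mapping
}

#' Date formats tried when parsing record dates
#'
#' ISO-8601 first, then a fallback list. Strings matching none parse to `NA`
#' (a missing date, never a guess).
#'
#' @return Character vector of `strptime` formats.
#' @export
occ_date_formats <- function() {
  c("%Y-%m-%d", "%Y/%m/%d", "%d/%m/%Y", "%d-%m-%Y", "%Y%m%d")
}

#' Parse dates with a format fallback list
#'
#' @param x character vector.
#' @param formats formats tried in order; see [occ_date_formats()].
#' @return `Date` vector; unparseable entries are `NA`.
#' @export
parse_occ_date <- function(x, formats = occ_date_formats()) {
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  todo <- !is.na(x) & nzchar(trimws(x))
  for (fmt in formats) {
    if (!any(todo)) break
    parsed <- as.Date(x[todo], format = fmt)
    # strptime ignores trailing text; only accept parses that reproduce the
    # input exactly, so "10/05/1999" is never read as year 10
    ok <- !is.na(parsed) & format(parsed, fmt) == trimws(x[todo])
    out[which(todo)[ok]] <- parsed[ok]
    todo[which(todo)[ok]] <- FALSE
  }
  out
}

# ---- audit log -------------------------------------------------------------

#' Create audit-log entries
#'
#' The audit log is the pipeline's book-keeping: every record discarded,
#' modified or merged at any stage leaves at least one entry, so that
#' `records in = kept + discarded` can be verified after every stage.
#'
#' @param record_id character vector of record ids.
#' @param stage one of `geo`, `taxonomy`, `dedup`, `flags`, `habit`.
#' @param action one of `kept`, `discarded`, `modified`, `merged`.
#' @param reason free-text reason, recycled.
#' @return data.frame with columns `record_id`, `stage`, `action`, `reason`.
#' @export
audit_entries <- function(record_id, stage, action, reason) {
  stage <- match.arg(stage, audit_stages())
  action <- match.arg(action, audit_actions())
  if (length(record_id) == 0) return(empty_audit())
  data.frame(record_id = as.character(record_id), stage = stage,
             action = action, reason = as.character(reason),
             stringsAsFactors = FALSE)
}

#' @rdname audit_entries
#' @export
empty_audit <- function() {
  data.frame(record_id = character(), stage = character(),
             action = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Retrieve the audit log attached to a record table
#'
#' @param records an `occ_records` table.
#' @return data.frame of audit entries (possibly empty).
#' @export
occ_audit <- function(records) {
  a <- attr(records, "audit", exact = TRUE)
  if (is.null(a)) empty_audit() else a
}

set_audit <- function(records, audit) {
  attr(records, "audit") <- audit
  records
}

bind_audit <- function(...) {
  do.call(rbind, Filter(Negate(is.null), list(...)))
}

# ---- construction / validation --------------------------------------------

#' Build a canonical occurrence table from a data.frame
#'
#' Coerces columns to their canonical types, validates coordinates
#' (latitude in \[-90, 90\], longitude in \[-180, 180\]) and record-id
#' uniqueness, and attaches an audit log. Out-of-range or unparseable
#' coordinates never fail the load: the record is kept, its coordinates are
#' marked invalid, and an audit entry explains why.
#'
#' @param df data.frame containing (a subset of) the canonical fields.
#' @param date_formats see [occ_date_formats()].
#' @return An `occ_records` data.frame with all canonical columns plus a
#'   logical `coord_valid` column, audit log in `occ_audit()`.
#' @export
as_occ_records <- function(df, date_formats = occ_date_formats()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  audit <- empty_audit()
  for (f in c("record_id", "genus")) {
    if (!f %in% names(df)) stop("missing mandatory column: ", f)
  }
  chr_fields <- setdiff(occ_fields(),
                        c("identification_date", "collection_date",
                          "latitude", "longitude"))
  for (f in chr_fields) {
    df[[f]] <- if (f %in% names(df)) as.character(df[[f]]) else NA_character_
    df[[f]][!is.na(df[[f]]) & !nzchar(trimws(df[[f]]))] <- NA_character_
  }
  for (f in c("identification_date", "collection_date")) {
    df[[f]] <- if (!f %in% names(df)) as.Date(rep(NA_character_, nrow(df)))
               else if (inherits(df[[f]], "Date")) df[[f]]
               else parse_occ_date(df[[f]], date_formats)
  }
  for (f in c("latitude", "longitude")) {
    raw <- if (f %in% names(df)) df[[f]] else rep(NA_real_, nrow(df))
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & nzchar(trimws(as.character(raw))) & is.na(num)
    if (any(bad)) {
      audit <- bind_audit(audit, audit_entries(
        df$record_id[bad], "geo", "modified", paste("unparseable", f)))
    }
    df[[f]] <- num
  }
  lat_bad <- !is.na(df$latitude) & abs(df$latitude) > 90
  lon_bad <- !is.na(df$longitude) & abs(df$longitude) > 180
  if (any(lat_bad)) {
    audit <- bind_audit(audit, audit_entries(
      df$record_id[lat_bad], "geo", "modified", "lat out of range"))
  }
  if (any(lon_bad)) {
    audit <- bind_audit(audit, audit_entries(
      df$record_id[lon_bad], "geo", "modified", "lon out of range"))
  }
  kind <- tolower(trimws(df$source_kind))
  kind[!is.na(kind) & !kind %in% occ_source_kinds()] <- NA_character_
  df$source_kind <- kind
  if (anyDuplicated(df$record_id)) {
    stop("record_id values are not unique: ",
         paste(unique(df$record_id[duplicated(df$record_id)])[1:3], collapse = ", "))
  }
  df$coord_valid <- !is.na(df$latitude) & !is.na(df$longitude) &
    !lat_bad & !lon_bad
  df <- df[c(occ_fields(), "coord_valid")]
  rownames(df) <- NULL
  class(df) <- c("occ_records", "data.frame")
  set_audit(df, audit)
}

#' Read occurrence records from a CSV file
#'
#' Reads a UTF-8 CSV (RFC 4180) with a header row, maps columns through a
#' configurable mapping (so Darwin Core exports load directly), and returns
#' the canonical occurrence table. Row count is preserved: unparseable
#' coordinates or dates become missing values with audit entries, never a
#' failure. Missing mandatory columns (record id, taxon name) are a hard
#' error naming the column.
#'
#' @param path CSV file path.
#' @param mapping see [occ_column_mapping()].
#' @param date_formats see [occ_date_formats()].
#' @return An `occ_records` table; see [as_occ_records()].
#' @export
read_records <- function(path, mapping = occ_column_mapping(),
                         date_formats = occ_date_formats()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "", fileEncoding = "UTF-8")
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in names(mapping)) {
    hit <- intersect(mapping[[f]], names(raw))
    if (length(hit)) {
      df[[f]] <- raw[[hit[1]]]
    } else if (f %in% c("record_id", "genus")) {
      stop("missing mandatory column: ", f,
           " (accepted names: ", paste(mapping[[f]], collapse = ", "), ")")
    }
  }
  as_occ_records(df, date_formats)
}

#' Write occurrence records to CSV
#'
#' Writes the canonical columns in stable order, UTF-8, missing values as
#' empty cells, dates as ISO-8601. `read_records(write_records(x))` is
#' field-wise lossless, and output is byte-stable across repeated writes.
#'
#' @param records an `occ_records` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- as.data.frame(records)[occ_fields()]
  for (f in c("identification_date", "collection_date")) {
    out[[f]] <- format(out[[f]], "%Y-%m-%d")
  }
  for (f in c("latitude", "longitude")) {
    out[[f]] <- vapply(out[[f]], function(v)
      if (is.na(v)) NA_character_ else as.character(v), character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Full taxon name of each record
#'
#' Assembles genus + species epithet (+ infraspecific rank and epithet) into
#' the name string used for backbone matching.
#'
#' @param records an `occ_records` table (or any data.frame with the name
#'   part columns).
#' @return Character vector of names.
#' @export
taxon_name <- function(records) {
  parts <- mapply(function(g, s, r, ie) {
    toks <- c(g, s)
    if (!is.na(ie)) toks <- c(toks, if (!is.na(r)) r, ie)
    paste(toks[!is.na(toks)], collapse = " ")
  }, records$genus, records$species, records$infra_rank,
     records$infra_epithet, USE.NAMES = FALSE)
  as.character(parts)
}

#' Taxonomic rank specificity of each record's identification
#'
#' @param records an `occ_records` table.
#' @return Integer: 1 = genus only, 2 = species, 3 = infraspecific. Higher
#'   means more specific ("lowest" rank in the herbarium sense).
#' @export
rank_specificity <- function(records) {
  ifelse(!is.na(records$infra_epithet), 3L,
         ifelse(!is.na(records$species), 2L, 1L))
}

# ---- country codes ---------------------------------------------------------

#' Country name to ISO-3166 alpha-3 lookup table
#'
#' @return data.frame with columns `name`, `iso3`.
#' @export
country_code_table <- function() {
  utils::read.csv(system.file("extdata", "country_codes.csv",
                              package = "occurclean"),
                  stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Normalize country names or codes to ISO-3166 alpha-3
#'
#' Three-letter inputs pass through upper-cased; otherwise names are matched
#' case-insensitively against the shipped lookup table. Unmatched values
#' yield `NA` with a warning.
#'
#' @param x character vector of country names or codes.
#' @param table lookup table, see [country_code_table()].
#' @return Character vector of alpha-3 codes (or `NA`).
#' @export
normalize_country <- function(x, table = country_code_table()) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  trimmed <- trimws(x)
  is_code <- !is.na(trimmed) & grepl("^[A-Za-z]{3}$", trimmed)
  out[is_code] <- toupper(trimmed[is_code])
  idx <- match(tolower(trimmed[!is_code]), tolower(table$name))
  out[!is_code] <- table$iso3[idx]
  unmatched <- !is.na(trimmed) & nzchar(trimmed) & is.na(out)
  if (any(unmatched)) {
    warning("unmatched country name(s): ",
            paste(unique(trimmed[unmatched]), collapse = ", "))
  }
  out
}

#' @export
print.occ_records <- function(x, ...) {
  cat(sprintf("<occ_records: %d records, %d with valid coordinates, %d audit entries>\n",
              nrow(x), sum(x$coord_valid), nrow(occ_audit(x))))
  NextMethod()
}
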