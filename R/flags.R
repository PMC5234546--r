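# Flagging of non-natural occurrences: ex-situ collection localities
# (botanical gardens and the like, detected from locality text) and
# introduced/cultivated taxa (rarely-collected species whose external range
# lies mostly outside the study region).

#' Default ex-situ locality keywords
#'
#' Case-insensitive substrings that flag a locality description as a
#' possible ex-situ (cultivated) collection site. Editable / replaceable;
#' matches are *candidates* for review, not automatic discards.
#'
#' @return Character vector of keywords.
#' @export
default_ex_situ_keywords <- function() {
  c("botanical garden", "botanic garden", "jardin botanique", "hortus",
    "arboretum", "cultivated", "cultivation", "planted", "plantation",
    "nursery", "garden")
}

#' Screen locality text for ex-situ collection sites
#'
#' Builds a preliminary list of locality descriptions matching any keyword.
#' Records from localities confirmed as ex-situ (the `confirmed` list, the
#' product of manual review) are discarded with audit entries; matched but
#' unconfirmed localities are returned as a review table and their records
#' kept. Records with empty localities are kept.
#'
#' @param records an `occ_records` table.
#' @param keywords case-insensitive substrings; see
#'   [default_ex_situ_keywords()].
#' @param confirmed character vector of locality strings confirmed as
#'   ex-situ collection sites (`NULL`: nothing confirmed yet, everything
#'   matched goes to review).
#' @return List: `records` (kept), `discarded`, `flags` (one row per
#'   matched locality: `locality`, `keyword`, `decision`, `n_records`),
#'   `review` (the unconfirmed subset of `flags`), `audit`.
#' @export
screen_localities <- function(records, keywords = default_ex_situ_keywords(),
                              confirmed = NULL) {
  loc <- records$locality
  matched_kw <- rep(NA_character_, nrow(records))
  for (kw in keywords) {
    hit <- is.na(matched_kw) & !is.na(loc) &
      grepl(kw, loc, ignore.case = TRUE, fixed = FALSE)
    matched_kw[hit] <- kw
  }
  matched <- !is.na(matched_kw)
  is_conf <- matched & loc %in% confirmed
  flags <- unique(data.frame(
    locality = loc[matched], keyword = matched_kw[matched],
    decision = ifelse(loc[matched] %in% confirmed, "ex_situ", "natural"),
    stringsAsFactors = FALSE))
  if (nrow(flags)) {
    flags$n_records <- vapply(flags$locality,
                              function(l) sum(loc == l, na.rm = TRUE),
                              integer(1), USE.NAMES = FALSE)
    flags <- flags[order(flags$locality), , drop = FALSE]
    rownames(flags) <- NULL
  } else {
    flags$n_records <- integer(0)
  }
  audit <- audit_entries(records$record_id[is_conf], "flags", "discarded",
                         paste0("ex-situ locality: ", loc[is_conf]))
  kept <- records[!is_conf, , drop = FALSE]
  discarded <- records[is_conf, , drop = FALSE]
  class(kept) <- class(records); class(discarded) <- class(records)
  kept <- set_audit(kept, bind_audit(occ_audit(records), audit))
  list(records = kept, discarded = discarded, flags = flags,
       review = flags[flags$decision == "natural", , drop = FALSE],
       audit = audit)
}

species_binomial <- function(records) {
  ifelse(is.na(records$species), records$genus,
         paste(records$genus, records$species))
}

region_contains <- function(lon, lat, region) {
  if (is.matrix(region)) region <- list(region)
  region <- lapply(region, function(r) {
    if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
    r
  })
  for (r in region) if (point_on_ring(lon, lat, r)) return(TRUE)
  sum(vapply(region, function(r) ring_crossings(lon, lat, r),
             integer(1))) %% 2L == 1L
}

#' Find candidate introduced/cultivated species
#'
#' Introduced or cultivated taxa are expected among the rarely-collected
#' species: every species with fewer than `threshold` records in the data
#' is checked against an external occurrence source, and species whose
#' external records fall mostly (fraction > `outside_fraction`) outside the
#' study region are marked `introduced_candidate` for manual confirmation.
#' Species with no external records stay `native` (no evidence); when no
#' external source is available the decision is `deferred`, never silently
#' dropped.
#'
#' @param records an `occ_records` table (deduplicated and standardized).
#' @param threshold species with fewer than this many records are screened
#'   (default 11, i.e. "fewer than eleven records").
#' @param external_source `NULL`, or a function `(species) -> data.frame`
#'   with columns `longitude`, `latitude` of occurrences from an external
#'   aggregator.
#' @param region study-region polygon: a ring matrix (lon, lat) or list of
#'   rings.
#' @param outside_fraction candidates need more than this fraction of
#'   external records outside the region (default 0.5).
#' @return data.frame: `species`, `n_records_internal`,
#'   `n_records_external`, `fraction_outside`, `decision` in
#'   `c("native", "introduced_candidate", "deferred")`.
#' @export
find_introduced_candidates <- function(records, threshold = 11,
                                       external_source = NULL, region = NULL,
                                       outside_fraction = 0.5) {
  sp <- species_binomial(records)
  counts <- table(sp)
  out <- data.frame(species = names(counts),
                    n_records_internal = as.integer(counts),
                    n_records_external = NA_integer_,
                    fraction_outside = NA_real_,
                    decision = "native", stringsAsFactors = FALSE)
  rare <- out$n_records_internal < threshold
  for (i in which(rare)) {
    if (is.null(external_source)) {
      out$decision[i] <- "deferred"
      next
    }
    ext <- external_source(out$species[i])
    n_ext <- if (is.null(ext)) 0L else nrow(ext)
    out$n_records_external[i] <- n_ext
    if (n_ext == 0) next   # no evidence: stays native
    inside <- vapply(seq_len(n_ext), function(j)
      region_contains(ext$longitude[j], ext$latitude[j], region), logical(1))
    out$fraction_outside[i] <- mean(!inside)
    if (out$fraction_outside[i] > outside_fraction) {
      out$decision[i] <- "introduced_candidate"
    }
  }
  out
}

#' Remove records of confirmed introduced/cultivated species
#'
#' @param records an `occ_records` table.
#' @param confirmed character vector of species binomials confirmed as
#'   introduced or cultivated (the reviewed candidate list). Listed species
#'   absent from the data only raise a warning.
#' @return List: `records` (kept, audit log extended), `removed`, `audit`.
#' @export
apply_introduced_list <- function(records, confirmed) {
  sp <- species_binomial(records)
  missing <- setdiff(confirmed, sp)
  if (length(missing)) {
    warning("listed species absent from data: ",
            paste(missing, collapse = ", "))
  }
  drop <- sp %in% confirmed
  audit <- audit_entries(records$record_id[drop], "flags", "discarded",
                         paste0("introduced/cultivated species: ", sp[drop]))
  kept <- records[!drop, , drop = FALSE]
  removed <- records[drop, , drop = FALSE]
  class(kept) <- class(records); class(removed) <- class(records)
  kept <- set_audit(kept, bind_audit(occ_audit(records), audit))
  list(records = kept, removed = removed, audit = audit)
}
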