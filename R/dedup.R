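# Herbarium duplicate detection and merging. Sheets from one gathering
# (same collector, collector number, collection date) distributed to several
# herbaria are clustered on a normalized match key and merged; conflicting
# identifications and georeferences are resolved by priority cascades.

#' Duplicate-matching configuration
#'
#' @param collector_similarity minimum normalized edit similarity between
#'   normalized collector strings for a fuzzy match (default 0.85).
#' @param require_genus_without_number when the collector number is absent,
#'   require exact genus agreement in the match key (default `TRUE`).
#' @return A `dedup_config` list.
#' @export
dedup_config <- function(collector_similarity = 0.85,
                         require_genus_without_number = TRUE) {
  stopifnot(collector_similarity >= 0, collector_similarity <= 1)
  structure(list(collector_similarity = collector_similarity,
                 require_genus_without_number = require_genus_without_number),
            class = "dedup_config")
}

#' Normalize a collector name for matching
#'
#' Case-folds, transliterates diacritics, strips punctuation, drops
#' single-letter tokens (initials), and sorts the remaining tokens, so that
#' `"Fontaine, A.B."` and `"A.B. Fontaine"` normalize identically.
#'
#' @param x character vector of collector strings.
#' @return Character vector of normalized surname-token keys.
#' @export
normalize_collector <- function(x) {
  vapply(as.character(x), function(s) {
    if (is.na(s)) return(NA_character_)
    s <- tolower(iconv(s, to = "ASCII//TRANSLIT"))
    s <- gsub("[^a-z0-9]+", " ", s)
    toks <- strsplit(trimws(s), "\\s+")[[1]]
    toks <- toks[nchar(toks) > 1]
    if (!length(toks)) return(NA_character_)
    paste(sort(unique(toks)), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

collector_similarity <- function(a, b) {
  if (is.na(a) || is.na(b)) return(0)
  1 - utils::adist(a, b)[1, 1] / max(nchar(a), nchar(b))
}

# deterministic pick used by the "random" cascade steps: keyed on the sorted
# member ids and the caller's seed, never on input order
id_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

deterministic_pick <- function(ids, seed) {
  ids <- sort(ids)
  h <- id_hash(paste(ids, collapse = "|"))
  ids[(h + as.integer(seed)) %% length(ids) + 1]
}

# ---- clustering ------------------------------------------------------------

#' Find duplicate clusters
#'
#' Records sharing a normalized match key — normalized collector (fuzzy, see
#' [dedup_config()]), normalized collector number, and collection year —
#' are clustered; when the collector number is absent, exact genus agreement
#' is additionally required. Singletons are excluded; the clustering is a
#' partition of the clustered records.
#'
#' @param records an `occ_records` table.
#' @param config a [dedup_config()].
#' @return data.frame `cluster_id`, `record_id`, `match_key`, one row per
#'   member of each multi-member cluster.
#' @export
find_duplicates <- function(records, config = dedup_config()) {
  n <- nrow(records)
  empty <- data.frame(cluster_id = integer(), record_id = character(),
                      match_key = character(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  coll <- normalize_collector(records$collector)
  num <- toupper(gsub("[^A-Za-z0-9]", "", as.character(records$collector_number)))
  num[is.na(num) | !nzchar(num)] <- NA_character_
  year <- ifelse(is.na(records$collection_date), "?",
                 format(records$collection_date, "%Y"))
  block <- ifelse(!is.na(num),
                  paste0("N:", num, "|", year),
                  paste0("C:", ifelse(is.na(coll), "?", coll), "|",
                         if (config$require_genus_without_number)
                           records$genus else "", "|", year))
  groups <- split(seq_len(n), block)
  out <- list()
  for (idx in groups) {
    if (length(idx) < 2) next
    if (startsWith(block[idx[1]], "N:")) {
      # fuzzy single-linkage on normalized collectors within the block
      comp <- seq_along(idx)
      cs <- coll[idx]
      for (i in seq_along(idx)) {
        for (j in seq_len(i - 1)) {
          sim <- if (!is.na(cs[i]) && !is.na(cs[j]) && cs[i] == cs[j]) 1
                 else collector_similarity(cs[i], cs[j])
          if (sim >= config$collector_similarity) {
            old <- comp[i]; comp[comp == old] <- comp[j]
          }
        }
      }
      for (cpt in unique(comp)) {
        members <- idx[comp == cpt]
        if (length(members) >= 2) out[[length(out) + 1]] <- members
      }
    } else {
      out[[length(out) + 1]] <- idx
    }
  }
  if (!length(out)) return(empty)
  # deterministic cluster numbering by smallest member record_id
  first_id <- vapply(out, function(m) min(records$record_id[m]), character(1))
  out <- out[order(first_id)]
  do.call(rbind, lapply(seq_along(out), function(k) {
    m <- out[[k]]
    data.frame(cluster_id = k,
               record_id = records$record_id[m],
               match_key = block[m],
               stringsAsFactors = FALSE)
  }))
}

# ---- resolution cascades ---------------------------------------------------

#' Choose the most reliable identification in a duplicate cluster
#'
#' Cascade, in order: (1) an identification from a personal (expert-curated)
#' database wins over institutional ones; (2) otherwise the most recent
#' identification date wins; (3) otherwise the identification at the lowest
#' (most specific) taxonomic rank wins; (4) otherwise a member is chosen
#' reproducibly from the sorted record ids and the seed. Each step narrows
#' the candidate set; `rule` records the step that singled out the winner.
#'
#' @param members `occ_records` rows of one cluster (>= 2 rows).
#' @param seed integer seed for the final reproducible-random step.
#' @return List: `record_id` of the winner, `rule` in
#'   `c("personal", "most_recent_date", "lowest_rank", "random")`.
#' @export
resolve_identification <- function(members, seed = 1) {
  stopifnot(nrow(members) >= 2)
  cand <- members[order(members$record_id), , drop = FALSE]
  personal <- !is.na(cand$source_kind) & cand$source_kind == "personal"
  if (any(personal) && !all(personal)) {
    cand <- cand[personal, , drop = FALSE]
    if (nrow(cand) == 1) {
      return(list(record_id = cand$record_id, rule = "personal"))
    }
  }
  d <- cand$identification_date
  if (any(!is.na(d))) {
    win <- which(!is.na(d) & d == max(d, na.rm = TRUE))
    if (length(win) == 1) {
      return(list(record_id = cand$record_id[win], rule = "most_recent_date"))
    }
    cand <- cand[win, , drop = FALSE]
  }
  rs <- rank_specificity(cand)
  win <- which(rs == max(rs))
  if (length(win) == 1) {
    return(list(record_id = cand$record_id[win], rule = "lowest_rank"))
  }
  cand <- cand[win, , drop = FALSE]
  list(record_id = deterministic_pick(cand$record_id, seed), rule = "random")
}

#' Choose the most reliable georeference in a duplicate cluster
#'
#' Cascade, in order: (1) a member that passed the documented-country check
#' wins over members that did not; (2) otherwise a personal-database
#' georeference wins over institutional ones; (3) otherwise the highest
#' coordinate precision code wins; (4) otherwise a reproducible seeded
#' choice.
#'
#' @param members `occ_records` rows of one cluster (>= 2 rows).
#' @param passed named logical vector (names = record ids): did the member
#'   pass the country check? Missing/`NULL` means all passed.
#' @param codes named integer vector of precision codes (1-8); missing
#'   entries are treated as unknown.
#' @param seed integer seed for the final step.
#' @return List: `record_id`, `rule` in `c("passed_country_check",
#'   "personal", "highest_precision", "random")`.
#' @export
resolve_coordinates <- function(members, passed = NULL, codes = NULL,
                                seed = 1) {
  stopifnot(nrow(members) >= 2)
  cand <- members[order(members$record_id), , drop = FALSE]
  if (!is.null(passed)) {
    p <- passed[cand$record_id]
    p[is.na(p)] <- TRUE
    if (any(p) && !all(p)) {
      cand <- cand[p, , drop = FALSE]
      if (nrow(cand) == 1) {
        return(list(record_id = cand$record_id, rule = "passed_country_check"))
      }
    }
  }
  personal <- !is.na(cand$source_kind) & cand$source_kind == "personal"
  if (any(personal) && !all(personal)) {
    cand <- cand[personal, , drop = FALSE]
    if (nrow(cand) == 1) {
      return(list(record_id = cand$record_id, rule = "personal"))
    }
  }
  if (!is.null(codes)) {
    k <- codes[cand$record_id]
    if (any(!is.na(k))) {
      win <- which(!is.na(k) & k == max(k, na.rm = TRUE))
      if (length(win) == 1) {
        return(list(record_id = cand$record_id[win], rule = "highest_precision"))
      }
      cand <- cand[win, , drop = FALSE]
    }
  }
  list(record_id = deterministic_pick(cand$record_id, seed), rule = "random")
}

# ---- merging ---------------------------------------------------------------

first_non_missing <- function(x) {
  i <- which(!is.na(x))
  if (length(i)) x[i[1]] else x[1]
}

merge_cluster <- function(members, passed = NULL, codes = NULL, seed = 1) {
  members <- members[order(members$record_id), , drop = FALSE]
  idw <- resolve_identification(members, seed)
  cow <- resolve_coordinates(members, passed, codes, seed)
  id_row <- members[members$record_id == idw$record_id, , drop = FALSE]
  co_row <- members[members$record_id == cow$record_id, , drop = FALSE]
  consensus <- members[1, , drop = FALSE]       # smallest record_id
  id_fields <- c("source_id", "source_kind", "family", "genus", "species",
                 "infra_rank", "infra_epithet", "authorship",
                 "identification_date")
  co_fields <- c("latitude", "longitude", "verbatim_coordinates",
                 "country_code", "coord_valid")
  consensus[id_fields] <- id_row[id_fields]
  consensus[co_fields] <- co_row[co_fields]
  for (f in c("locality", "description", "collector", "collector_number",
              "collection_date")) {
    consensus[[f]] <- first_non_missing(members[[f]])
  }
  list(consensus = consensus, id_winner = idw, coord_winner = cow)
}

#' Merge duplicate clusters into consensus records
#'
#' Runs both resolution cascades on every cluster and replaces its members
#' by one consensus record: identification fields from the identification
#' winner, coordinate fields from the coordinate winner, remaining fields
#' unioned (first non-missing over members in record-id order). Output is
#' sorted by record id, so the result is invariant under shuffling of the
#' input rows.
#'
#' @param records an `occ_records` table.
#' @param clusters output of [find_duplicates()]; computed if `NULL`.
#' @param geo_results results data.frame from [geo_validate()] (used for
#'   the passed-country-check cascade step), or `NULL`.
#' @param precision_codes named integer vector of precision codes; when
#'   `NULL` and the records carry a `precision_code` column it is used.
#' @param seed integer seed for the reproducible-random steps.
#' @param config a [dedup_config()] (used only if `clusters` is `NULL`).
#' @return List: `records` (merged table, audit log extended), `clusters`
#'   (per-cluster summary with winners and rules used), `audit`.
#' @export
merge_duplicates <- function(records, clusters = NULL, geo_results = NULL,
                             precision_codes = NULL, seed = 1,
                             config = dedup_config()) {
  if (is.null(clusters)) clusters <- find_duplicates(records, config)
  passed <- NULL
  if (!is.null(geo_results)) {
    passed <- stats::setNames(geo_results$verdict == "keep",
                              geo_results$record_id)
  }
  if (is.null(precision_codes) && "precision_code" %in% names(records)) {
    precision_codes <- stats::setNames(records$precision_code,
                                       records$record_id)
  }
  audit <- empty_audit()
  summaries <- list()
  consensus_rows <- list()
  clustered_ids <- character(0)
  for (k in unique(clusters$cluster_id)) {
    ids <- clusters$record_id[clusters$cluster_id == k]
    members <- records[records$record_id %in% ids, , drop = FALSE]
    m <- merge_cluster(members, passed, precision_codes, seed)
    consensus_rows[[length(consensus_rows) + 1]] <- m$consensus
    clustered_ids <- c(clustered_ids, ids)
    absorbed <- setdiff(ids, m$consensus$record_id)
    audit <- bind_audit(audit,
      audit_entries(absorbed, "dedup", "merged",
                    paste0("merged into ", m$consensus$record_id)))
    summaries[[length(summaries) + 1]] <- data.frame(
      cluster_id = k, size = length(ids),
      members = paste(sort(ids), collapse = ";"),
      consensus_id = m$consensus$record_id,
      id_winner = m$id_winner$record_id, id_rule = m$id_winner$rule,
      coord_winner = m$coord_winner$record_id, coord_rule = m$coord_winner$rule,
      stringsAsFactors = FALSE)
  }
  singletons <- records[!records$record_id %in% clustered_ids, , drop = FALSE]
  merged <- rbind(singletons, do.call(rbind, consensus_rows))
  merged <- merged[order(merged$record_id), , drop = FALSE]
  rownames(merged) <- NULL
  class(merged) <- class(records)
  merged <- set_audit(merged, bind_audit(occ_audit(records), audit))
  list(records = merged,
       clusters = if (length(summaries)) do.call(rbind, summaries) else
         data.frame(),
       audit = audit)
}
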