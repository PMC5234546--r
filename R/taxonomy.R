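# Taxonomic name standardization against a local backbone table. The
# backbone links each name to its accepted name, which lets heterogeneous
# name usage (misspellings, synonyms) be rewritten to one canonical form.
# Name matching is a local emulation of an online resolution service:
# genus and epithet are scored separately by normalized Levenshtein
# similarity and combined into an overall score in [0, 1], 1 iff the
# submitted string matches a backbone name exactly.

#' Load or validate a taxonomic backbone
#'
#' @param x a CSV path or data.frame with columns `name_id`, `name`,
#'   `rank`, `status` (`accepted`, `synonym` or `unresolved`),
#'   `accepted_name_id`.
#' @return A validated `backbone` data.frame. Accepted entries must
#'   self-link; synonym entries must link to an accepted entry (so links
#'   are acyclic by construction).
#' @export
read_backbone <- function(x) {
  bb <- if (is.character(x)) {
    utils::read.csv(x, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  need <- c("name_id", "name", "rank", "status", "accepted_name_id")
  miss <- setdiff(need, names(bb))
  if (length(miss)) stop("backbone missing column(s): ",
                         paste(miss, collapse = ", "))
  bb$name_id <- as.character(bb$name_id)
  bb$accepted_name_id <- as.character(bb$accepted_name_id)
  if (!all(bb$status %in% c("accepted", "synonym", "unresolved"))) {
    stop("backbone status must be accepted/synonym/unresolved")
  }
  acc <- bb$status == "accepted"
  if (any(bb$accepted_name_id[acc] != bb$name_id[acc])) {
    stop("accepted backbone entries must self-link")
  }
  syn <- bb$status == "synonym"
  tgt <- match(bb$accepted_name_id[syn], bb$name_id)
  if (anyNA(tgt) || any(bb$status[tgt] != "accepted")) {
    stop("synonym entries must link to an accepted entry")
  }
  if (anyDuplicated(bb$name_id)) stop("backbone name_id not unique")
  class(bb) <- c("backbone", "data.frame")
  bb
}

accepted_name_of <- function(backbone, name_id) {
  tgt <- backbone$accepted_name_id[match(name_id, backbone$name_id)]
  backbone$name[match(tgt, backbone$name_id)]
}

split_genus_epithet <- function(name) {
  toks <- strsplit(trimws(name), "\\s+")[[1]]
  list(genus = if (length(toks)) toks[1] else "",
       epithet = if (length(toks) > 1) paste(toks[-1], collapse = " ") else "")
}

string_similarity <- function(a, b) {
  if (!nzchar(a) && !nzchar(b)) return(1)
  if (!nzchar(a) || !nzchar(b)) return(0)
  1 - utils::adist(a, b)[1, 1] / max(nchar(a), nchar(b))
}

#' Match one submitted name against the backbone
#'
#' The best candidate maximizes the overall score, a length-weighted mean
#' of the genus and epithet normalized edit similarities (infraspecific
#' names are matched on the full trinomial epithet string; authorship is
#' ignored). The score is 1 iff the submitted string equals a backbone
#' canonical name exactly. The match is *partial* when only the genus
#' matches: the chosen candidate's genus is identical but its epithet
#' similarity falls below `partial_threshold`.
#'
#' @param submitted name string (non-empty).
#' @param backbone a [read_backbone()] table.
#' @param partial_threshold epithet similarity below which a genus-only hit
#'   is declared partial (default 0.75).
#' @return One-row data.frame: `submitted`, `matched_name_id`,
#'   `matched_name`, `status`, `accepted_name_id`, `accepted_name`,
#'   `score`, `partial`.
#' @export
match_name <- function(submitted, backbone, partial_threshold = 0.75) {
  if (is.na(submitted) || !nzchar(trimws(submitted))) {
    stop("empty submitted name")
  }
  sub <- split_genus_epithet(submitted)
  wg <- nchar(sub$genus); we <- max(nchar(sub$epithet), 1)
  best <- -1; best_i <- NA_integer_; best_esim <- 0
  for (i in seq_len(nrow(backbone))) {
    cand <- split_genus_epithet(backbone$name[i])
    gs <- string_similarity(sub$genus, cand$genus)
    es <- string_similarity(sub$epithet, cand$epithet)
    score <- (wg * gs + we * es) / (wg + we)
    if (score > best + 1e-12 ||
        (abs(score - best) <= 1e-12 && !is.na(best_i) &&
         backbone$name[i] < backbone$name[best_i])) {
      best <- score; best_i <- i; best_esim <- es
    }
  }
  exact <- backbone$name[best_i] == trimws(submitted)
  score <- if (exact) 1 else min(best, 1 - 1e-9)
  cand_genus <- split_genus_epithet(backbone$name[best_i])$genus
  partial <- identical(cand_genus, sub$genus) && !exact &&
    best_esim < partial_threshold
  data.frame(submitted = submitted,
             matched_name_id = backbone$name_id[best_i],
             matched_name = backbone$name[best_i],
             status = backbone$status[best_i],
             accepted_name_id = backbone$accepted_name_id[best_i],
             accepted_name = accepted_name_of(backbone,
                                              backbone$name_id[best_i]),
             score = score, partial = partial,
             stringsAsFactors = FALSE)
}

#' Match many names against the backbone
#'
#' @param names character vector of submitted names (deduplicated).
#' @inheritParams match_name
#' @return data.frame with one row per unique submitted name; see
#'   [match_name()].
#' @export
match_names <- function(names, backbone, partial_threshold = 0.75) {
  names <- unique(names[!is.na(names) & nzchar(trimws(names))])
  do.call(rbind, lapply(names, match_name, backbone = backbone,
                        partial_threshold = partial_threshold))
}

#' Candidate-misspelling review list
#'
#' Matches whose best hit has accepted status, an overall score below 1,
#' and no partial match (both genus and epithet matched) — i.e. names that
#' look like misspellings of an accepted name.
#'
#' @param matches output of [match_names()].
#' @return Subset of `matches`.
#' @export
build_misspelling_list <- function(matches) {
  matches[matches$status == "accepted" & matches$score < 1 &
            !matches$partial, , drop = FALSE]
}

#' Candidate-synonym review list
#'
#' Matches where (i) the score is 1 but the submitted name differs from the
#' accepted name (an exact hit on a synonym), or (ii) the score is below 1
#' and the matched name differs from the accepted name (a fuzzy hit on a
#' synonym).
#'
#' @param matches output of [match_names()].
#' @return Subset of `matches`.
#' @export
build_synonym_list <- function(matches) {
  rule1 <- matches$score == 1 & matches$submitted != matches$accepted_name
  rule2 <- matches$score < 1 & matches$matched_name != matches$accepted_name
  matches[rule1 | rule2, , drop = FALSE]
}

name_to_fields <- function(name) {
  toks <- strsplit(trimws(name), "\\s+")[[1]]
  rank_markers <- c("subsp.", "ssp.", "var.", "f.")
  out <- list(genus = toks[1], species = NA_character_,
              infra_rank = NA_character_, infra_epithet = NA_character_)
  if (length(toks) >= 2) out$species <- toks[2]
  if (length(toks) >= 3) {
    if (toks[3] %in% rank_markers && length(toks) >= 4) {
      out$infra_rank <- toks[3]; out$infra_epithet <- toks[4]
    } else {
      out$infra_epithet <- toks[length(toks)]
    }
  }
  out
}

#' Apply reviewed standardization decisions to records
#'
#' Each flagged name carries an action from the manual review: keep it
#' (`accept_as_is`), rewrite it to the matched accepted name
#' (`correct_spelling`), rewrite it to the matched entry's accepted name
#' (`map_to_synonym_target`), or drop all its records (`exclude`). Names
#' that already match an accepted backbone name exactly pass through
#' unchanged. The pipeline never excludes a name without a decision.
#'
#' @param records an `occ_records` table.
#' @param matches output of [match_names()] for `taxon_name(records)`.
#' @param decisions data.frame with columns `name`, `action`; every `name`
#'   must appear among the submitted names in `matches` (unknown names are
#'   a hard error).
#' @param backbone the backbone used for matching.
#' @return List: `records` (standardized, exclusions removed, audit log
#'   extended), `excluded` (dropped records), `audit`.
#' @export
apply_standardization <- function(records, matches, decisions, backbone) {
  actions <- c("accept_as_is", "correct_spelling", "map_to_synonym_target",
               "exclude")
  if (nrow(decisions)) {
    if (!all(decisions$action %in% actions)) {
      stop("unknown decision action(s): ",
           paste(setdiff(decisions$action, actions), collapse = ", "))
    }
    unknown <- setdiff(decisions$name, matches$submitted)
    if (length(unknown)) {
      stop("decision references unknown name(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  nm <- taxon_name(records)
  audit <- empty_audit()
  drop <- rep(FALSE, nrow(records))
  for (j in seq_len(nrow(decisions))) {
    name <- decisions$name[j]; action <- decisions$action[j]
    hit <- which(nm == name)
    if (!length(hit) || action == "accept_as_is") next
    if (action == "exclude") {
      drop[hit] <- TRUE
      audit <- bind_audit(audit, audit_entries(
        records$record_id[hit], "taxonomy", "discarded",
        paste0("name excluded: ", name)))
      next
    }
    m <- matches[matches$submitted == name, , drop = FALSE][1, ]
    target <- switch(action,
                     correct_spelling = m$matched_name,
                     map_to_synonym_target = m$accepted_name)
    # a corrected spelling may itself be a synonym: follow the link
    if (action == "correct_spelling" && m$status == "synonym") {
      target <- m$accepted_name
    }
    f <- name_to_fields(target)
    for (fld in names(f)) records[[fld]][hit] <- f[[fld]]
    audit <- bind_audit(audit, audit_entries(
      records$record_id[hit], "taxonomy", "modified",
      paste0("standardized '", name, "' -> '", target, "'")))
  }
  excluded <- records[drop, , drop = FALSE]
  kept <- records[!drop, , drop = FALSE]
  class(kept) <- class(records); class(excluded) <- class(records)
  kept <- set_audit(kept, bind_audit(occ_audit(records), audit))
  list(records = kept, excluded = excluded, audit = audit)
}
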