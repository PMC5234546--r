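# Growth-habit inference from specimen description text. Seven habit
# classes are recognized; each specimen description is scanned for
# per-class keyword lists at word boundaries, every matched class adds one
# tag for the species, and the class with the most tags becomes the primary
# habit. If the primary class holds less than half of the species' tags the
# second-ranked class is kept as a secondary habit.

#' The seven habit classes
#'
#' Order doubles as the fixed tie-break order when two classes receive the
#' same number of tags.
#'
#' @return Character vector of class names.
#' @export
habit_classes <- function() {
  c("tree", "shrub", "liana", "herb", "epiphyte", "parasitic",
    "mycoheterotroph")
}

#' Default habit keyword lists
#'
#' Per-class keyword variants matched case-sensitively at word boundaries
#' (so "tree" never fires inside "street"). The tree list carries the
#' classic herbarium-label variants in English, French and Latin
#' ("Tree", "tree", "Arbre", "arbre", "Arbor", "arbor"); the other classes
#' follow the same pattern and are fully configurable.
#'
#' @return Named list (one element per habit class) of keyword vectors.
#' @export
default_habit_keywords <- function() {
  list(
    tree = c("Tree", "tree", "Arbre", "arbre", "Arbor", "arbor"),
    shrub = c("Shrub", "shrub", "Arbuste", "arbuste", "Frutex", "frutex",
              "Shrublet", "shrublet"),
    liana = c("Liana", "liana", "Liane", "liane", "Climber", "climber"),
    herb = c("Herb", "herb", "Herbe", "herbe", "Herba", "herba",
             "Herbaceous", "herbaceous"),
    epiphyte = c("Epiphyte", "epiphyte", "Epiphytic", "epiphytic"),
    parasitic = c("Parasite", "parasite", "Parasitic", "parasitic"),
    mycoheterotroph = c("Mycoheterotroph", "mycoheterotroph",
                        "Mycoheterotrophic", "mycoheterotrophic",
                        "Saprophyte", "saprophyte", "Saprophytic",
                        "saprophytic")
  )
}

#' Tag one specimen description with habit classes
#'
#' A class is tagged when any of its keywords occurs in the text at a word
#' boundary (case-sensitive). A record can tag several classes; each class
#' counts at most once per record, however many of its keywords occur.
#'
#' @param description_text specimen description string (`NA`/empty gives no
#'   tags).
#' @param keywords per-class keyword lists; see [default_habit_keywords()].
#' @return Character vector of tagged classes (possibly empty).
#' @export
tag_record <- function(description_text, keywords = default_habit_keywords()) {
  if (is.na(description_text) || !nzchar(description_text)) return(character(0))
  hit <- vapply(keywords, function(kws) {
    any(vapply(kws, function(kw) {
      grepl(paste0("\\b", kw, "\\b"), description_text, perl = TRUE)
    }, logical(1)))
  }, logical(1))
  names(keywords)[hit]
}

#' Aggregate per-record tags into a species habit profile
#'
#' Tags are summed over records; the class with the highest count is the
#' primary habit (ties broken by the fixed order of [habit_classes()]). If
#' the primary class holds strictly less than half of all tags, the
#' second-ranked class is recorded as a secondary habit.
#'
#' @param tags list of per-record tag vectors (from [tag_record()]), or a
#'   named count vector over classes.
#' @param species optional species name carried in the profile.
#' @return A `habit_profile` list: `species`, `tag_counts` (named, all
#'   classes), `n_tags`, `primary_habit`, `secondary_habit` (`NA` when
#'   absent).
#' @export
aggregate_habit <- function(tags, species = NA_character_) {
  classes <- habit_classes()
  counts <- stats::setNames(rep(0L, length(classes)), classes)
  if (is.list(tags)) {
    for (tg in tags) {
      tg <- intersect(tg, classes)
      counts[tg] <- counts[tg] + 1L
    }
  } else {
    stopifnot(!is.null(names(tags)))
    counts[intersect(names(tags), classes)] <-
      as.integer(tags[intersect(names(tags), classes)])
  }
  total <- sum(counts)
  if (total == 0) {
    return(structure(list(species = species, tag_counts = counts,
                          n_tags = 0L, primary_habit = NA_character_,
                          secondary_habit = NA_character_),
                     class = "habit_profile"))
  }
  ord <- order(-counts, match(classes, classes))  # counts desc, fixed order
  primary <- classes[ord[1]]
  secondary <- NA_character_
  if (counts[ord[1]] < total / 2 && counts[ord[2]] > 0) {
    secondary <- classes[ord[2]]
  }
  structure(list(species = species, tag_counts = counts,
                 n_tags = as.integer(total), primary_habit = primary,
                 secondary_habit = secondary),
            class = "habit_profile")
}

#' @export
print.habit_profile <- function(x, ...) {
  cat(sprintf("<habit_profile%s: primary=%s%s; %d tags>\n",
              if (is.na(x$species)) "" else paste0(" ", x$species),
              x$primary_habit,
              if (is.na(x$secondary_habit)) ""
              else paste0(", secondary=", x$secondary_habit),
              x$n_tags))
  invisible(x)
}

#' Habit profiles for every species in a record table
#'
#' Tags every record's description, sums tags per species and derives
#' primary/secondary habits. Erect palm-like taxa whose keywords are
#' misleading can be forced to a habit through `overrides` (a named vector,
#' species -> class, applied after aggregation; the override becomes the
#' primary habit and clears the secondary).
#'
#' @param records an `occ_records` table.
#' @param keywords see [default_habit_keywords()].
#' @param overrides named character vector of species-level habit overrides.
#' @return data.frame: `species`, `n_tags`, one count column per class,
#'   `primary_habit`, `secondary_habit`.
#' @export
species_habit_profiles <- function(records,
                                   keywords = default_habit_keywords(),
                                   overrides = NULL) {
  sp <- species_binomial(records)
  tags <- lapply(records$description, tag_record, keywords = keywords)
  rows <- lapply(sort(unique(sp)), function(s) {
    prof <- aggregate_habit(tags[sp == s], species = s)
    if (!is.null(overrides) && s %in% names(overrides)) {
      prof$primary_habit <- unname(overrides[s])
      prof$secondary_habit <- NA_character_
    }
    cbind(data.frame(species = s, n_tags = prof$n_tags,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(prof$tag_counts)),
          data.frame(primary_habit = prof$primary_habit,
                     secondary_habit = prof$secondary_habit,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Reconcile inferred habits against a reference table
#'
#' Species whose inferred primary habit agrees with the reference are
#' `confirmed`; disagreements are `mismatch` (flagged for a manual
#' decision); species missing from the reference are `unverified` (the
#' inferred profile stands).
#'
#' @param profiles output of [species_habit_profiles()].
#' @param reference `NULL`, or data.frame with columns `species`, `habit`.
#' @return `profiles` with `reference_habit`, `final_habit` and `status`
#'   columns added.
#' @export
reconcile_habits <- function(profiles, reference = NULL) {
  ref <- if (is.null(reference)) rep(NA_character_, nrow(profiles)) else
    reference$habit[match(profiles$species, reference$species)]
  profiles$reference_habit <- ref
  profiles$final_habit <- profiles$primary_habit
  profiles$status <- ifelse(is.na(ref), "unverified",
                            ifelse(ref == profiles$primary_habit,
                                   "confirmed", "mismatch"))
  profiles
}
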