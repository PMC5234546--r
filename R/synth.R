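# Ground-truthed synthetic fixtures: tessellated country polygon sets,
# taxonomic backbones and occurrence tables with errors injected at known
# rates, so every pipeline stage can be tested offline against a planted
# truth. Countries are planar lat/lon rectangles; at fixture extents
# (a few degrees) great-circle distances on them are accurate to well
# within the 5 km tolerances being exercised.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

make_iso_codes <- function(n) {
  stopifnot(n <= 26 * 26)
  paste0("Z", LETTERS[(seq_len(n) - 1) %/% 26 + 1],
         LETTERS[(seq_len(n) - 1) %% 26 + 1])
}

#' Describe a synthetic fixture
#'
#' Collects the sizes, error-injection rates and seed that define one
#' synthetic dataset. All rates are probabilities in \[0, 1\]; generation
#' is fully deterministic given the seed.
#'
#' @param n_countries number of tessellated countries (>= 2).
#' @param n_species number of accepted species in the backbone.
#' @param n_records number of base occurrence records.
#' @param error_rates named list of injection rates: `border_swap` (point
#'   nudged < 5 km into an adjacent country), `sea_point` (point moved
#'   offshore, half within 5 km of the coast and half far out),
#'   `far_error` (point moved into a non-adjacent country), `duplicate`
#'   (record duplicated into a second source), `misspelling` (one-edit
#'   epithet typo), `synonym_use` (name replaced by a backbone synonym),
#'   `cultivated` (fraction of species planted as introduced, each with
#'   few records), `ex_situ_locality` (locality set to a botanical-garden
#'   string). Unnamed rates default to 0.
#' @param seed integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_countries = 4, n_species = 30, n_records = 200,
                         error_rates = list(), seed = 1) {
  known <- c("border_swap", "sea_point", "far_error", "duplicate",
             "misspelling", "synonym_use", "cultivated", "ex_situ_locality")
  bad <- setdiff(names(error_rates), known)
  if (length(bad)) stop("unknown error rate(s): ", paste(bad, collapse = ", "))
  rates <- stats::setNames(rep(0, length(known)), known)
  rates[names(error_rates)] <- unlist(error_rates)
  if (any(rates < 0 | rates > 1)) stop("error rates must be in [0, 1]")
  stopifnot(n_countries >= 2, n_species >= 1, n_records >= 1)
  structure(list(n_countries = n_countries, n_species = n_species,
                 n_records = n_records, error_rates = as.list(rates),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# ---- polygons --------------------------------------------------------------

#' Generate a tessellated synthetic country polygon set
#'
#' Countries are rectangles on a regular grid sharing full border edges
#' (rook adjacency); the outer rim of the grid is the coastline and
#' everything beyond it is ocean. Ring vertices are laid on a common step
#' so shared borders have identical vertex chains.
#'
#' @param n_countries number of countries, or a [fixture_spec()].
#' @param origin lon/lat of the grid's south-west corner.
#' @param cell_degrees country width/height in degrees.
#' @param ncols grid columns (default: square-ish grid).
#' @param vertex_step vertex spacing along edges, degrees.
#' @return A [country_polygon_set()] with a `layout` attribute describing
#'   each country's rectangle and grid position.
#' @export
make_polygons <- function(n_countries, origin = c(8, -4), cell_degrees = 2,
                          ncols = NULL, vertex_step = 0.5) {
  if (inherits(n_countries, "fixture_spec")) {
    n_countries <- n_countries$n_countries
  }
  stopifnot(n_countries >= 2)
  if (is.null(ncols)) ncols <- ceiling(sqrt(n_countries))
  nrows <- ceiling(n_countries / ncols)
  isos <- make_iso_codes(n_countries)
  rect_ring <- function(x0, y0, x1, y1) {
    xs <- seq(x0, x1, by = vertex_step)
    ys <- seq(y0, y1, by = vertex_step)
    ring <- rbind(
      cbind(xs, y0),
      cbind(x1, ys[-1]),
      cbind(rev(xs)[-1], y1),
      cbind(x0, rev(ys)[-c(1, length(ys))]))
    rbind(ring, ring[1, ])
  }
  polys <- list(); layout <- list()
  for (k in seq_len(n_countries)) {
    r <- (k - 1) %/% ncols + 1; c <- (k - 1) %% ncols + 1
    x0 <- origin[1] + (c - 1) * cell_degrees
    y0 <- origin[2] + (r - 1) * cell_degrees
    polys[[isos[k]]] <- list(rect_ring(x0, y0, x0 + cell_degrees,
                                       y0 + cell_degrees))
    layout[[isos[k]]] <- list(row = r, col = c, x0 = x0, y0 = y0,
                              x1 = x0 + cell_degrees, y1 = y0 + cell_degrees)
  }
  ps <- country_polygon_set(polys)
  attr(ps, "layout") <- list(countries = layout, nrows = nrows,
                             ncols = ncols, cell_degrees = cell_degrees,
                             origin = origin, n = n_countries)
  ps
}

#' Write a country polygon set to GeoJSON
#'
#' @param polyset a [country_polygon_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polyset, path) {
  features <- lapply(names(polyset$polygons), function(iso) {
    rings <- lapply(polyset$polygons[[iso]], function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature", id = iso,
         properties = list(iso_a3 = iso),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- backbone --------------------------------------------------------------

synth_word <- function(n_syllables = 3) {
  syl <- c("ba", "co", "da", "fe", "gi", "lo", "mu", "ne", "pa", "ra",
           "se", "ti", "vu", "ze", "ka", "mo", "li", "tu")
  paste(sample(syl, n_syllables, replace = TRUE), collapse = "")
}

#' Generate a synthetic taxonomic backbone
#'
#' Accepted binomial species names (unique, pronounceable nonsense) plus a
#' fraction of synonym entries linking to random accepted names.
#'
#' @param n_species number of accepted species, or a [fixture_spec()].
#' @param seed integer seed (taken from the spec when one is given).
#' @param synonym_fraction fraction of accepted species that also get one
#'   synonym entry (default 0.25).
#' @param n_genera number of genera to spread species over.
#' @return A [read_backbone()]-validated backbone data.frame.
#' @export
make_backbone <- function(n_species, seed = 1, synonym_fraction = 0.25,
                          n_genera = NULL) {
  if (inherits(n_species, "fixture_spec")) {
    seed <- n_species$seed
    n_species <- n_species$n_species
  }
  if (is.null(n_genera)) n_genera <- max(3, n_species %/% 5)
  with_seed(seed + 101L, {
    cap <- function(s) paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
    genera <- character(0)
    while (length(genera) < n_genera) {
      genera <- unique(c(genera, cap(synth_word())))
    }
    names_seen <- character(0)
    sp_names <- character(0)
    while (length(sp_names) < n_species) {
      nm <- paste(sample(genera, 1), synth_word())
      if (!nm %in% names_seen) {
        names_seen <- c(names_seen, nm)
        sp_names <- c(sp_names, nm)
      }
    }
    n_syn <- round(synonym_fraction * n_species)
    syn_of <- if (n_syn) sort(sample(seq_len(n_species), n_syn)) else integer(0)
    syn_names <- character(0)
    while (length(syn_names) < n_syn) {
      nm <- paste(sample(genera, 1), synth_word())
      if (!nm %in% names_seen) {
        names_seen <- c(names_seen, nm)
        syn_names <- c(syn_names, nm)
      }
    }
    ids <- sprintf("N%04d", seq_len(n_species + n_syn))
    bb <- data.frame(
      name_id = ids,
      name = c(sp_names, syn_names),
      rank = "species",
      status = c(rep("accepted", n_species), rep("synonym", n_syn)),
      accepted_name_id = c(ids[seq_len(n_species)], ids[syn_of]),
      stringsAsFactors = FALSE)
    read_backbone(bb)
  })
}

# ---- records ---------------------------------------------------------------

KM_PER_DEG <- 111.19493  # one degree of a great circle at R = 6371.0088 km

mutate_epithet <- function(name) {
  toks <- strsplit(name, " ")[[1]]
  ep <- toks[length(toks)]
  i <- sample(seq_len(nchar(ep) - 1), 1) + 1   # never the first letter
  repeat {
    ch <- sample(letters, 1)
    if (ch != substr(ep, i, i)) break
  }
  substr(ep, i, i) <- ch
  paste(c(toks[-length(toks)], ep), collapse = " ")
}

#' Generate ground-truthed synthetic occurrence records
#'
#' Produces a canonical occurrence table plus a truth table labelling every
#' record with its planted fate at each pipeline stage: true geographic
#' classification and verdict, duplicate cluster membership, true (accepted)
#' name and how the written name deviates from it, true habit, and
#' introduced / ex-situ flags. Error injection is disjoint per record for
#' the geographic classes and driven by the spec's rates; everything is
#' deterministic given the spec seed.
#'
#' @param spec a [fixture_spec()].
#' @param polygons a [make_polygons()] set (built from `spec` when `NULL`).
#' @param backbone a [make_backbone()] backbone (built from `spec` when
#'   `NULL`).
#' @return List: `records` (an `occ_records` table), `truth` (data.frame,
#'   one row per record), `polygons`, `backbone`, `introduced_species`
#'   (character vector of planted introduced species).
#' @export
make_records <- function(spec, polygons = NULL, backbone = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(polygons)) polygons <- make_polygons(spec)
  if (is.null(backbone)) backbone <- make_backbone(spec)
  layout <- attr(polygons, "layout")
  if (is.null(layout)) stop("make_records needs polygons from make_polygons()")
  rates <- spec$error_rates
  n <- spec$n_records
  with_seed(spec$seed, {
    isos <- names(polygons$polygons)
    acc <- backbone[backbone$status == "accepted", , drop = FALSE]
    species_pool <- acc$name[seq_len(min(spec$n_species, nrow(acc)))]
    syn_by_accepted <- split(
      backbone$name[backbone$status == "synonym"],
      accepted_name_of(backbone,
                       backbone$name_id[backbone$status == "synonym"]))
    habit_of <- stats::setNames(
      sample(c("tree", "shrub", "herb", "liana"), length(species_pool),
             replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
      species_pool)
    habit_phrase <- c(
      tree = "Tree %d m tall, bole straight",
      shrub = "Shrub %d m, much branched",
      herb = "Erect herb %d dm high",
      liana = "Large liana climbing to %d m")

    # introduced species are planted among the rarely-collected ones
    n_introduced <- round(rates$cultivated * length(species_pool))
    introduced <- if (n_introduced) sample(species_pool, n_introduced)
                  else character(0)

    species_of <- character(n)
    slots <- seq_len(n)
    for (s in introduced) {           # at most 3 records each: always "rare"
      k <- min(length(slots), sample(1:3, 1))
      take <- slots[seq_len(k)]
      species_of[take] <- s
      slots <- slots[-seq_len(k)]
    }
    common <- setdiff(species_pool, introduced)
    if (length(slots)) {
      species_of[slots] <- sample(common, length(slots), replace = TRUE)
    }

    surnames <- c("Okafor", "Mbeki", "Lindqvist", "Ferreira", "Takahashi",
                  "Nkemelu", "Bergström", "Van Dam", "Moreau", "Castillo")
    collector_of <- sample(surnames, n, replace = TRUE)
    number_of <- as.character(sample(1:99999, n))
    coll_date <- as.Date("1960-01-01") + sample(0:20000, n, replace = TRUE)
    id_date <- coll_date + sample(0:8000, n, replace = TRUE)

    country_of <- sample(isos, n, replace = TRUE)
    margin <- 0.25
    lon <- lat <- numeric(n)
    for (i in seq_len(n)) {
      rc <- layout$countries[[country_of[i]]]
      lon[i] <- stats::runif(1, rc$x0 + margin, rc$x1 - margin)
      lat[i] <- stats::runif(1, rc$y0 + margin, rc$y1 - margin)
    }

    # --- disjoint geographic fates ---
    k_border <- round(rates$border_swap * n)
    k_sea <- round(rates$sea_point * n)
    k_far <- round(rates$far_error * n)
    if (k_border + k_sea + k_far > n) stop("geographic error rates sum > 1")
    shuffled <- sample(seq_len(n))
    i_border <- shuffled[seq_len(k_border)]
    i_sea <- shuffled[k_border + seq_len(k_sea)]
    i_far <- shuffled[k_border + k_sea + seq_len(k_far)]

    geo_class <- rep("Match", n)
    geo_verdict <- rep("keep", n)
    geo_dist <- rep(NA_real_, n)

    for (i in i_border) {
      iso <- country_of[i]
      nbs <- polygons$adjacency[[iso]]
      nb <- sample(nbs, 1)
      a <- layout$countries[[iso]]; b <- layout$countries[[nb]]
      d_km <- stats::runif(1, 1, 4)
      if (b$col > a$col) {        # neighbour to the east
        lat[i] <- stats::runif(1, a$y0 + margin, a$y1 - margin)
        lon[i] <- a$x1 + d_km / (KM_PER_DEG * cos(lat[i] * pi / 180))
      } else if (b$col < a$col) {
        lat[i] <- stats::runif(1, a$y0 + margin, a$y1 - margin)
        lon[i] <- a$x0 - d_km / (KM_PER_DEG * cos(lat[i] * pi / 180))
      } else if (b$row > a$row) { # neighbour to the north
        lon[i] <- stats::runif(1, a$x0 + margin, a$x1 - margin)
        lat[i] <- a$y1 + d_km / KM_PER_DEG
      } else {
        lon[i] <- stats::runif(1, a$x0 + margin, a$x1 - margin)
        lat[i] <- a$y0 - d_km / KM_PER_DEG
      }
      geo_class[i] <- "Neighbour"; geo_verdict[i] <- "keep"
      geo_dist[i] <- d_km
    }

    coastal <- Filter(function(iso) {
      rc <- layout$countries[[iso]]
      rc$row == 1 || rc$row == layout$nrows || rc$col == 1 ||
        rc$col == layout$ncols
    }, isos)
    for (j in seq_along(i_sea)) {
      i <- i_sea[j]
      iso <- sample(coastal, 1)
      country_of[i] <- iso
      rc <- layout$countries[[iso]]
      sides <- c(if (rc$col == 1) "W", if (rc$col == layout$ncols) "E",
                 if (rc$row == 1) "S", if (rc$row == layout$nrows) "N")
      side <- sample(sides, 1)
      near <- j %% 2 == 0
      d_km <- if (near) stats::runif(1, 1, 4) else stats::runif(1, 15, 50)
      if (side %in% c("W", "E")) {
        lat[i] <- stats::runif(1, rc$y0 + margin, rc$y1 - margin)
        dlon <- d_km / (KM_PER_DEG * cos(lat[i] * pi / 180))
        lon[i] <- if (side == "W") rc$x0 - dlon else rc$x1 + dlon
      } else {
        lon[i] <- stats::runif(1, rc$x0 + margin, rc$x1 - margin)
        dlat <- d_km / KM_PER_DEG
        lat[i] <- if (side == "S") rc$y0 - dlat else rc$y1 + dlat
      }
      geo_class[i] <- "Sea"
      geo_verdict[i] <- if (near) "keep" else "discard"
      geo_dist[i] <- d_km
    }

    if (k_far > 0) {
      for (i in i_far) {
        iso <- country_of[i]
        non_adj <- setdiff(isos, c(iso, polygons$adjacency[[iso]]))
        if (!length(non_adj)) {
          stop("far_error injection needs a non-adjacent country pair; ",
               "use a larger grid")
        }
        nc <- sample(non_adj, 1)
        rc <- layout$countries[[nc]]
        lon[i] <- stats::runif(1, rc$x0 + margin, rc$x1 - margin)
        lat[i] <- stats::runif(1, rc$y0 + margin, rc$y1 - margin)
        geo_class[i] <- "Error"; geo_verdict[i] <- "discard"
      }
    }

    # --- names as written ---
    name_written <- species_of
    name_status <- rep("correct", n)
    k_mis <- round(rates$misspelling * n)
    k_syn <- round(rates$synonym_use * n)
    has_syn <- which(species_of %in% names(syn_by_accepted))
    name_slots <- sample(seq_len(n))
    i_mis <- name_slots[seq_len(k_mis)]
    i_syn_pool <- setdiff(intersect(name_slots, has_syn), i_mis)
    i_syn <- utils::head(i_syn_pool, k_syn)
    for (i in i_mis) {
      name_written[i] <- mutate_epithet(species_of[i])
      name_status[i] <- "misspelled"
    }
    for (i in i_syn) {
      syns <- syn_by_accepted[[species_of[i]]]
      name_written[i] <- syns[sample.int(length(syns), 1)]
      name_status[i] <- "synonym"
    }

    # --- localities, descriptions ---
    towns <- c("Mbala", "Kisolo", "Eanda", "Ngove", "Alima", "Bokasso")
    locality <- paste(sample(towns, n, replace = TRUE), "road, km",
                      sample(1:60, n, replace = TRUE))
    ex_situ <- rep(FALSE, n)
    k_ex <- round(rates$ex_situ_locality * n)
    i_ex <- sample(seq_len(n), k_ex)
    locality[i_ex] <- paste0("Botanical garden, ",
                             sample(towns, k_ex, replace = TRUE))
    ex_situ[i_ex] <- TRUE
    description <- sprintf(habit_phrase[habit_of[species_of]],
                           sample(2:30, n, replace = TRUE))

    # --- duplicates: extra copies of selected base records ---
    k_dup <- round(rates$duplicate * n)
    i_dup <- sort(sample(seq_len(n), k_dup))
    dup_cluster <- rep(NA_integer_, n)
    dup_cluster[i_dup] <- seq_along(i_dup)

    record_id <- sprintf("R%05d", seq_len(n))
    base <- data.frame(
      record_id = record_id,
      source_id = "INST-A", source_kind = "institutional",
      name = name_written,
      identification_date = format(id_date, "%Y-%m-%d"),
      country_code = country_of,
      latitude = round(lat, 6), longitude = round(lon, 6),
      verbatim_coordinates = NA_character_,
      locality = locality, description = description,
      collector = paste0(collector_of, ", D.J."),
      collector_number = number_of,
      collection_date = format(coll_date, "%Y-%m-%d"),
      stringsAsFactors = FALSE)

    truth <- data.frame(
      record_id = record_id,
      species_true = species_of,
      name_written = name_written,
      name_status = name_status,
      geo_classification = geo_class,
      geo_verdict = geo_verdict,
      geo_distance_km = geo_dist,
      duplicate_cluster = dup_cluster,
      habit_true = unname(habit_of[species_of]),
      introduced = species_of %in% introduced,
      ex_situ = ex_situ,
      stringsAsFactors = FALSE)

    if (k_dup) {
      dup <- base[i_dup, , drop = FALSE]
      dup$record_id <- sprintf("R%05dD", i_dup)
      dup$source_id <- "PERS-B"
      dup$source_kind <- "personal"
      # same person, differently formatted entry
      dup$collector <- paste0("D.J. ", collector_of[i_dup])
      dup$identification_date <- format(id_date[i_dup] + 200, "%Y-%m-%d")
      dup_truth <- truth[i_dup, , drop = FALSE]
      dup_truth$record_id <- dup$record_id
      base <- rbind(base, dup)
      truth <- rbind(truth, dup_truth)
      rownames(base) <- rownames(truth) <- NULL
    }

    parts <- lapply(base$name, name_to_fields)
    base$genus <- vapply(parts, `[[`, character(1), "genus")
    base$species <- vapply(parts, function(p) p$species, character(1))
    base$family <- paste0(substr(base$genus, 1, 4), "aceae")
    base$name <- NULL

    list(records = as_occ_records(base), truth = truth,
         polygons = polygons, backbone = backbone,
         introduced_species = introduced)
  })
}
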