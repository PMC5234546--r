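---
title: "Curation methods for georeferenced occurrence records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation methods for georeferenced occurrence records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occurclean)
```

`occurclean` curates tabular occurrence records of collection specimens
before they enter a regional floristic database. This vignette explains
each stage's model and assumptions, the parameters that matter, the
numerical choices made where the procedure was genuinely open, and what the
synthetic fixtures do and do not demonstrate.

## Data model

Records are rows of a canonical table (`occ_fields()`): an opaque unique
`record_id`, a source identifier and kind (`institutional`, `personal`,
`silica`, `plot` — the kind matters because personal datasets are
expert-curated and get priority in conflict resolution), a structured taxon
name, decimal WGS84 coordinates plus an optional verbatim coordinate
string, free-text locality and description, collector, collector number and
dates. CSVs are RFC 4180, UTF-8; a configurable column mapping loads Darwin
Core exports directly. Coordinates that fail to parse or fall outside
[-90, 90] × [-180, 180] never abort a load: the record is kept with its
coordinates marked invalid and an audit entry saying why. Dates are parsed
ISO-8601-first with a fallback format list; a format is accepted only if
re-formatting reproduces the input string exactly (this guards against the
C library's tolerance for trailing text, which would otherwise misread
`10/05/1999` as year 10). Unparseable dates become missing — the pipeline
never guesses.

Every stage appends to an audit log (`occ_audit()`), so the conservation
invariant *records in = kept + discarded (+ merged)* is checkable at any
point; the test suite asserts it end to end.

## Geospatial validation

Two checks are applied to each georeferenced record.

**Documented-country agreement.** If the point lies inside the documented
country's polygon the record is a `Match`. If it lies in a country that
shares a border with the documented one it is a `Neighbour`: the nearest
distance to the documented country's border is computed and the record is
retained iff the distance is at most `tolerance_km` (default 5 km) — the
rationale being that near a border either the map or the coordinate may
simply not be precise enough. A point in a non-adjacent country is an
`Error` and is discarded.

**Coastline tolerance.** A point lying in no polygon is at `Sea`; the
distance to the documented country's coastline decides retention under the
same 5 km rule. A point at sea with no documented country has nothing to be
measured against and is discarded.

Numerical choices:

* Distances are great-circle on a sphere of mean radius 6371.0088 km. No
  datum is modelled; at a 5 km tolerance the spherical/ellipsoidal
  difference (< 0.3%) is immaterial.
* The boundary polyline is densified to segments of at most 1 km; the
  minimum distance is found by a vertex sweep followed by an exact
  point-to-segment refinement near the closest vertex (the perpendicular
  foot is located in a local equirectangular frame and the distance to it
  measured by the haversine formula). The refinement matters: a bare 1 km
  vertex sweep misestimates short distances by up to a few percent, and the
  package's own property tests require 0.1% agreement with a brute-force
  oracle.
* Point-in-polygon uses the even-odd crossing rule over all rings (holes
  therefore work untreated). A point exactly on the documented country's
  border counts as inside — ties break toward retention. Retention at
  exactly the tolerance is inclusive (`distance <= tolerance`), applied
  uniformly to the border and coastline checks.
* "Neighbouring" means sharing at least one border segment in the polygon
  set; adjacency is precomputed from shared ring edges (vertices rounded to
  1e-6°), which is exact for tessellated sets built on a common vertex
  grid, and can be supplied explicitly for polygon sets whose borders are
  digitized independently.
* Records with coordinates but no documented country cannot be checked;
  they are flagged `NoCountry` and kept by default (configurable), with a
  warning.

Which border dataset is used matters near borders: polygons are therefore
an explicit input (GeoJSON FeatureCollection, lon/lat order). A density
grid (`density_grid()`, default 2°) with half-open `[lower, upper)` cells
summarises retained records; a record exactly on a cell edge belongs to the
cell whose lower edge it sits on.

## Coordinate precision codes

The accuracy code expresses the granularity at which a coordinate pair was
recorded:

| code | granularity | ~uncertainty |
|------|-------------------------|--------------|
| 1 | whole degrees | 110 km |
| 2 | 15 minutes | 30 km |
| 3 | 5 minutes | 10 km |
| 4 | 2 minutes | 4 km |
| 5 | exact minute | 2 km |
| 6 | 0.1 decimal minute | 200 m |
| 7 | 0.01 decimal minute | 20 m |
| 8 | 0.001 decimal minute | 2 m |

How codes are derived from stored values is this package's decision: when a
verbatim sexagesimal string is present its *stated* granularity is used
(degrees only → 1; integer minutes → 2–5 by divisibility by 15, 5, 2;
decimal minutes with *d* stated decimals → 5 + *d*), and the record's code
is the finer of the two component codes — the granularity actually needed
to write both components down (4°15′ paired with 12°33′ is minute-level
data; the quarter-degree look of 15′ is coincidence). Without a verbatim
string, the code is inferred from the decimal degrees by scanning the
granularities from coarse to fine and taking the first of which both
components are integer multiples. Divisibility is tested in integer
thousandths of a minute after rounding to 10 decimals (tolerance 1e-9 in
degrees), which defeats binary float artifacts; a coordinate matching no
granularity is true decimal-degree data and is coded 8, there being no
finer class. The coding is deterministic, idempotent, and monotone under
refinement: adding decimals of minutes never lowers the code.

## Duplicate detection and merging

Herbarium duplicates are sheets of one gathering distributed to several
collections, so the match key is the gathering: normalized collector +
collector number + collection year. Collector normalization case-folds,
transliterates, strips punctuation, drops single-letter tokens (initials)
and sorts the rest, so `Fontaine, A.B.` and `A.B. Fontaine` agree; within a
number/year block, collectors are fuzzy-grouped by single linkage at a
normalized edit similarity of ≥ 0.85 (configurable). When the collector
number is absent the key additionally requires exact genus agreement —
without a number, the gathering identity is too weak otherwise. Collection
years (not exact dates) are compared because duplicate sheets are often
databased with day-level discrepancies; records two years apart never
cluster.

Conflicts inside a cluster are resolved by two cascades. Identification:
(1) personal database beats institutional; (2) most recent identification
date; (3) lowest — i.e. most specific — taxonomic rank (infraspecific <
species < genus); (4) a reproducible "random" choice. Coordinates:
(1) the member that passed the country check; (2) personal database;
(3) highest precision code; (4) reproducible choice. Each step narrows the
candidate set and the reported `rule` is the step that singled out the
winner. The "random" steps hash the sorted member ids together with a
caller seed, so results are reproducible and independent of input order;
the whole merge is order-invariant (output sorted by record id), which the
tests verify by shuffling.

The consensus record takes all identification fields from the
identification winner, all coordinate fields from the coordinate winner,
and fills the remaining fields with the first non-missing value over
members in record-id order. Absorbed members are audited as `merged`.

## Name standardization

Names are standardized against a local backbone table (name, rank, status,
accepted-name link; accepted entries self-link, synonyms link to accepted
entries, so chains are one hop and acyclic). Matching emulates an online
resolution service locally for reproducible offline runs: genus and
epithet are scored separately by normalized Levenshtein similarity and
combined as a length-weighted mean; the score is 1 exactly for a verbatim
hit on a backbone name; a match is *partial* when only the genus matched
(epithet similarity below 0.75). Infraspecific names match on the full
trinomial; authorship is ignored. A service adapter can replace the scorer
without touching the list logic, which is the reproducible part:

* **misspelling list** — accepted-status matches with score < 1 and no
  partial match (both genus and epithet matched);
* **synonym list** — exact-score matches whose submitted name differs from
  the accepted name, plus sub-1 matches whose matched name differs from its
  accepted name.

The two lists are disjoint from each other and from the exact-accepted set.
Every exclusion or rewrite requires an explicit per-name decision
(`accept_as_is`, `correct_spelling`, `map_to_synonym_target`, `exclude`) —
the manual review step is a first-class input, and the pipeline never
auto-excludes. A decision naming an unknown name is a hard error.
Standardization is idempotent: all output names are accepted backbone
names, and a second pass changes nothing.

## Ex-situ and introduced taxa

Locality screening is two-staged, mirroring the fact that keyword hits
need human confirmation: a case-insensitive substring keyword list
("botanical garden", "jardin botanique", "hortus", ...) builds a
preliminary list; only localities on the reviewed confirmed list are
discarded, the rest are emitted for review ("near the garden village"
matches "garden" but is presumably natural).

Introduced/cultivated taxa are sought among the rarely-collected: species
with fewer than 11 records are checked against a pluggable external
occurrence source (function `species -> data.frame(longitude, latitude)`;
a live aggregator client is deliberately out of scope and tests use
synthetic sources). "Mostly collected outside the study region" is
quantified as an outside fraction > 0.5 — no published figure exists, and
the monotonicity property (raising the threshold never adds candidates)
holds for any cut-off. No external records means no evidence: the species
stays native. An unavailable source defers the decision rather than
silently dropping the species. Removal of the reviewed confirmed list is a
separate, audited step.

## Habit inference

Seven classes: tree, shrub, liana, herb, epiphyte, parasitic,
mycoheterotroph. Description text is scanned per class with case-sensitive
keyword variants at word boundaries ("tree" never fires inside "street");
a record contributes at most one tag per class however many of that class's
keywords occur — presence, not occurrence counting, so verbose labels don't
dominate. Per species, tags are summed; the modal class is the primary
habit; if the primary holds strictly less than half of all tags the
second-ranked class becomes the secondary habit (9 tags of 20 is a maximum
but under half, so a secondary is assigned; 5 of 10 is exactly half and is
not "less than half"). Ties at the top break by the fixed class order
above. Erect palm-like taxa whose labels mislead the keywords are handled
by a species-level override table. Profiles can be reconciled against an
external reference table: agreements are confirmed, disagreements flagged
for manual decision, absences marked unverified.

## Synthetic fixtures

`make_polygons()` tessellates rectangular countries on a grid (rook
adjacency, shared vertex chains along borders, the rim as coastline),
`make_backbone()` generates unique pronounceable names with a synonym
fraction, and `make_records()` plants records with known fates: border
nudges at 1–4 km (unambiguously inside the 5 km tolerance), offshore
points at 1–4 km or 15–50 km (unambiguously on either side), non-adjacent
placements, duplicate copies with reformatted collector strings, one-edit
epithet typos, synonym substitutions, introduced species (each planted
with at most 3 records, i.e. under the rarity threshold) and
botanical-garden localities. Everything is deterministic given the seed,
and rates default to zero — the caller states the study conditions.

Planar rectangles with great-circle distances are an accepted
approximation at fixture extents (< 5°); offsets are generated
perpendicular to grid-aligned borders precisely so that planted distances
equal measured great-circle distances to within the test tolerances.

What passing fixtures shows — and does not. The fixtures exercise the
decision logic under clean separations: offsets far from the 5 km
boundary, typos of exactly one edit on well-separated names, duplicates
with consistent gathering data. Real data additionally contain ambiguous
cases the fixtures deliberately avoid: records near the tolerance
boundary (their fate flips with the border dataset used), collector
homonyms and shared numbers, names whose nearest backbone neighbour is a
different valid species one edit away, and localities whose ex-situ status
genuinely requires human knowledge. For those, the package's contribution
is not a correct automatic answer but an explicit, audited review surface.

## Problem sizes used in the tests

The test suite runs on fixtures of 120–1,000 records, backbones of up to
200 names and grids of 2–9 countries, with 1,000 synthetic duplicate
clusters for the cascade checks — sizes at which every expected value can
be recomputed by brute force alongside the implementation. The suite
completes in well under a minute.

## Known limitations

* Polygon input is GeoJSON only; shapefile geometry is not read.
* No reprojection: coordinates are assumed WGS84 lon/lat.
* Adjacency from shared edges requires topologically consistent polygon
  sets; independently digitized borders need an explicit adjacency list.
* The name matcher scores plain binomials/trinomials; authorship strings
  and hybrid markers are not parsed.
* No probabilistic record linkage: duplicate detection is key-based by
  design, and gatherings databased with different collector numbers will
  not cluster.
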