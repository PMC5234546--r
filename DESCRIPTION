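Package: occurclean
Title: Quality Control and Curation of Georeferenced Specimen Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A curation toolkit for tabular, Darwin-Core-style occurrence
    records of collection specimens. Implements the quality-control workflow
    used to assemble large regional floristic databases: geospatial
    validation of coordinates against documented-country polygons (with a
    neighbouring-country and coastline distance tolerance), ordinal coding of
    coordinate precision from verbatim or decimal coordinates, detection and
    merging of herbarium duplicates via collector/number/date match keys with
    identification- and coordinate-priority cascades, taxonomic name
    standardization against a local backbone (misspelling and synonym lists),
    flagging of ex-situ and introduced/cultivated taxa, growth-habit
    inference from specimen description text by keyword voting, and a fully
    ground-truthed synthetic fixture generator so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    sp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
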