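test_that("backbone validation enforces link structure", {
  expect_error(read_backbone(data.frame(
    name_id = "1", name = "Acacia seyal", rank = "species",
    status = "accepted", accepted_name_id = "2")), "self-link")
  expect_error(read_backbone(data.frame(
    name_id = c("1", "2"), name = c("A b", "C d"), rank = "species",
    status = c("synonym", "synonym"), accepted_name_id = c("2", "1"))),
    "accepted entry")
  expect_silent(tiny_backbone())
})

test_that("exact hits score 1 and one-edit misspellings score below 1", {
  bb <- tiny_backbone()
  m <- match_name("Acacia adenocalyx", bb)
  expect_equal(m$score, 1)
  expect_false(m$partial)
  expect_equal(m$matched_name, "Acacia adenocalyx")

  m <- match_name("Acacia adenocalix", bb)
  # frozen from the scoring rule: genus 6/6 exact, epithet 9/10 characters
  # agree -> length-weighted (6*1 + 10*0.9) / 16
  expect_equal(m$score, 0.9375)
  expect_false(m$partial)
  expect_equal(m$matched_name, "Acacia adenocalyx")

  m <- match_name("Acacia nonexistens", bb)
  expect_true(m$partial)
  expect_lt(m$score, 1)
  expect_error(match_name("", bb), "empty")
})

test_that("misspelling list keeps accepted sub-1 non-partial matches only", {
  bb <- tiny_backbone()
  matches <- match_names(c("Acacia adenocalyx",   # exact accepted
                           "Acacia adenocalix",   # misspelt accepted
                           "Acacia nonexistens",  # partial
                           "Acacia gloriosa"),    # exact synonym
                         bb)
  mis <- build_misspelling_list(matches)
  expect_equal(mis$submitted, "Acacia adenocalix")
})

test_that("synonym list applies both construction rules", {
  bb <- tiny_backbone()
  matches <- match_names(c("Acacia gloriosa",      # (i) exact hit, accepted differs
                           "Chlorophora excelsq",  # (ii) fuzzy hit on a synonym
                           "Acacia adenocalyx",    # exact accepted: excluded
                           "Acacia adenocalix"),   # misspelt accepted: excluded
                         bb)
  syn <- build_synonym_list(matches)
  expect_setequal(syn$submitted, c("Acacia gloriosa", "Chlorophora excelsq"))
  # misspelling and synonym lists are disjoint from each other and from the
  # exact-accepted set
  mis <- build_misspelling_list(matches)
  expect_length(intersect(mis$submitted, syn$submitted), 0)
  expect_false("Acacia adenocalyx" %in% c(mis$submitted, syn$submitted))
})

test_that("standardization rewrites, excludes and audits per the decisions file", {
  bb <- tiny_backbone()
  recs <- make_test_records(data.frame(
    record_id = c("r1", "r2", "r3", "r4"),
    genus = c("Acacia", "Acacia", "Chlorophora", "Acacia"),
    species = c("adenocalyx", "adenocalix", "excelsa", "gloriosa")))
  matches <- match_names(taxon_name(recs), bb)
  decisions <- data.frame(
    name = c("Acacia adenocalix", "Chlorophora excelsa", "Acacia gloriosa"),
    action = c("correct_spelling", "map_to_synonym_target", "exclude"),
    stringsAsFactors = FALSE)
  out <- apply_standardization(recs, matches, decisions, bb)
  expect_equal(nrow(out$records), 3)
  expect_equal(nrow(out$excluded), 1)
  expect_equal(out$excluded$record_id, "r4")
  expect_true(any(out$audit$action == "discarded"))
  nm <- taxon_name(out$records)
  expect_equal(sort(unique(nm)), c("Acacia adenocalyx", "Milicia excelsa"))
  # every output name is an accepted backbone name
  expect_true(all(nm %in% bb$name[bb$status == "accepted"]))

  # idempotence: re-matching and re-applying changes nothing
  matches2 <- match_names(nm, bb)
  out2 <- apply_standardization(out$records, matches2,
                                decisions[0, , drop = FALSE], bb)
  expect_equal(taxon_name(out2$records), nm)
  expect_equal(nrow(out2$records), 3)

  expect_error(apply_standardization(recs, matches, data.frame(
    name = "Notin matches", action = "exclude")), "unknown name")
  expect_error(apply_standardization(recs, matches, data.frame(
    name = "Acacia gloriosa", action = "obliterate")), "unknown decision")
})

test_that("planted misspellings and synonyms in a fixture are fully recovered", {
  bb <- make_backbone(50, seed = 23, synonym_fraction = 0.3)
  acc <- bb$name[bb$status == "accepted"]
  syn <- bb$name[bb$status == "synonym"]
  mutate1 <- function(s) {
    i <- nchar(s); ch <- substr(s, i, i)
    paste0(substr(s, 1, i - 1), if (ch == "x") "y" else "x")
  }
  planted_mis <- vapply(acc[1:10], mutate1, character(1), USE.NAMES = FALSE)
  planted_syn <- syn[1:5]
  submitted <- c(acc[11:25], planted_mis, planted_syn)
  matches <- match_names(submitted, bb)
  expect_setequal(build_misspelling_list(matches)$submitted, planted_mis)
  expect_setequal(build_synonym_list(matches)$submitted, planted_syn)
})
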