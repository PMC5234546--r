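cluster_members <- function(...) {
  make_test_records(data.frame(...))
}

test_that("collector name variants normalize to the same key and cluster", {
  recs <- cluster_members(
    record_id = c("h1", "h2", "x1"),
    collector = c("Fontaine, A.B.", "A.B. Fontaine", "Kimani, J.K."),
    collector_number = c("1234", "1234", "1234"),
    collection_date = c("1999-05-10", "1999-06-01", "1999-05-10"))
  expect_equal(normalize_collector("Fontaine, A.B."),
               normalize_collector("A.B. Fontaine"))
  cl <- find_duplicates(recs)
  expect_equal(sort(cl$record_id), c("h1", "h2"))
  expect_equal(length(unique(cl$cluster_id)), 1)
})

test_that("records identical up to id and source cluster; distant dates do not", {
  recs <- cluster_members(
    record_id = c("a", "b", "c"),
    source_id = c("S1", "S2", "S3"),
    collector = "Moreau, G.",
    collector_number = "55",
    collection_date = c("2001-03-03", "2001-03-03", "2003-03-03"))
  cl <- find_duplicates(recs)
  expect_equal(sort(cl$record_id), c("a", "b"))  # 2 years apart: no match
})

test_that("without a collector number, exact genus agreement is required", {
  recs <- make_test_records(data.frame(
    record_id = c("g1", "g2", "g3"),
    genus = c("Acacia", "Acacia", "Milicia"),
    collector = "Abebe, B.",
    collector_number = NA_character_,
    collection_date = "2005-01-01"))
  cl <- find_duplicates(recs)
  expect_equal(sort(cl$record_id), c("g1", "g2"))
})

test_that("identification cascade follows personal > recency > rank > seeded random", {
  base <- list(collector = "X", collector_number = "1",
               collection_date = "2000-01-01")
  m1 <- cluster_members(record_id = c("i", "p"),
                        source_kind = c("institutional", "personal"),
                        identification_date = c("2010-01-01", "2001-01-01"))
  r <- resolve_identification(m1)
  expect_equal(r$record_id, "p")     # personal beats a newer institutional id
  expect_equal(r$rule, "personal")

  m2 <- cluster_members(record_id = c("a", "b"),
                        identification_date = c("2001-01-01", "2010-01-01"))
  r <- resolve_identification(m2)
  expect_equal(r$record_id, "b")
  expect_equal(r$rule, "most_recent_date")

  m3 <- make_test_records(data.frame(
    record_id = c("gen", "sub"),
    genus = "Acacia",
    species = c(NA, "adenocalyx"),
    infra_rank = c(NA, "subsp."),
    infra_epithet = c(NA, "parvifolia")))
  r <- resolve_identification(m3)
  expect_equal(r$record_id, "sub")   # most specific rank wins
  expect_equal(r$rule, "lowest_rank")

  m4 <- cluster_members(record_id = c("t1", "t2"))
  r42a <- resolve_identification(m4, seed = 42)
  r42b <- resolve_identification(m4, seed = 42)
  expect_equal(r42a$rule, "random")
  expect_identical(r42a$record_id, r42b$record_id)
})

test_that("coordinate cascade follows country-check > personal > precision > random", {
  m <- cluster_members(record_id = c("c1", "c2"),
                       source_kind = c("personal", "institutional"))
  r <- resolve_coordinates(m, passed = c(c1 = FALSE, c2 = TRUE))
  expect_equal(r$record_id, "c2")    # passing the geo check trumps personal
  expect_equal(r$rule, "passed_country_check")

  r <- resolve_coordinates(m)
  expect_equal(r$record_id, "c1")
  expect_equal(r$rule, "personal")

  m2 <- cluster_members(record_id = c("k5", "k7"))
  r <- resolve_coordinates(m2, codes = c(k5 = 5L, k7 = 7L))
  expect_equal(r$record_id, "k7")
  expect_equal(r$rule, "highest_precision")

  r1 <- resolve_coordinates(m2, seed = 9)
  expect_equal(r1$rule, "random")
  expect_identical(r1$record_id, resolve_coordinates(m2, seed = 9)$record_id)
})

test_that("merging conserves counts and unions non-conflicting fields", {
  recs <- cluster_members(
    record_id = c("m1", "m2", "m3", "solo"),
    collector = "Moretti, T.",
    collector_number = c("9", "9", "9", "10"),
    collection_date = "2010-06-06",
    locality = c(NA, "Monts de Cristal", NA, NA))
  out <- merge_duplicates(recs, seed = 1)
  expect_equal(nrow(out$records), 4 - (3 - 1))   # n - sum(size - 1)
  expect_equal(nrow(out$audit), 2)               # absorbed members audited
  expect_true(all(out$audit$action == "merged"))
  consensus <- out$records[out$records$record_id != "solo", ]
  expect_equal(consensus$locality, "Monts de Cristal")
})

test_that("merging is invariant under shuffling of the input rows", {
  fx <- make_records(fixture_spec(n_countries = 4, n_species = 20,
                                  n_records = 150,
                                  error_rates = list(duplicate = 0.3),
                                  seed = 17))
  recs <- fx$records
  out1 <- merge_duplicates(recs, seed = 5)
  perm <- withr::with_seed(99, sample(nrow(recs)))
  shuffled <- recs[perm, ]
  class(shuffled) <- class(recs)
  out2 <- merge_duplicates(shuffled, seed = 5)
  expect_equal(nrow(out1$records), nrow(out2$records))
  for (f in occ_fields()) {
    expect_equal(out1$records[[f]], out2$records[[f]], info = f)
  }
})

test_that("adding a personal member never leaves an institutional id winning", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:4, 1)
    m <- make_test_records(data.frame(
      record_id = sprintf("r%d", seq_len(n)),
      source_kind = "institutional",
      identification_date = format(as.Date("2000-01-01") +
                                     sample(0:5000, n), "%Y-%m-%d")))
    plus <- make_test_records(data.frame(
      record_id = c(sprintf("r%d", seq_len(n)), "zz"),
      source_kind = c(rep("institutional", n), "personal"),
      identification_date = c(format(as.Date("2000-01-01") +
                                       sample(0:5000, n), "%Y-%m-%d"),
                              "1990-01-01")))
    r <- resolve_identification(plus)
    expect_equal(r$record_id, "zz")
  }
})
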