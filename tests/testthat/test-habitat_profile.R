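test_that("habitat_percent is the taxon-internal share of a descriptor", {
  m <- worked_example_matrix()
  expect_equal(round(habitat_percent(m, "Actinobacteria", "Soil"), 2), 13.23)
  s <- small_matrix()
  expect_equal(habitat_percent(s, "D", "d1"), 0)               # no records
  expect_equal(habitat_percent(s, "uncultured", "d3"), 8)      # 40/500
  full <- count_matrix(matrix(10, 1, 1, dimnames = list("A", "d")), 10,
                       archaea = NA_character_, uncultured = NA_character_)
  expect_equal(habitat_percent(full, "A", "d"), 100)           # full coverage
  zero <- count_matrix(matrix(0, 1, 1, dimnames = list("A", "d")), 0,
                       archaea = NA_character_, uncultured = NA_character_)
  expect_error(habitat_percent(zero, "A", "d"), "undefined")
  expect_error(habitat_percent(s, "nope", "d1"), "unknown taxon")
})

test_that("profiles rank descriptors by decreasing share with label tie-break", {
  m <- small_matrix()
  p <- build_profile(m, "A")
  # A: d1 = 50/200 = 25%, d2 = 10/200 = 5%, d3 = 0 (excluded)
  expect_equal(p$entries$descriptor, c("d1", "d2"))
  expect_equal(p$entries$h, c(25, 5))
  expect_equal(p$coverage_fraction, 2 / 3)
  # top-ranked h equals the brute-force maximum over all descriptors
  h_all <- vapply(descriptor_labels(m), function(d) habitat_percent(m, "A", d),
                  numeric(1))
  expect_equal(p$entries$h[1], max(h_all))
  # tie-break: equal shares ordered by label
  tie <- count_matrix(matrix(c(5, 5), 1, 2, dimnames = list("A", c("z", "y"))),
                      10, archaea = NA_character_, uncultured = NA_character_)
  expect_equal(build_profile(tie, "A")$entries$descriptor, c("y", "z"))
})

test_that("profiles are invariant to descriptor column order", {
  m <- small_matrix()
  m_rev <- count_matrix(m$counts[, c("d3", "d1", "d2")], m$baseline)
  for (taxon in c("A", "C", "E")) {
    expect_equal(build_profile(m_rev, taxon), build_profile(m, taxon))
  }
})

test_that("cosmopolitanism uses the >= 90% linked-descriptor criterion", {
  # boundary: 43/48 descriptors (0.896) misses, 44/48 (0.917) qualifies
  make <- function(k, total = 48) {
    counts <- matrix(c(rep(1, k), rep(0, total - k)), 1, total,
                     dimnames = list("T", sprintf("d%02d", seq_len(total))))
    count_matrix(counts, 100, archaea = NA_character_,
                 uncultured = NA_character_)
  }
  expect_false(build_profile(make(43), "T")$cosmopolitan)
  expect_true(build_profile(make(44), "T")$cosmopolitan)
  expect_true(build_profile(make(48), "T")$cosmopolitan)   # full coverage
  expect_false(build_profile(make(2), "T")$cosmopolitan)   # short list
  # a configurable minimum count raises the bar for "linked"
  expect_false(build_profile(make(48), "T", min_count = 2)$cosmopolitan)
})

test_that("cosmopolitan_census counts and percentages match the verdicts", {
  stub <- function(cos) structure(list(taxon = "x", cosmopolitan = cos),
                                  class = "habitat_profile")
  profs <- c(replicate(11, stub(TRUE), simplify = FALSE),
             replicate(18, stub(FALSE), simplify = FALSE))
  cen <- cosmopolitan_census(profs)
  expect_equal(cen$count, 11)
  expect_equal(cen$total, 29)
  expect_equal(round(cen$percent, 1), 37.9)
  expect_equal(cosmopolitan_census(list(stub(FALSE)))$percent, 0)
  expect_equal(cosmopolitan_census(replicate(5, stub(TRUE),
                                             simplify = FALSE))$percent, 100)
})

test_that("profile TSVs carry ranks and the census verdicts", {
  m <- small_matrix()
  profs <- build_profiles(m)
  expect_named(profs, c("A", "B", "C", "D", "E"))
  long <- withr::local_tempfile(fileext = ".tsv")
  cen <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(profs, long, cen)
  lt <- read.delim(long)
  expect_named(lt, c("taxon", "rank", "descriptor", "h_percent"))
  a <- lt[lt$taxon == "A", ]
  expect_equal(a$rank, seq_len(nrow(a)))
  ct <- read.delim(cen)
  expect_named(ct, c("taxon", "coverage_fraction", "cosmopolitan"))
  expect_equal(nrow(ct), 5)
})
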