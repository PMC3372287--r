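two_taxon_spec <- function(f = c(2, 1), seed = 1L, depth = 1e5) {
  synthetic_spec(
    baseline_props = c(A = 0.5, B = 0.5), baseline_depth = 1e6,
    effects = matrix(f, 2, 1, dimnames = list(c("A", "B"), "d")),
    column_depths = depth, seed = seed
  )
}

test_that("specs are validated and serialization round-trips", {
  expect_error(synthetic_spec(c(A = 0.5, B = 0.6), 100,
                              matrix(1, 2, 1, dimnames = list(c("A", "B"), "d")),
                              10), "sum to 1")
  expect_error(two_taxon_spec(f = c(0, 1)), "> 0")
  spec <- default_synthetic_spec(seed = 3)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_synthetic_spec(spec, path)
    expect_equal(read_synthetic_spec(path), spec)
  }
})

test_that("generation is seed-deterministic and satisfies matrix invariants", {
  spec <- default_synthetic_spec(seed = 42, baseline_depth = 1e5,
                                 column_depths = 5e3)
  m1 <- generate(spec)
  m2 <- generate(spec)
  expect_identical(m1$counts, m2$counts)
  expect_identical(m1$baseline, m2$baseline)
  expect_false(identical(m1$counts,
                         generate(default_synthetic_spec(seed = 43,
                                                         baseline_depth = 1e5,
                                                         column_depths = 5e3))$counts))
  # invariants: containment, exact column depths, exact baseline depth
  expect_true(all(sweep(m1$counts, 1, m1$baseline, `<=`)))
  expect_equal(unname(colSums(m1$counts)), spec$column_depths)
  expect_equal(sum(m1$baseline), spec$baseline_depth)
  # generation does not disturb the caller's RNG stream
  set.seed(99); x <- runif(1)
  set.seed(99); invisible(generate(spec)); y <- runif(1)
  expect_identical(x, y)
})

test_that("expected enrichment follows the closed form", {
  # two equal taxa with f = (2, 1): p_sub = (2/3, 1/3), fold = (4/3, 2/3)
  ee <- expected_enrichment(two_taxon_spec())
  expect_equal(ee$p_sub, 100 * c(2 / 3, 1 / 3))
  expect_equal(ee$fold, c(4 / 3, 2 / 3))
  expect_equal(ee$net, 100 * c(2 / 3 - 0.5, 1 / 3 - 0.5))
  # neutral spec: net 0, fold 1 everywhere
  neutral <- two_taxon_spec(f = c(1, 1))
  en <- expected_enrichment(neutral)
  expect_equal(en$net, c(0, 0))
  expect_equal(en$fold, c(1, 1))
})

test_that("closed-form expectation agrees with the Monte-Carlo mean", {
  spec <- two_taxon_spec(f = c(3, 1), depth = 2e5)
  ee <- expected_enrichment(spec)
  reps <- 30
  p_A <- vapply(seq_len(reps), function(i) {
    spec$seed <- 1000L + i
    m <- generate(spec)
    subcommunity_percentages(m, "d")[["A"]]
  }, numeric(1))
  se <- stats::sd(p_A) / sqrt(reps)
  expect_lt(abs(mean(p_A) - ee$p_sub[ee$taxon == "A"]), 3 * se + 1e-9)
})

test_that("empirical folds track planted effects", {
  # neutral effects at large depth: folds hug 1 for non-rare taxa
  spec <- default_synthetic_spec(seed = 8)
  spec$effects[] <- 1
  et <- enrichment_table(generate(spec))
  common <- et$p_base >= 5
  expect_true(all(et$fold[common] > 0.9 & et$fold[common] < 1.1))
  # planted effects: estimated fold rank order matches the planted rank order
  # among taxa whose expected folds are distinct (tied neutral taxa differ
  # only by sampling noise, so no order is defined for them)
  spec2 <- default_synthetic_spec(seed = 9)
  et2 <- enrichment_table(generate(spec2))
  ee2 <- expected_enrichment(spec2)
  soil <- merge(et2[et2$descriptor == "Soil", ], ee2[ee2$descriptor == "Soil", ],
                by = "taxon", suffixes = c("", ".exp"))
  keep <- soil$taxon %in% c("Acidobacteria", "Actinobacteria", "Firmicutes")
  expect_equal(order(soil$fold[keep]), order(soil$fold.exp[keep]))
})
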