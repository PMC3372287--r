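one_column <- function(counts, label = "d") {
  taxa <- paste0("t", seq_along(counts))
  count_matrix(matrix(counts, ncol = 1, dimnames = list(taxa, label)),
               baseline = pmax(counts, 1),
               archaea = NA_character_, uncultured = NA_character_)
}

test_that("indices match the direct-summation oracle on (50, 30, 20)", {
  # oracle values frozen from explicit sums over p = (0.5, 0.3, 0.2):
  # D = 0.38, H' = -(0.5 ln 0.5 + 0.3 ln 0.3 + 0.2 ln 0.2)
  idx <- community_indices(one_column(c(50, 30, 20)), "d")
  expect_equal(idx$S, 3L)
  expect_equal(round(idx$inv_simpson, 4), 2.6316)
  expect_equal(round(idx$shannon, 4), 1.0297)
  expect_equal(round(idx$simpson_evenness, 4), 0.8772)
  expect_equal(round(idx$pielou, 4), 0.9372)
})

test_that("indices agree with vegan on random communities", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:10) {
    counts <- sample(0:500, sample(3:10, 1))
    counts[1] <- counts[1] + 1 # at least one record
    idx <- community_indices(one_column(counts), "d")
    x <- counts[counts > 0]
    expect_equal(idx$shannon, unname(vegan::diversity(x, "shannon")))
    expect_equal(idx$inv_simpson, unname(vegan::diversity(x, "invsimpson")))
  }
})

test_that("degenerate communities hit the documented identities", {
  # monodominance
  mono <- community_indices(one_column(c(0, 99, 0)), "d")
  expect_equal(mono$S, 1L)
  expect_equal(mono$inv_simpson, 1)
  expect_equal(mono$shannon, 0)
  expect_true(is.na(mono$pielou))
  # uniform community over k taxa: maximal diversity and evenness
  for (k in c(2, 5, 12)) {
    u <- community_indices(one_column(rep(7, k)), "d")
    expect_equal(u$inv_simpson, k)
    expect_equal(u$shannon, log(k))
    expect_equal(u$simpson_evenness, 1)
    expect_equal(u$pielou, 1)
  }
  # empty column is a marked empty community
  empty <- community_indices(one_column(c(0, 0)), "d")
  expect_equal(empty$S, 0L)
  expect_true(is.na(empty$inv_simpson))
})

test_that("indices are replication-invariant and respect Hill ordering", {
  set.seed(3)
  for (i in 1:15) {
    counts <- sample(0:200, sample(2:8, 1))
    counts[1] <- counts[1] + 1
    a <- community_indices(one_column(counts), "d")
    b <- community_indices(one_column(counts * 2), "d")
    expect_equal(b, a)
    # Hill ordering N1 >= N2 >= 1
    expect_gte(exp(a$shannon) + 1e-12, a$inv_simpson)
    expect_gte(a$inv_simpson, 1)
    # bounds when S >= 2
    if (a$S >= 2) {
      expect_lte(a$shannon, log(a$S) + 1e-12)
      expect_true(a$simpson_evenness >= 0 && a$simpson_evenness <= 1)
      expect_true(a$pielou >= 0 && a$pielou <= 1 + 1e-12)
    }
  }
})

test_that("merging two equal-proportion taxa decreases H' and 1/D", {
  a <- community_indices(one_column(c(40, 40, 20)), "d")
  merged <- community_indices(one_column(c(80, 20)), "d")
  expect_lt(merged$shannon, a$shannon)
  expect_lt(merged$inv_simpson, a$inv_simpson)
})

test_that("the log base rescales H' but not J'", {
  m <- one_column(c(50, 30, 20))
  ln <- community_indices(m, "d")
  l2 <- community_indices(m, "d", log_base = "log2")
  expect_equal(l2$shannon, ln$shannon / log(2))
  expect_equal(l2$pielou, ln$pielou)
})

test_that("index_report ranks descriptors stably with label tie-breaks", {
  taxa <- c("A", "B", "C")
  counts <- cbind(uniform = c(10, 10, 10), mono = c(30, 0, 0),
                  mid = c(20, 9, 1))
  rownames(counts) <- taxa
  m <- count_matrix(counts, baseline = c(50, 50, 50),
                    archaea = NA_character_, uncultured = NA_character_)
  rep <- index_report(m, sort_by = "shannon")
  expect_equal(rep$descriptor, c("uniform", "mid", "mono"))
  # the uniform column dominates the monodominant one on the diversity
  # indices; on the evenness indices both are maximally even (tie), where the
  # stable label tie-break applies
  for (s in c("inv_simpson", "shannon")) {
    expect_equal(index_report(m, sort_by = s)$descriptor[1], "uniform")
  }
  es <- index_report(m, sort_by = "simpson_evenness")
  expect_equal(es$simpson_evenness[es$descriptor == "uniform"],
               es$simpson_evenness[es$descriptor == "mono"])
  expect_equal(es$descriptor[1:2], c("mono", "uniform"))
  # permuting taxa rows leaves all indices unchanged
  m_perm <- count_matrix(counts[c(3, 1, 2), ], c(50, 50, 50),
                         archaea = NA_character_, uncultured = NA_character_)
  expect_equal(index_report(m_perm), index_report(m))
  # independent recomputation oracle on a random matrix
  set.seed(5)
  rm <- random_matrix(5, 4)
  rep2 <- index_report(rm)
  for (i in seq_len(nrow(rep2))) {
    n <- rm$counts[rm$analysis, rep2$descriptor[i]]
    p <- n[n > 0] / sum(n)
    expect_equal(rep2$inv_simpson[i], 1 / sum(p^2))
    expect_equal(rep2$shannon[i], -sum(p * log(p)))
  }
})
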