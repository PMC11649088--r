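test_that("individual-level heterozygosity matches its frequency form and edge cases", {
  expect_equal(het_ind(c(0, 1)), 0.5) # p = 0.5 attains the maximum
  expect_equal(het_ind(c(0, 1, 1, 0)), 0.5)
  expect_equal(het_ind(rep(0, 5)), 0)
  expect_equal(het_ind(rep(1, 3)), 0)
  expect_error(het_ind(numeric(0)), class = "popdiv_invalid_input")
  expect_error(het_ind(c(0, 2)), class = "popdiv_invalid_input")
})

test_that("individual-level SSD is the both-states-present indicator", {
  expect_equal(ssd_ind(c(0, 1)), 1)
  expect_equal(ssd_ind(c(1, 1, 1)), 0)
  expect_equal(ssd_ind(c(0, 0)), 0)
  for (form in c("frequency", "pairwise", "linear")) {
    expect_equal(ssd_ind(c(0, 0, 1), form = form), 1)
  }
  expect_error(ssd_ind(numeric(0)), class = "popdiv_invalid_input")
})

test_that("collection measures reproduce the worked island values", {
  A1 <- c(0.1, 0.9)
  B1 <- c(0.5, 0.5)
  expect_equal(het_pooling(A1), 0.5)
  expect_equal(het_pooling(B1), 0.5)
  expect_equal(het_averaging(A1), 0.18)
  expect_equal(het_averaging(B1), 0.5)
  expect_equal(het_differencing(A1), 0.32)
  expect_equal(het_differencing(B1), 0)
  expect_equal(het_fixing(A1), 0.41)
  expect_equal(het_fixing(B1), 0.25)
  expect_equal(ssd_pooling(A1), 1)
  expect_equal(ssd_differencing(A1), 0.64)
  expect_equal(ssd_fixing(A1), 0.82)
  expect_equal(ssd_fixing(B1), 0.5)
})

test_that("degenerate and boundary frequency vectors score as expected", {
  expect_equal(het_pooling(c(0, 0)), 0)
  expect_equal(het_averaging(c(0, 1)), 0)
  expect_equal(het_fixing(c(1, 1)), 0)
  expect_equal(ssd_pooling(c(0, 0, 0)), 0)
  expect_equal(ssd_pooling(c(1, 1)), 0)
  expect_equal(ssd_averaging(c(0.5, 0.5)), 1)
  expect_equal(ssd_averaging(c(0, 1)), 0)
  expect_equal(ssd_averaging(c(0.1, 0, 1, 0.9)), 0.5)
  expect_equal(ssd_differencing(c(0.5, 0.5)), 0)
  expect_equal(ssd_differencing(c(0, 0.3, 1)), 1)
  expect_equal(ssd_fixing(c(1, 1, 1)), 0)
  expect_error(het_pooling(c(0.2, 1.2)), class = "popdiv_invalid_input")
})

test_that("second island example ordering holds measure by measure", {
  A2 <- c(0.2, 0.2)
  B2 <- c(0.1, 0)
  expect_equal(het_pooling(A2), 0.32)
  expect_equal(het_pooling(B2), 0.095)
  expect_equal(het_differencing(A2), 0)
  expect_equal(het_differencing(B2), 0.005)
  expect_gt(het_pooling(A2), het_pooling(B2))
  expect_gt(het_averaging(A2), het_averaging(B2))
  expect_gt(het_fixing(A2), het_fixing(B2))
  expect_gt(het_differencing(B2), het_differencing(A2))
})

test_that("size weighting shifts pooled/averaged scores and reduces when equal", {
  p <- c(0.1, 0.9)
  w <- c(3, 1)
  pbar <- (3 * 0.1 + 1 * 0.9) / 4
  expect_equal(het_pooling(p, weights = w), 2 * pbar * (1 - pbar))
  expect_equal(het_averaging(p, weights = w),
               (3 * 2 * 0.1 * 0.9 + 1 * 2 * 0.9 * 0.1) / 4)
  expect_equal(het_pooling(p, weights = c(2, 2)), het_pooling(p))
  expect_equal(ssd_averaging(c(0.5, 0), weights = c(1, 3)), 0.25)
  expect_error(het_pooling(p, weights = c(1, -1)), class = "popdiv_invalid_input")
})

test_that("collection_diversity sums per-locus scores and validates labels", {
  M <- frequency_matrix(rbind(A = c(0.1, 0.1), B = c(0.9, 0.9)))
  res <- collection_diversity(M, c("A", "B"), "het_averaging")
  expect_s3_class(res, "diversity_result")
  expect_equal(res$total, 0.36) # two loci, each the 0.18 island score
  expect_equal(unname(res$per_locus), c(0.18, 0.18))
  expect_equal(res$total, sum(res$per_locus))

  expect_equal(collection_diversity(M, "A", "het_differencing")$total, 0)
  zero <- frequency_matrix(matrix(0, 3, 4))
  for (mm in diversity_measures()) {
    expect_equal(collection_diversity(zero, measure = mm)$total, 0)
  }
  expect_error(collection_diversity(M, c("A", "Z"), "het_pooling"),
               class = "popdiv_unknown_label")
  expect_error(collection_diversity(M, c("A", "B"), "het_bogus"),
               class = "popdiv_invalid_input")
  expect_error(collection_diversity(M, character(0), "het_pooling"),
               class = "popdiv_invalid_input")
})

test_that("individuals_to_frequencies takes column means and records sizes", {
  one <- individual_matrix(rbind(c(0, 1), c(1, 1)))
  M <- individuals_to_frequencies(list(P = one))
  expect_equal(unname(unclass(M)[1, ]), c(0.5, 1))
  expect_equal(pop_sizes(M), c(P = 2))

  zero <- individual_matrix(matrix(0, 3, 2))
  M0 <- individuals_to_frequencies(list(zero))
  expect_true(all(unclass(M0) == 0))

  # single-population heterozygosity equals pooling of its one-row matrix
  x <- c(0, 1, 1, 0, 1)
  Mx <- individuals_to_frequencies(list(individual_matrix(matrix(x, ncol = 1))))
  expect_equal(het_pooling(unclass(Mx)[, 1]), het_ind(x))

  a <- individual_matrix(matrix(0, 2, 2), loci = c("l1", "l2"))
  b <- individual_matrix(matrix(0, 2, 2), loci = c("l1", "l3"))
  expect_error(individuals_to_frequencies(list(a, b)), class = "popdiv_invalid_input")
})

test_that("vectorised subset scoring agrees with per-locus collection_diversity", {
  set.seed(31)
  M <- frequency_matrix(matrix(random_freq_vector(8 * 6), nrow = 8))
  subsets <- list(1L, c(2L, 5L), c(1L, 3L, 8L), 1:5)
  fast <- subset_scores(M, subsets)
  for (mm in diversity_measures()) {
    slow <- vapply(subsets, function(s) collection_diversity(M, s, mm)$total,
                   numeric(1))
    expect_equal(unname(fast[, mm]), slow, tolerance = 1e-12)
  }
})
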