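test_that("pearson_r handles perfect linearity and degeneracy explicitly", {
  x <- c(1, 2, 5, 7)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(3, 4)), class = "popdiv_undefined_correlation")
  expect_error(pearson_r(x, x[1:3]), class = "popdiv_invalid_input")
  expect_error(pearson_r(1, 2), class = "popdiv_invalid_input")
  # symmetric and invariant under positive affine transforms
  set.seed(8)
  a <- runif(20)
  b <- runif(20)
  expect_equal(pearson_r(a, b), pearson_r(b, a))
  expect_equal(pearson_r(3 * a + 2, b), pearson_r(a, b), tolerance = 1e-12)
})

test_that("sampled-correlation standard error follows (1 - r^2)/sqrt(N - 3)", {
  expect_equal(correlation_se(1, 100), 0)
  expect_equal(correlation_se(0, 1000), 1 / sqrt(997))
  expect_equal(correlation_se(0.5, 103), 0.075)
  expect_error(correlation_se(0.5, 3), class = "popdiv_invalid_input")
})

test_that("fixing-approach Het and SSD totals correlate perfectly for k = 2 and 3", {
  M <- uniform_matrix(12, 80, seed = 21)
  for (k in 2:3) {
    sc <- subset_scores(M, combn(12, k), measures = c("het_fixing", "ssd_fixing"))
    expect_equal(pearson_r(sc[, 1], sc[, 2]), 1, tolerance = 1e-9)
  }
})

test_that("differencing-approach Het and SSD are proportional at k = 2", {
  M <- salmon_like_matrix(15, 60, seed = 33)
  sc <- subset_scores(M, combn(15, 2),
                      measures = c("het_differencing", "ssd_differencing"))
  # per locus het_differencing = ssd_differencing / 2 when k = 2
  expect_equal(sc[, 1], sc[, 2] / 2, tolerance = 1e-12)
  expect_gte(pearson_r(sc[, 1], sc[, 2]), 0.999)
})

test_that("correlation_matrix reuses one score table and flags degenerate pairs", {
  M <- uniform_matrix(8, 40, seed = 3)
  rep3 <- correlation_matrix(M, 3, mode = "exhaustive")
  expect_s3_class(rep3, "correlation_report")
  expect_equal(nrow(rep3), choose(8, 2))
  expect_true(all(rep3$n_subsets == choose(8, 3)))
  defined <- !is.na(rep3$r)
  expect_true(all(abs(rep3$r[defined]) <= 1))
  expect_true(all(rep3$se[defined] >= 0))
  # continuous uniform entries: pooled/averaged SSD are constant -> flagged
  degen <- rep3$measure_x == "ssd_pooling" | rep3$measure_y == "ssd_pooling" |
    rep3$measure_x == "ssd_averaging" | rep3$measure_y == "ssd_averaging"
  expect_true(all(is.na(rep3$r[degen])))
  expect_true(all(rep3$note[degen] != ""))
  expect_true(all(rep3$note[!degen] == ""))

  # a measure correlates perfectly with itself
  sc <- subset_scores(M, combn(8, 3), measures = c("het_pooling", "het_pooling"))
  expect_equal(pearson_r(sc[, 1], sc[, 2]), 1)
})

test_that("sampled mode is reproducible and records its seed", {
  M <- salmon_like_matrix(20, 50, seed = 4)
  r1 <- correlation_matrix(M, 6, mode = "sampled", N = 200, seed = 99)
  r2 <- correlation_matrix(M, 6, mode = "sampled", N = 200, seed = 99)
  expect_identical(r1$r, r2$r)
  expect_true(all(r1$seed == 99L))
  expect_true(all(r1$n_subsets == 200L))
  expect_true(all(r1$se[!is.na(r1$r)] == correlation_se(r1$r[!is.na(r1$r)], 200)))
})

test_that("locus-summed correlation matches single-locus correlation structure", {
  # duplicated column: summing scales both variables, r is unchanged exactly
  set.seed(55)
  M1 <- frequency_matrix(matrix(random_freq_vector(10), ncol = 1))
  M2 <- frequency_matrix(cbind(unclass(M1)[, 1], unclass(M1)[, 1]))
  pair <- c("het_averaging", "het_differencing")
  chk1 <- locus_sum_correlation_check(M1, 2, pair)
  chk2 <- locus_sum_correlation_check(M2, 2, pair)
  expect_equal(chk1$summed_r, chk1$per_locus_r[1])
  expect_equal(chk2$summed_r, chk1$summed_r, tolerance = 1e-12)
  expect_equal(chk2$per_locus_r, rep(chk1$summed_r, 2), tolerance = 1e-12)

  # i.i.d. columns: summed r within sampling spread of the single-locus r's
  M <- uniform_matrix(10, 40, seed = 14)
  chk <- locus_sum_correlation_check(M, 2, pair)
  spread <- stats::sd(chk$per_locus_r, na.rm = TRUE)
  expect_lt(abs(chk$summed_r - chk$mean_locus_r), 3 * spread)
})

test_that("correlation reports round-trip through CSV", {
  M <- uniform_matrix(6, 20, seed = 2)
  rep2 <- correlation_matrix(M, 2, measures = c("het_pooling", "het_averaging",
                                                "het_fixing"))
  path <- tempfile(fileext = ".csv")
  write_correlation_report(rep2, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$r, rep2$r, tolerance = 1e-12)
})
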