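test_that("published contingency statistics reproduce from the raw counts", {
  ct <- contingency_table(counts = table1_counts())
  expect_equal(ct$chi_square, 112.608, tolerance = 5e-4)
  expect_equal(ct$likelihood_ratio, 118.450, tolerance = 5e-4)
  expect_equal(ct$expected["tropical_moist_broadleaf", "melanistic"], 21.2,
               tolerance = 3e-3)
  ar <- ct$adjusted_residuals
  expect_equal(round(ar["tropical_moist_broadleaf", ], 1), c(-10.5, 10.5),
               ignore_attr = TRUE)
  expect_equal(round(ar["desert_xeric", ], 1), c(3.1, -3.1),
               ignore_attr = TRUE)
  expect_equal(round(ar["tropical_grassland", ], 1), c(4.4, -4.4),
               ignore_attr = TRUE)
  expect_equal(ct$pct_within_landscape["tropical_moist_broadleaf",
                                       "melanistic"], 30.1, tolerance = 2e-3)
  expect_equal(round(sum(ct$pct_of_total[, "melanistic"]), 1), 10.8)
  expect_equal(ct$dof, 10)
})

test_that("chi-square and G match an independent brute-force oracle", {
  set.seed(10)
  for (i in 1:5) {
    counts <- matrix(rpois(8, lambda = sample(5:60, 1)), ncol = 2)
    counts[counts == 0] <- 1
    rownames(counts) <- paste0("b", 1:4)
    ct <- contingency_table(counts = counts)
    or <- oracle_chisq(counts)
    expect_equal(ct$chi_square, or$chi, tolerance = 1e-9)
    expect_equal(ct$likelihood_ratio, or$g, tolerance = 1e-9)
    # margins of expected match observed margins
    expect_equal(rowSums(ct$expected), rowSums(counts))
    expect_equal(colSums(ct$expected), colSums(counts))
    # two cells of a row have equal-magnitude, opposite-sign residuals
    expect_equal(ct$adjusted_residuals[, 1], -ct$adjusted_residuals[, 2])
    # column swap flips residual signs
    ct2 <- contingency_table(counts = counts[, 2:1])
    expect_equal(ct2$adjusted_residuals[, 1], ct$adjusted_residuals[, 2])
  }
})

test_that("G and chi-square agree asymptotically on well-filled tables", {
  set.seed(11)
  for (i in 1:10) {
    p <- matrix(runif(8, 0.5, 1.5), ncol = 2)
    p <- p / sum(p)
    counts <- matrix(rmultinom(1, 2000, as.vector(p)), ncol = 2)
    ct <- contingency_table(counts = counts)
    if (all(ct$expected >= 20))
      expect_lt(abs(ct$likelihood_ratio - ct$chi_square) /
                  max(ct$chi_square, 1e-12), 0.1)
  }
})

test_that("degenerate tables: independence gives zeros, empties rejected", {
  ct <- contingency_table(counts = matrix(c(10, 10, 5, 5), 2,
                                          dimnames = list(c("x", "y"), NULL)))
  expect_equal(ct$chi_square, 0)
  expect_true(all(abs(ct$adjusted_residuals) < 1e-12))
  expect_error(contingency_table(counts = matrix(0, 2, 2)), "empty")
  expect_warning(
    ct2 <- contingency_table(counts = matrix(c(5, 0, 5, 0), 2,
                                             dimnames = list(c("a", "z"), NULL))),
    "zero total")
  expect_equal(nrow(ct2$counts), 1)
})

test_that("linear-by-linear uses configurable scores", {
  counts <- table1_counts()
  ct <- contingency_table(counts = counts)
  # default scores: (N-1) * r^2 oracle
  x <- rep(rep(seq_len(nrow(counts)), 2), as.vector(counts))
  y <- rep(rep(c(0, 1), each = nrow(counts)), as.vector(counts))
  expect_equal(ct$linear_by_linear, (sum(counts) - 1) * cor(x, y)^2,
               tolerance = 1e-12)
  # reversing row scores leaves the squared-trend statistic unchanged
  ct_rev <- contingency_table(counts = counts,
                              row_scores = rev(seq_len(nrow(counts))))
  expect_equal(ct_rev$linear_by_linear, ct$linear_by_linear, tolerance = 1e-9)
})

test_that("phenotype frequency honours the denominator policy", {
  rec <- make_records(624, seed = 6)
  rec$phenotype[1:67] <- "melanistic"
  rec$phenotype[68:72] <- "unconfirmed_melanistic"
  rec <- read_records(rec)
  expect_equal(phenotype_frequency(rec)$frequency_pct, 100 * 67 / 619,
               tolerance = 1e-12)
  expect_equal(phenotype_frequency(rec, "all_records")$frequency_pct,
               100 * 67 / 624, tolerance = 1e-12)
  expect_equal(round(phenotype_frequency(rec)$frequency_pct, 1), 10.8)
  none <- read_records(make_records(5))
  expect_equal(phenotype_frequency(none)$frequency_pct, 0)
})

test_that("contingency CSV export round-trips the table", {
  ct <- contingency_table(counts = table1_counts())
  path <- tempfile(fileext = ".csv")
  write_contingency_csv(ct, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 11)
  expect_equal(back$count_mel[back$biome == "tropical_moist_broadleaf"], 59)
  expect_equal(back$adj_residual_mel[back$biome == "tropical_moist_broadleaf"],
               ct$adjusted_residuals["tropical_moist_broadleaf", 2])
})
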