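test_that("relative abundances are exact row-normalized proportions", {
  ct <- toy_counts()
  rel <- to_relative_abundance(ct)
  expect_equal(unname(rel$values["s1", ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(rowSums(rel$values)), rep(1, 3), tolerance = 1e-12)

  # degenerate single-feature table
  one <- count_table(matrix(c(7, 3), 2, 1,
                            dimnames = list(c("a", "b"), "f")))
  expect_equal(unname(to_relative_abundance(one)$values[, 1]), c(1, 1))

  zero <- count_table(rbind(a = c(0, 0, 0), b = c(1, 2, 3)))
  expect_error(to_relative_abundance(zero), "a")

  set.seed(4)
  big <- count_table(matrix(rpois(600, 20), 20, 30))
  expect_equal(unname(rowSums(to_relative_abundance(big)$values)),
               rep(1, 20), tolerance = 1e-12)
})

test_that("sqrt and arcsine transforms are exact and strictly monotone", {
  vals <- rbind(a = c(0, 0.25, 0.75), b = c(0.5, 0.25, 0.25),
                c = c(1, 0, 0))
  rel <- abundance_table(vals, stage = "relative")

  sq <- transform_sqrt(rel)
  expect_identical(sq$stage, "sqrt_transformed")
  expect_equal(unname(sq$values["a", ]), c(0, 0.5, sqrt(0.75)))

  ar <- transform_arcsine(rel)
  expect_identical(ar$stage, "arcsine_transformed")
  expect_equal(unname(ar$values["c", 1]), pi / 2)
  expect_equal(unname(ar$values["a", 1]), 0)
  expect_equal(unname(ar$values["a", 2]), pi / 6)
  expect_equal(unname(ar$values["b", 1]), pi / 4)

  # arcsine equals the composition arcsin o sqrt, cellwise
  expect_equal(ar$values, asin(sq$values), tolerance = 1e-15)

  # strict monotonicity on a random grid of proportion pairs
  set.seed(9)
  p <- sort(runif(50))
  expect_true(all(diff(sqrt(p)) > 0))
  expect_true(all(diff(asin(sqrt(p))) > 0))
  expect_true(all(asin(sqrt(p)) >= 0 & asin(sqrt(p)) <= pi / 2))

  # stage discipline
  expect_error(transform_sqrt(sq), "relative")
  expect_error(transform_arcsine(ar), "relative")
})

test_that("Bartlett's statistic matches the textbook formula", {
  # fixed example: two samples, four feature values each
  g <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  res <- bartlett_homogeneity(g)
  ora <- oracle_bartlett(list(g[1, ], g[2, ]))
  expect_equal(res$statistic, ora$statistic, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, ora$p_value, tolerance = 1e-10)

  # 100 random tables against the direct formula
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    m <- sample(3:8, 1)
    vals <- matrix(rnorm(n * m, sd = runif(1, 0.5, 2)), n, m)
    res <- bartlett_homogeneity(vals)
    ora <- oracle_bartlett(split(vals, row(vals)))
    expect_equal(res$statistic, ora$statistic, tolerance = 1e-10)
    expect_equal(res$df, n - 1)
  }

  # identical within-sample variances give statistic 0, p-value 1
  eq <- rbind(a = c(1, 2, 3), b = c(11, 12, 13))
  res <- bartlett_homogeneity(eq)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  # scale invariance
  set.seed(12)
  v <- matrix(rnorm(24), 4, 6)
  expect_equal(bartlett_homogeneity(v)$statistic,
               bartlett_homogeneity(7.3 * v)$statistic, tolerance = 1e-10)

  # degenerate inputs are refused with the offending sample named
  expect_error(bartlett_homogeneity(matrix(1:4, 2, 2) * c(1, 0)),
               "zero within-sample variance")
  expect_error(bartlett_homogeneity(matrix(1:3, 3, 1)), "m < 2")
})

test_that("transform choice follows the homogeneity-and-band rule", {
  # homogeneous variances: no transform advised
  set.seed(21)
  base <- abs(rnorm(10, 1, 0.1))
  hom <- t(replicate(6, base + rnorm(10, sd = 0.01)))
  hom <- hom / rowSums(hom)
  expect_identical(choose_transform(abundance_table(hom, stage = "relative")),
                   "none")

  # heterogeneous, all proportions in the low band -> sqrt
  low <- rbind(rep(c(0.11, 0.09), 5),            # near-uniform, tiny variance
               rep(c(0.2, 0.0), 5),              # spread, large variance
               rep(c(0.15, 0.05), 5))
  ab_low <- abundance_table(low, stage = "relative")
  expect_lt(bartlett_homogeneity(ab_low)$p_value, 0.05)
  expect_identical(choose_transform(ab_low), "sqrt")

  # heterogeneous with values in both bands -> arcsine
  both <- rbind(c(0.75, 0.2, 0.05, 0), c(0.97, 0.01, 0.01, 0.01),
                c(0.28, 0.24, 0.24, 0.24))
  ab_both <- abundance_table(both, stage = "relative")
  expect_lt(bartlett_homogeneity(ab_both)$p_value, 0.05)
  expect_identical(choose_transform(ab_both), "arcsine")
})
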