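test_that("Lilliefors gate rejects degenerate input and matches nortest's D", {
  expect_error(lilliefors_ks(rep(3, 4)), "degenerate")
  expect_error(lilliefors_ks(c(1, 2, 3)), "at least 4")
  skip_if_not_installed("nortest")
  set.seed(77)
  for (i in 1:5) {
    x <- rnorm(15 + i)
    expect_equal(attr(lilliefors_ks(x, n_mc = 100), "statistic"),
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("Lilliefors test is calibrated under the null and powerful vs skew", {
  set.seed(101)
  p_null <- replicate(1000, lilliefors_ks(rnorm(20), n_mc = 5000))
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.02)
  p_exp <- replicate(100, lilliefors_ks(rexp(100), n_mc = 2000))
  expect_gt(mean(p_exp < 0.05), 0.9)
})

test_that("Mann-Whitney exact path agrees with enumeration references", {
  # canonical extreme split: 2 of C(6,3)=20 assignments are as extreme
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$method,
               "exact enumeration")
  # tie-free small samples agree with the exact wilcoxon distribution
  set.seed(42)
  for (i in 1:10) {
    a <- round(rnorm(4), 6); b <- round(rnorm(4, 0.5), 6)
    expect_equal(mann_whitney(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # large samples fall back to the tie-corrected normal approximation
  set.seed(7)
  big <- mann_whitney(rnorm(10), rnorm(10))
  expect_equal(big$method, "normal approximation")
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("gated comparison picks the right test and is symmetric", {
  set.seed(5)
  a <- rnorm(8, 10, 1); b <- rnorm(8, 12, 1)
  cmp <- compare_groups(a, b)
  expect_equal(cmp$test_used, "student_t")
  expect_equal(cmp$p_value,
               stats::t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(cmp$significant, cmp$p_value < 0.05)
  # swapping groups keeps P and inverts the fold-change
  rev <- compare_groups(b, a)
  expect_equal(rev$p_value, cmp$p_value)
  expect_equal(rev$fold_change, 1 / cmp$fold_change, tolerance = 1e-12)
  # heavy skew in one group routes to Mann-Whitney
  set.seed(6)
  skewed <- exp(rnorm(30, 0, 2))
  cmp2 <- compare_groups(rnorm(30), skewed)
  expect_equal(cmp2$test_used, "mann_whitney")
  # identical samples: fold-change 1, p ~ 1
  x <- c(1.2, 3.4, 2.2, 4.8)
  same <- compare_groups(x, x)
  expect_equal(same$fold_change, 1)
  expect_gte(same$p_value, 0.99)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("Pearson correlation matches hand-computed references", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1)$p_value, 0)
  expect_equal(pearson_r(1:4, -(1:4))$r, -1)
  res <- pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$p_value, stats::cor.test(c(1, 2, 3, 4),
                                            c(1, 3, 2, 4))$p.value,
               tolerance = 1e-10)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "length")
})
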