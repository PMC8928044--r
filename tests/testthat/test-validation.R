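test_that("Clopper-Pearson matches brute-force tail inversion to 1e-9", {
  for (n in c(1, 2, 5, 13, 29, 50)) {
    for (x in 0:n) {
      got <- clopper_pearson(x, n)
      want <- cp_oracle(x, n)
      expect_equal(unname(got), want, tolerance = 1e-9,
                   label = sprintf("CI for x=%d n=%d", x, n))
    }
  }
})

test_that("Clopper-Pearson boundary cases have closed forms", {
  expect_identical(clopper_pearson(0, 5)[["low"]], 0)
  expect_identical(clopper_pearson(5, 5)[["high"]], 1)
  expect_equal(clopper_pearson(158, 158)[["low"]], 0.025^(1 / 158),
               tolerance = 1e-12)
  expect_error(clopper_pearson(3, 10, level = 1.2), "level")
  expect_error(clopper_pearson(11, 10), "0 <= x <= n")
})

test_that("Clopper-Pearson agrees with binom.test and is monotone in x", {
  for (x in c(0, 3, 7, 10)) {
    bt <- binom.test(x, 10)$conf.int
    expect_equal(unname(clopper_pearson(x, 10)), as.numeric(bt),
                 tolerance = 1e-10)
  }
  ci <- t(vapply(0:30, function(x) clopper_pearson(x, 30), numeric(2)))
  expect_true(all(diff(ci[, 1]) > 0 | (ci[-31, 1] == 0 & ci[-1, 1] >= 0)))
  expect_true(all(diff(ci[, 2]) > 0 | (ci[-1, 2] == 1)))
  # the interval always contains the point estimate
  expect_true(all(ci[, 1] <= (0:30) / 30 & (0:30) / 30 <= ci[, 2]))
})

test_that("interval coverage is at least nominal in simulation", {
  set.seed(1)
  n <- 30
  for (p in c(0.1, 0.5, 0.9)) {
    x <- rbinom(10000, n, p)
    lo <- qbeta(0.025, x, n - x + 1)
    lo[x == 0] <- 0
    hi <- qbeta(0.975, x + 1, n - x)
    hi[x == n] <- 1
    covered <- mean(lo <= p & p <= hi)
    expect_gte(covered, 0.95)
  }
})

test_that("PPV and sensitivity are verified-over-flagged ratios", {
  e <- ppv(158, 200)
  expect_equal(e$estimate, 0.79)
  expect_equal(ppv(142, 200)$estimate, 0.71)
  expect_equal(ppv(0, 10)$estimate, 0)
  expect_error(ppv(1, 0), "no flagged")
  expect_error(ppv(5, 3), "n_true")
  s <- sensitivity(142, 158)
  expect_equal(round(s$estimate, 3), 0.899)
  expect_equal(sensitivity(79, 79)$estimate, 1)
  # the same ratio at reduced counts gives the same estimate, wider CI
  s2 <- sensitivity(71, 79)
  expect_equal(s2$estimate, s$estimate)
  expect_gt(s2$ci_high - s2$ci_low, s$ci_high - s$ci_low)
  expect_error(sensitivity(1, 0), "no condition-positive")
})

test_that("specificity and LR+ are refused under the case-only design", {
  expect_error(specificity(10, 20), "not estimable from this design")
  expect_error(positive_likelihood_ratio(0.9, 0.8), "not estimable")
  expect_equal(specificity(18, 20, design = "case_control")$estimate, 0.9)
  expect_equal(positive_likelihood_ratio(0.9, 0.8, design = "case_control"),
               4.5)
})

test_that("contingency table construction validates shape and counts", {
  expect_error(contingency_table(matrix(1:3, 3, 1)), "at least 2")
  expect_error(contingency_table(matrix(c(1, -1, 2, 3), 2)), "nonnegative")
  expect_error(contingency_table(matrix(c(1.5, 1, 2, 3), 2)), "nonnegative")
  tab <- contingency_table(matrix(c(2, 1, 0, 4), 2),
                           row_labels = c("a", "b"), col_labels = c("x", "y"))
  expect_identical(rownames(tab), c("a", "b"))
})

test_that("the validation table tallies histopathology against the index", {
  recs <- list(
    make_record("V1", clinical = "respiratory_symptoms",
                biopsies = biopsy_records("lung", "nonnecrotizing_granuloma")),
    make_record("V2", clinical = "respiratory_symptoms"),
    make_record("V3"))
  tab <- build_validation_table(classify_cohort(recs))
  expect_identical(unclass(unname(tab)),
                   matrix(c(1L, 1L, 0L, 1L), 2))
  single <- build_validation_table(classify_cohort(recs[1]))
  expect_identical(as.integer(single), c(1L, 0L, 0L, 0L))
  expect_error(build_validation_table(classify_cohort(list())), "empty")
  # low-index patients with granulomas land in the granuloma/low cell
  recs4 <- c(recs, list(make_record("V4",
    biopsies = biopsy_records("skin", "nonnecrotizing_granuloma"))))
  tab4 <- build_validation_table(classify_cohort(recs4))
  expect_identical(tab4[["granuloma_confirmed", "low"]], 1L)
})

test_that("chi-square test matches the algebraic 2x2 formula", {
  res <- chi_square_test(contingency_table(matrix(c(127, 15, 15, 1), 2)))
  expect_equal(round(res$p_value, 2), 0.59)
  expect_identical(res$df, 1L)
  same <- chi_square_test(contingency_table(matrix(c(5, 5, 7, 7), 2,
                                                   byrow = TRUE)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(3)
  for (i in 1:20) {
    m <- matrix(rpois(4, 20) + 1, 2)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    n <- sum(m)
    hand <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    got <- chi_square_test(contingency_table(m))
    expect_equal(got$statistic, hand, tolerance = 1e-12)
    expect_equal(chi_square_test(contingency_table(t(m)))$statistic,
                 got$statistic, tolerance = 1e-12)
  }
  wide <- chi_square_test(contingency_table(matrix(rpois(12, 30) + 1, 3)))
  expect_identical(wide$df, 6L)
})

test_that("Fisher exact equals hand-enumerated 2x2 probabilities", {
  # margins (2,2)x(2,2): three candidate tables with probabilities
  # 1/6, 4/6, 1/6; observed diagonal table has p = 1/6, two-sided sum 1/3
  expect_equal(fisher_exact(contingency_table(matrix(c(2, 0, 0, 2), 2))),
               1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact(contingency_table(matrix(1, 2, 2))), 1,
               tolerance = 1e-12)
})

test_that("Fisher exact equals the full-enumeration oracle on small tables", {
  set.seed(11)
  shapes <- list(c(2, 2), c(2, 3), c(3, 2), c(3, 3))
  n_checked <- 0
  while (n_checked < 120) {
    dims <- shapes[[sample.int(4, 1)]]
    m <- matrix(rpois(prod(dims), sample(1:3, 1)), dims[1], dims[2])
    if (sum(m) > 20 || any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p_pkg <- fisher_exact(contingency_table(m))
    p_orc <- fisher_oracle(m)
    expect_equal(p_pkg, p_orc, tolerance = 1e-12,
                 label = paste("fisher", paste(m, collapse = ",")))
    expect_gt(p_pkg, 0)
    expect_lte(p_pkg, 1)
    # invariance under row and column permutation
    expect_equal(fisher_exact(contingency_table(
      m[sample(nrow(m)), sample(ncol(m)), drop = FALSE])), p_pkg,
      tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
})

test_that("oversized tables are refused with a Monte-Carlo suggestion", {
  big <- contingency_table(matrix(rep(60L, 12), 3))
  expect_error(fisher_exact(big), "monte_carlo")
  p1 <- fisher_exact(big, mode = "monte_carlo", B = 2000, seed = 5)
  p2 <- fisher_exact(big, mode = "monte_carlo", B = 2000, seed = 5)
  expect_identical(p1, p2)
})

test_that("Welch t from summaries reproduces published-style p-values", {
  res <- welch_t_from_summary(65.5, 10.8, 142, 69.3, 10.3, 16)
  expect_equal(round(res$p_value, 2), 0.18)
  same <- welch_t_from_summary(50, 5, 20, 50, 5, 20)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # equal variances and equal n: Welch df collapses to the pooled 2n - 2
  eq <- welch_t_from_summary(10, 2, 15, 12, 2, 15)
  expect_equal(eq$df, 28)
  pooled_t <- (10 - 12) / (2 * sqrt(2 / 15))
  expect_equal(eq$t, pooled_t)
  expect_equal(eq$p_value, 2 * pt(-abs(pooled_t), 28))
  expect_error(welch_t_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
  expect_error(welch_t_from_summary(1, 0, 5, 2, 1, 5), "positive SDs")
})

test_that("sarc_validate ties the scalar estimates to the table cells", {
  cohort <- build_fixture_cohort(check = FALSE)
  cls <- classify_cohort(cohort)
  val <- sarc_validate(cls)
  tab <- val$table
  expect_equal(val$ppv_icd_alone$estimate, sum(tab[, "high"]) / sum(tab))
  expect_equal(val$ppv_icd_confirmed$estimate,
               tab["granuloma_confirmed", "high"] / sum(tab))
  expect_equal(val$sensitivity_histopath$estimate,
               tab["granuloma_confirmed", "high"] / sum(tab[, "high"]))
  expect_equal(val$ppv_icd_plus_index$estimate, 1)
})

test_that("validation marks index-based estimates not estimable without highs", {
  recs <- list(make_record("L1"), make_record("L2"))
  val <- sarc_validate(classify_cohort(recs))
  expect_null(val$ppv_icd_plus_index)
  expect_null(val$sensitivity_histopath)
  expect_match(val$notes, "not estimable")
  expect_output(print(val), "not estimable")
})
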