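test_that("empirical ROC handles the textbook cases", {
  # perfect separation: the curve contains (sens 1, spec 1)
  curve <- empirical_roc(c(8, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(curve$sens == 1 & curve$spec == 1))

  # degenerate constant index: only trivial points, AUC 0.5
  idx <- rep(3, 6); out <- rep(c(TRUE, FALSE), 3)
  curve <- empirical_roc(idx, out)
  expect_true(all((curve$sens %in% c(0, 1)) & (curve$spec %in% c(0, 1))))
  expect_equal(auc_mann_whitney(idx, out), 0.5)

  # 1 concordant of 2 informative pairs
  expect_equal(auc_mann_whitney(c(3, 5, 4), c(TRUE, TRUE, FALSE)), 0.5)
  # one win one tie -> (1 + 0.5) / 2
  expect_equal(auc_mann_whitney(c(3, 5, 3), c(TRUE, TRUE, FALSE)), 0.75)
  # clean separation
  expect_equal(auc_mann_whitney(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)

  expect_error(empirical_roc(1:4, rep(TRUE, 4)),
               class = "efindex_validation_error")
})

test_that("Mann-Whitney AUC equals pair counting and the trapezoid area", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    idx <- sample(0:10, n, replace = TRUE)
    out <- runif(n) < 0.5
    if (!any(out) || all(out)) next
    a <- auc_mann_whitney(idx, out)
    expect_equal(a, oracle_auc_pairs(idx, out))
    expect_equal(a, efindex:::.roc_trapezoid_area(empirical_roc(idx, out)))
  }
})

test_that("reversing direction maps AUC to 1 - AUC and swaps the rule", {
  set.seed(12)
  idx <- rpois(50, 5); out <- runif(50) < 0.4
  a_hi <- auc_mann_whitney(idx, out, "higher_is_positive")
  a_lo <- auc_mann_whitney(idx, out, "lower_is_positive")
  expect_equal(a_hi + a_lo, 1)
  c_hi <- empirical_roc(idx, out, "higher_is_positive")
  c_lo <- empirical_roc(idx, out, "lower_is_positive")
  expect_equal(efindex:::.roc_trapezoid_area(c_lo),
               1 - efindex:::.roc_trapezoid_area(c_hi))
})

test_that("Hanley-McNeil SE matches its closed forms and the printed value", {
  # symmetric null case: Q1 = Q2 = 1/3 and SE^2 = (n+1) / (12 n^2)
  for (n in c(10, 50, 85)) {
    expect_equal(auc_se_hanley_mcneil(0.5, n, n),
                 sqrt((0.25 + 2 * (n - 1) * (1 / 3 - 0.25)) / n^2))
    expect_equal(auc_se_hanley_mcneil(0.5, n, n),
                 sqrt((2 * n + 1) / (12 * n^2)))
  }
  # the published cohort: printed SE 0.039, our value within +/- 0.002
  expect_equal(auc_se_hanley_mcneil(0.641, 85, 114), 0.039,
               tolerance = 0.002 / 0.039)
  expect_error(auc_se_hanley_mcneil(1, 10, 10),
               class = "efindex_validation_error")
})

test_that("bootstrap SE agrees with Hanley-McNeil on a well-behaved cohort", {
  set.seed(13)
  idx <- c(rnorm(90, 1), rnorm(110, 0))
  out <- rep(c(TRUE, FALSE), c(90, 110))
  hm <- auc_se_hanley_mcneil(auc_mann_whitney(idx, out), 90, 110)
  bs <- auc_se_bootstrap(idx, out, reps = 2000, seed = 99)
  expect_equal(bs, hm, tolerance = 0.25)
  # seeded bootstrap is reproducible
  expect_identical(bs, auc_se_bootstrap(idx, out, reps = 2000, seed = 99))
})

test_that("Wald CI and the test against 0.5 reproduce the printed rows", {
  ct <- auc_ci_test(0.641, 0.039)
  expect_equal(ct$ci[1], 0.564, tolerance = 0.001 / 0.564)
  expect_equal(ct$ci[2], 0.717, tolerance = 0.001 / 0.717)
  expect_lt(ct$p_vs_half, 0.001)

  ct2 <- auc_ci_test(0.445, 0.041)
  expect_equal(ct2$p_vs_half, 0.184, tolerance = 0.01 / 0.184)

  expect_equal(auc_ci_test(0.5, 0.04)$p_vs_half, 1)
  expect_error(auc_ci_test(0.6, 0), class = "efindex_validation_error")
})

test_that("sens_spec recomputes the printed operating point", {
  ss <- sens_spec(paper_pregnancy_table())
  expect_equal(round(100 * ss$sens, 1), 71.8)
  expect_equal(round(100 * ss$spec, 1), 52.6)
  expect_equal(round(ss$youden_j, 3), 0.244)

  expect_equal(sens_spec(two_by_two(10, 0, 0, 10)),
               list(sens = 1, spec = 1, youden_j = 1))
  ss3 <- sens_spec(paper_pilot_table())
  expect_equal(round(ss3$sens, 3), 0.657)
  expect_equal(round(ss3$spec, 3), 0.5)
  expect_error(sens_spec(two_by_two(0, 5, 0, 5)),
               class = "efindex_validation_error")
})

test_that("youden_optimal picks the documented cut-off", {
  # reconstruct the published 2x2 as per-patient data: EFI >= 6 vs <= 5
  idx <- rep(c(6, 6, 5, 5), c(61, 54, 24, 60))
  out <- rep(c(TRUE, FALSE, TRUE, FALSE), c(61, 54, 24, 60))
  y <- youden_optimal(empirical_roc(idx, out))
  expect_equal(y$cutoff, 6)
  expect_equal(round(100 * y$sens, 1), 71.8)
  expect_equal(round(100 * y$spec, 1), 52.6)
  expect_equal(round(y$youden_j, 3), 0.244)

  # perfect separation: J = 1 at the separating threshold
  y2 <- youden_optimal(empirical_roc(c(8, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(y2$youden_j, 1)
  expect_equal(y2$cutoff, 8)

  # constant index: J = 0
  y3 <- youden_optimal(empirical_roc(rep(2, 8), rep(c(TRUE, FALSE), 4)))
  expect_equal(y3$youden_j, 0)
})

test_that("roc_analysis bundles everything consistently", {
  set.seed(14)
  idx <- c(rpois(40, 7), rpois(60, 5))
  out <- rep(c(TRUE, FALSE), c(40, 60))
  ra <- roc_analysis(idx, out)
  expect_s3_class(ra, "roc_analysis")
  expect_equal(ra$auc, auc_mann_whitney(idx, out))
  expect_equal(ra$se, auc_se_hanley_mcneil(ra$auc, 40, 60))
  expect_equal(ra$youden_j, ra$youden_sens + ra$youden_spec - 1)
  expect_true(ra$ci95[1] >= 0 && ra$ci95[2] <= 1)
  expect_output(print(ra), "AUC")
  ra_b <- roc_analysis(idx, out, se_method = "bootstrap", boot_reps = 200,
                       seed = 5)
  expect_equal(ra_b$auc, ra$auc)
  expect_false(identical(ra_b$se, ra$se))
})
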