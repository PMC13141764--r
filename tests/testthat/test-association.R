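test_that("contingency tables from an exact-margins cohort recover the printed cells", {
  cohort <- make_cohort(330, exact_margins = TRUE, seed = 3)
  vol <- build_contingency(cohort, "volume", cutpoint = 20.17)
  expect_equal(unclass(vol)[, ], matrix(c(22L, 139L, 12L, 157L), 2, 2,
    dimnames = list(c("<=20.17", ">20.17"), c("L", "C"))
  ))
  age <- build_contingency(cohort, "age", cutpoint = 38)
  expect_equal(as.integer(age), c(91L, 70L, 58L, 111L))
  # pathology variables drop their missing patients
  idh <- build_contingency(cohort, "idh1", level_order = c("mutant", "wild"))
  expect_equal(as.integer(idh), c(73L, 14L, 85L, 15L))
  expect_equal(attr(idh, "n_dropped"), 330L - 73L - 14L - 85L - 15L)
})

test_that("contingency construction guards its input", {
  cohort <- make_cohort(50, seed = 1)
  expect_error(build_contingency(cohort, "no_such"), class = "glioshape_unknown_variable")
  expect_error(build_contingency(cohort, "age"), class = "glioshape_missing_cutpoint")
  expect_error(
    build_contingency(dplyr::tibble(shape_label = character(), epilepsy = character()), "epilepsy"),
    class = "glioshape_degenerate_table"
  )
  # an absent level yields a zero row, not an error
  tab <- build_contingency(cohort, "epilepsy", level_order = c("yes", "no", "unknown"))
  expect_equal(unname(tab["unknown", ]), c(0L, 0L))
})

test_that("the cross-product odds ratio and Woolf interval are exact", {
  res <- odds_ratio(matrix(c(22, 139, 12, 157), 2, 2))
  expect_equal(res$or, (22 * 157) / (12 * 139))
  expect_equal(round(res$or, 2), 2.07)
  # independence
  expect_equal(odds_ratio(matrix(c(10, 20, 30, 60), 2, 2))$or, 1.0)
  # the OGS row: closed-form Woolf interval
  ogs <- odds_ratio(matrix(c(46, 74, 71, 65), 2, 2))
  se <- sqrt(1 / 46 + 1 / 71 + 1 / 74 + 1 / 65)
  expect_equal(ogs$ci_low, exp(log(ogs$or) - 1.96 * se))
  expect_equal(round(c(ogs$ci_low, ogs$ci_high), 2), c(0.35, 0.94))
})

test_that("odds-ratio symmetry properties hold on random tables", {
  set.seed(7)
  for (i in 1:25) {
    tab <- matrix(sample(1:200, 4, replace = TRUE), 2, 2)
    a <- odds_ratio(tab)$or
    expect_equal(a * odds_ratio(tab[2:1, ])$or, 1, tolerance = 1e-12)
    expect_equal(odds_ratio(tab, orientation = "row2-first")$or, 1 / a, tolerance = 1e-12)
    expect_equal(odds_ratio(tab[2:1, 2:1])$or, a, tolerance = 1e-12)
    ci <- odds_ratio(tab)
    expect_true(ci$ci_low <= ci$or && ci$or <= ci$ci_high)
  }
})

test_that("zero cells fall back to Haldane-Anscombe with a flag", {
  res <- odds_ratio(matrix(c(5, 10, 0, 20), 2, 2))
  expect_true(res$haldane)
  expect_equal(res$or, (5.5 * 20.5) / (0.5 * 10.5))
  expect_error(odds_ratio(matrix(c(0, 10, 0, 20), 2, 2)), class = "glioshape_degenerate_table")
  expect_error(odds_ratio(matrix(c(-1, 10, 5, 20), 2, 2)), class = "glioshape_bad_table")
})

test_that("the chi-square statistic matches the closed 2x2 form", {
  age <- matrix(c(91, 70, 58, 111), 2, 2)
  res <- chi_square(age)
  expect_equal(res$statistic, chi2_closed_form(age), tolerance = 1e-12)
  expect_equal(round(res$statistic, 2), 16.41)
  expect_lt(res$p, 0.001)
  flat <- chi_square(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_equal(chi_square(matrix(c(50, 0, 0, 50), 2, 2))$statistic, 100)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2, 2)), class = "glioshape_zero_expected")
})

test_that("associate_shape reproduces the printed odds ratios on the exact cohort", {
  cohort <- make_cohort(330, exact_margins = TRUE, seed = 5)
  assoc <- associate_shape(cohort)
  t1 <- table1_counts()
  merged <- dplyr::left_join(
    dplyr::mutate(assoc, variable = ifelse(variable == "ki67_index", "ki67", variable)),
    t1[, c("variable", "or_printed", "consistent")],
    by = "variable"
  )
  ok <- merged[merged$consistent, ]
  expect_gte(nrow(ok), 10)
  expect_equal(round(ok$or, 2), ok$or_printed)
})
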