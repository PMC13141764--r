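test_that("identical specs and seeds give bit-identical cohorts and shapes", {
  a <- make_cohort(120, seed = 7)
  b <- make_cohort(120, seed = 7)
  expect_identical(a, b)
  expect_false(identical(make_cohort(120, seed = 8)$pfs_months, a$pfs_months))
  s1 <- make_shape(shape_spec("sinusoid", size = 96, jitter = 0.1, seed = 3))
  s2 <- make_shape(shape_spec("sinusoid", size = 96, jitter = 0.1, seed = 3))
  expect_identical(s1$mask$pixels, s2$mask$pixels)
  expect_identical(s1$curve$x, s2$curve$x)
})

test_that("generated cell frequencies match the declared conditionals", {
  co <- make_cohort(330, seed = 19)
  # (age <= 38, L) has generator expectation 330 * (161/330) * (91/161) = 91
  n_cell <- sum(co$age <= 38 & co$shape_label == "L", na.rm = TRUE)
  bounds <- qbinom(c(0.005, 0.995), 330, (161 / 330) * (91 / 161))
  expect_gte(n_cell, bounds[1])
  expect_lte(n_cell, bounds[2])
  # goodness of fit at n = 10,000 on the age x shape cells
  big <- make_cohort(10000, seed = 20)
  obs <- c(
    sum(big$age <= 38 & big$shape_label == "L"),
    sum(big$age > 38 & big$shape_label == "L"),
    sum(big$age <= 38 & big$shape_label == "C"),
    sum(big$age > 38 & big$shape_label == "C")
  )
  p_exp <- c(161 / 330 * 91 / 161, 161 / 330 * 70 / 161, 169 / 330 * 58 / 169, 169 / 330 * 111 / 169)
  gof <- suppressWarnings(chisq.test(obs, p = p_exp))
  expect_gt(gof$p.value, 0.01)
})

test_that("exact margins reproduce every summary-table cell", {
  co <- make_cohort(330, exact_margins = TRUE, seed = 21)
  t1 <- table1_counts()
  checks <- list(
    c("age", "age", 38), c("volume", "volume", 20.17), c("ki67", "ki67_index", 0.10)
  )
  for (ch in checks) {
    row <- t1[t1$variable == ch[[1]], ]
    tab <- build_contingency(co, ch[[2]], cutpoint = as.numeric(ch[[3]]))
    expect_equal(as.integer(tab), c(row$l1, row$l2, row$c1, row$c2))
  }
  for (v in c("gender", "side", "histology", "idh1", "atrx", "mgmt", "tp53", "epilepsy")) {
    row <- t1[t1$variable == v, ]
    tab <- build_contingency(co, v, level_order = c(row$level1, row$level2))
    expect_equal(as.integer(tab), c(row$l1, row$l2, row$c1, row$c2))
  }
  expect_error(make_cohort(200, exact_margins = TRUE), class = "glioshape_bad_spec")
})

test_that("the censoring fraction is monotone in the censoring window", {
  fr <- vapply(c(30, 60, 120, 240), function(cm) {
    mean(make_cohort(800, censor_max = cm, seed = 22)$event == 0)
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("a null generating model carries no prognostic signal", {
  co <- make_cohort(400, model = "null", seed = 23)
  expect_true(all(attr(co, "true_lp") == 0))
  expect_identical(attr(co, "generator")$model, "null")
})

test_that("shape fixtures expose their analytic descriptor values", {
  st <- make_shape(shape_spec("straight-edge"))
  expect_equal(st$truth$tortuosity, 1)
  expect_equal(st$truth$total_curvature, 0)
  arc <- make_shape(shape_spec("arc", radius = 20, angle = 180, size = 128))
  expect_equal(arc$truth$tortuosity, pi / 2)
  expect_equal(arc$truth$total_curvature, pi)
  expect_equal(arc$truth$max_curvature, 0.05)
  koch <- make_shape(shape_spec("koch", iterations = 4))
  expect_equal(koch$truth$fd, log(4) / log(3))
  expect_equal(koch$truth$tortuosity, (4 / 3)^4)
  expect_error(
    make_shape(shape_spec("arc", radius = 200, size = 128)),
    class = "glioshape_shape_too_large"
  )
})

test_that("survival fixtures are the documented hand-checkable sets", {
  expect_equal(make_survival_fixture("km4")$pfs_months, 1:4)
  km6 <- make_survival_fixture("km6cens")
  expect_equal(sum(km6$event == 0), 2)
  lr <- make_survival_fixture("lr-balanced")
  expect_identical(
    lr$pfs_months[lr$group == "A"],
    lr$pfs_months[lr$group == "B"]
  )
  expect_error(make_survival_fixture("nope"), class = "glioshape_unknown_fixture")
})
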