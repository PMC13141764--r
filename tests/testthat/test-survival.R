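test_that("Kaplan-Meier matches hand-worked product-limit tables", {
  km4 <- km_estimate(make_survival_fixture("km4"))
  tab4 <- generics::tidy(km4)
  expect_equal(tab4$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(generics::glance(km4)$median, 2)

  km6 <- km_estimate(make_survival_fixture("km6cens"))
  tab6 <- generics::tidy(km6)
  # hand-worked: S(1)=5/6, S(3)=5/8, S(4)=5/12, S(6)=0
  expect_equal(tab6$surv[tab6$time %in% c(1, 3, 4, 6)], c(5 / 6, 5 / 8, 5 / 12, 0))
  expect_equal(generics::glance(km6)$median, 4)
})

test_that("with no events the survival curve stays at 1 and the median is undefined", {
  d <- dplyr::tibble(pfs_months = c(3, 7, 12), event = 0L)
  km <- km_estimate(d)
  expect_true(all(generics::tidy(km)$surv == 1))
  expect_true(is.na(generics::glance(km)$median))
  expect_error(km_estimate(dplyr::tibble(pfs_months = -1, event = 1L)),
    class = "glioshape_negative_time"
  )
})

test_that("KM equals 1 - ECDF when nothing is censored", {
  set.seed(2)
  t <- sort(sample(1:50, 30, replace = TRUE))
  km <- generics::tidy(km_estimate(dplyr::tibble(pfs_months = t, event = 1L)))
  for (i in seq_len(nrow(km))) {
    expect_equal(km$surv[i], mean(t > km$time[i]))
  }
})

test_that("identical groups give a zero log-rank statistic", {
  lr <- logrank_test(make_survival_fixture("lr-balanced"), "group")
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
})

test_that("the Mantel-Cox statistic equals independent oracles", {
  # brute per-event-time accumulation oracle on small fixtures
  set.seed(4)
  for (i in 1:5) {
    n <- 60
    d <- dplyr::tibble(
      pfs_months = sample(1:20, n, replace = TRUE),
      event = rbinom(n, 1, 0.7),
      group = sample(c("A", "B"), n, replace = TRUE)
    )
    lr <- logrank_test(d, "group")
    expect_equal(lr$statistic, logrank_oracle_2g(d$pfs_months, d$event, d$group),
      tolerance = 1e-10
    )
    # cross-check against survdiff
    sd <- survival::survdiff(survival::Surv(pfs_months, event) ~ group, data = d)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
  }
})

test_that("the log-rank test is invariant under group relabeling", {
  co <- make_cohort(200, seed = 6)
  co$group <- co$shape_label
  a <- logrank_test(co, "group")$statistic
  co$group <- ifelse(co$group == "L", "zz", "aa")
  expect_equal(logrank_test(co, "group")$statistic, a, tolerance = 1e-10)
})

test_that("Breslow-Wilcoxon weighting differs and detects early separation", {
  co <- make_cohort(400, model = "riskL", seed = 12)
  co$group <- co$shape_label
  mc <- logrank_test(co, "group", "mantel-cox")
  bw <- logrank_test(co, "group", "breslow-wilcoxon")
  expect_false(isTRUE(all.equal(mc$statistic, bw$statistic)))
  expect_true(all(bw$detail$weight == bw$detail$n_risk))
  expect_true(all(mc$detail$weight == 1))
})

test_that("log-rank errors are specific", {
  one <- dplyr::tibble(pfs_months = 1:4, event = 1L, group = "A")
  expect_error(logrank_test(one, "group"), class = "glioshape_bad_groups")
  nocens <- dplyr::tibble(pfs_months = 1:4, event = 0L, group = rep(c("A", "B"), 2))
  expect_error(logrank_test(nocens, "group"), class = "glioshape_no_events")
})

test_that("Harrell's C is exact against pair enumeration", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(20:50, 1)
    d <- dplyr::tibble(
      pfs_months = sample(1:30, n, replace = TRUE),
      event = rbinom(n, 1, 0.6)
    )
    sc <- sample(seq_len(10), n, replace = TRUE) # force some score ties
    mine <- harrell_c(d, sc)
    expect_equal(mine$c_index, harrell_oracle(d$pfs_months, d$event, sc))
  }
})

test_that("perfect and reversed rankings bracket the concordance scale", {
  set.seed(14)
  t <- runif(40, 1, 100)
  d <- dplyr::tibble(pfs_months = t, event = 1L)
  expect_equal(harrell_c(d, -t)$c_index, 1.0)
  expect_equal(harrell_c(d, t)$c_index, 0.0)
  s <- rnorm(40)
  expect_equal(harrell_c(d, s)$c_index + harrell_c(d, -s)$c_index, 1.0)
  none <- dplyr::tibble(pfs_months = 1:5, event = 0L)
  expect_true(is.na(harrell_c(none, rnorm(5))$c_index))
})

test_that("random scores concentrate near C = 0.5", {
  set.seed(15)
  d <- dplyr::tibble(pfs_months = rexp(1000, 0.05), event = rbinom(1000, 1, 0.7))
  c0 <- harrell_c(d, rnorm(1000))$c_index
  expect_gt(c0, 0.46)
  expect_lt(c0, 0.54)
})
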