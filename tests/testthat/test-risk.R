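# One patient with every adverse status and one with none, for both models.
all_adverse <- dplyr::tibble(
  ki67_index = 0.2, epilepsy = "yes", tp53 = "mutant",
  codel_1p19q = "co-deleted", volume = 30, idh1 = "mutant", age = 50,
  tortuosity = 2
)
none_adverse <- dplyr::tibble(
  ki67_index = 0.05, epilepsy = "no", tp53 = "wild",
  codel_1p19q = "intact", volume = 10, idh1 = "wild", age = 30,
  tortuosity = 1
)

test_that("the published coefficient sums are reproduced by the score", {
  both <- dplyr::bind_rows(all_adverse, none_adverse)
  sL <- risk_score(both, risk_model_L())$risk_score
  expect_equal(sL, c(0.78 + 0.54 - 0.77 - 0.90 + 0.55, 0))
  expect_equal(sL[1], 0.20)
  # tortuosity codes against the cohort median, so the two-row cohort splits 1/0
  sC <- risk_score(both, risk_model_C())$risk_score
  expect_equal(sC[1], 0.04 - 0.86 + 1.31 + 1.39 + 1.19 - 1.70)
  expect_equal(sC[1], 1.37)
  expect_equal(sC[2], 0)
})

test_that("the score is additive in each coded covariate", {
  model <- risk_model_L()
  co <- make_cohort(50, seed = 17)
  base <- risk_score(co, model)$risk_score
  coded <- code_covariates(co, model)
  for (v in names(model$coefficients)) {
    expect_equal(base - coded[[v]] * model$coefficients[[v]],
      drop(as.matrix(coded)[, setdiff(names(model$coefficients), v)] %*%
        model$coefficients[setdiff(names(model$coefficients), v)]),
      ignore_attr = TRUE
    )
  }
})

test_that("model construction and coding guard their domain", {
  expect_error(risk_model("m", c(0.5, 0.2), list()), class = "glioshape_bad_model")
  expect_error(
    risk_model("m", c(a = 0.5), list(b = "b > 1")),
    class = "glioshape_bad_model"
  )
  expect_error(
    code_covariates(dplyr::tibble(x = 1), risk_model_L()),
    class = "glioshape_missing_covariate"
  )
  na_cohort <- all_adverse
  na_cohort$ki67_index <- NA_real_
  expect_error(code_covariates(na_cohort, risk_model_L()),
    class = "glioshape_missing_covariate"
  )
})

test_that("the nomogram-100 points scale anchors the largest coefficient", {
  pts <- to_points(risk_model_L())
  expect_equal(pts$points[pts$term == "codel_1p19q"], -100)
  expect_equal(pts$points[pts$term == "ki67"], round(100 * 0.78 / 0.90))
  # single covariate -> +/-100
  one <- risk_model("one", c(x = -0.3), list(x = "as.integer(x > 0)"))
  expect_equal(to_points(one)$points, -100)
  # doubling every coefficient changes nothing
  dbl <- risk_model_L()
  dbl$coefficients <- dbl$coefficients * 2
  expect_equal(to_points(dbl)$points, pts$points)
  expect_error(to_points(risk_model("z", c(x = 0), list(x = "x"))),
    class = "glioshape_bad_model"
  )
})

test_that("stored model metadata carries the published thresholds and metrics", {
  mL <- risk_model_L()
  mC <- risk_model_C()
  expect_equal(mL$threshold, 23)
  expect_equal(mC$threshold, 41)
  expect_equal(mL$reference_metrics$bootstrap_c, 0.67)
  expect_equal(mL$reference_metrics$cv_mean_c, 0.63)
  expect_equal(mC$reference_metrics$bootstrap_c, 0.84)
  expect_equal(mC$reference_metrics$cv_mean_c, 0.81)
  expect_equal(mC$reference_metrics$ici, 0.061)
  expect_equal(mC$reference_metrics$e50, 0.021)
})

test_that("threshold search separates clearly split risk groups", {
  set.seed(23)
  n <- 100
  sc <- c(runif(n / 2, 0, 1), runif(n / 2, 3, 4))
  # perfect separation: every high-score patient progresses first
  t <- c(seq(100, 150, length.out = n / 2), seq(1, 50, length.out = n / 2))
  d <- dplyr::tibble(pfs_months = t, event = 1L)
  res <- threshold_search(d, sc)
  # the selected cut sits between the two score clusters
  expect_gte(res$threshold, max(sc[sc < 2]) - 1e-9)
  expect_lt(res$threshold, 3)
  expect_lt(res$p, 1e-6)
})

test_that("threshold search equals a brute-force scan", {
  set.seed(24)
  n <- 60
  sc <- sample(1:8, n, replace = TRUE)
  d <- dplyr::tibble(
    pfs_months = rexp(n, 0.02 * exp(0.3 * sc)),
    event = rbinom(n, 1, 0.8)
  )
  res <- threshold_search(d, sc, min_group_fraction = 0.10)
  # independent exhaustive scan
  best_stat <- -Inf
  best_cut <- NA
  for (cut in sort(unique(sc))[-length(unique(sc))]) {
    lo <- sc <= cut
    if (sum(lo) < 6 || sum(!lo) < 6) next
    g <- ifelse(lo, "low", "high")
    stat <- logrank_oracle_2g(d$pfs_months, d$event, g)
    if (stat > best_stat + 1e-12) {
      best_stat <- stat
      best_cut <- cut
    }
  }
  expect_equal(res$threshold, best_cut)
  expect_equal(res$statistic, best_stat, tolerance = 1e-10)
})

test_that("threshold search refuses inadmissible inputs", {
  d <- dplyr::tibble(pfs_months = rexp(20, 0.1), event = 1L)
  expect_error(threshold_search(d, rep(1, 20)), class = "glioshape_no_admissible_cut")
  expect_error(threshold_search(d, c(rep(1, 19), 2), min_group_fraction = 0.4),
    class = "glioshape_no_admissible_cut"
  )
})
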