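#' Simulate a patient cohort with a prescribed covariate and survival
#' structure
#'
#' Generates a cohort whose boundary-shape label and clinicopathological
#' covariates follow the conditional frequencies of the 330-patient summary
#' table ([table1_counts()]), and whose progression-free survival follows a
#' proportional-hazards model with an exponential baseline:
#' T ~ Exp(rate = `baseline_hazard` * exp(linear predictor)), right-censored
#' at an independent Uniform(0, `censor_max`) time. The linear predictor
#' uses the published risk-model coefficients (the generating truth for
#' parameter-recovery tests), with covariates coded by the model's own
#' coding map.
#'
#' Covariates are drawn conditionally independent given the shape label;
#' the real cohort's joint dependence structure is unknown, so this is a
#' fixture property, not a claim about the real data. Numeric companions
#' (age in years, volume in cm^3, Ki-67 fraction, tortuosity) are drawn
#' uniformly within their dichotomization bin so cut-point operations
#' reproduce the binary draws exactly.
#'
#' With `exact_margins = TRUE` (requires the default `n = 330` split), each
#' variable's per-shape level counts — including the missing-value counts of
#' the pathology variables — are reproduced exactly rather than in
#' expectation, by permuting assignments within each shape group; every
#' printed 2 x 2 table is then recovered cell-for-cell.
#'
#' @param n Number of patients (default 330).
#' @param model Generating risk model: `"riskL"` (default), `"riskC"`, or
#'   `"null"` (zero coefficients, no prognostic signal).
#' @param baseline_hazard Exponential baseline rate per month (default
#'   0.01).
#' @param censor_max Upper end of the uniform censoring window in months
#'   (default 120; larger values censor less).
#' @param p_curved Marginal probability of a curved boundary (default
#'   169/330).
#' @param exact_margins Reproduce the summary-table margins exactly
#'   (default `FALSE`).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @returns A cohort tibble with columns `id`, `age`, `gender`, `side`,
#'   `volume`, `histology`, `who_grade`, `idh1`, `codel_1p19q`, `atrx`,
#'   `mgmt`, `tp53`, `ki67_index`, `epilepsy`, `tortuosity`, `shape_label`,
#'   `pfs_months`, `event`. The generating linear predictor is attached as
#'   attribute `true_lp` and the generator settings as attribute
#'   `generator`.
#' @examples
#' cohort <- make_cohort(n = 330, seed = 7)
#' table(cohort$shape_label)
#' @export
make_cohort <- function(n = 330, model = c("riskL", "riskC", "null"),
                        baseline_hazard = 0.01, censor_max = 120,
                        p_curved = 169 / 330, exact_margins = FALSE,
                        seed = 1L) {
  model <- match.arg(model)
  if (n < 1) gs_abort("bad-spec", "`n` must be >= 1.")
  if (baseline_hazard <= 0) gs_abort("bad-spec", "`baseline_hazard` must be > 0.")
  if (p_curved < 0 || p_curved > 1) gs_abort("bad-spec", "`p_curved` must be a probability.")
  t1 <- table1_counts()
  set.seed(seed)

  if (exact_margins) {
    if (n != 330) gs_abort("bad-spec", "`exact_margins` requires n = 330.")
    n_l <- 161L
    shape <- sample(rep(c("L", "C"), c(n_l, n - n_l)))
  } else {
    shape <- ifelse(runif(n) < p_curved, "C", "L")
  }

  draw_var <- function(variable) {
    row <- t1[t1$variable == variable, ]
    out <- rep(NA_character_, n)
    for (sh in c("L", "C")) {
      idx <- which(shape == sh)
      k1 <- if (sh == "L") row$l1 else row$c1
      k2 <- if (sh == "L") row$l2 else row$c2
      if (exact_margins) {
        n_sh <- length(idx)
        pool <- c(
          rep(row$level1, k1), rep(row$level2, k2),
          rep(NA_character_, n_sh - k1 - k2)
        )
        out[idx] <- sample(pool)
      } else {
        out[idx] <- sample(c(row$level1, row$level2), length(idx),
          replace = TRUE, prob = c(k1, k2) / (k1 + k2)
        )
      }
    }
    out
  }

  age_bin <- draw_var("age")
  vol_bin <- draw_var("volume")
  ki67_bin <- draw_var("ki67")
  cohort <- tibble(
    id = sprintf("P%04d", seq_len(n)),
    age = dplyr::case_when(
      age_bin == "<=38" ~ round(runif(n, 19, 38)),
      age_bin == ">38" ~ round(runif(n, 39, 72)),
      .default = NA_real_
    ),
    gender = draw_var("gender"),
    side = draw_var("side"),
    volume = dplyr::case_when(
      vol_bin == "<=20.17" ~ round(runif(n, 1.5, 20.17), 2),
      vol_bin == ">20.17" ~ round(runif(n, 20.3, 120), 2),
      .default = NA_real_
    ),
    histology = draw_var("histology"),
    who_grade = draw_var("who_grade"),
    idh1 = draw_var("idh1"),
    codel_1p19q = draw_var("codel_1p19q"),
    atrx = draw_var("atrx"),
    mgmt = draw_var("mgmt"),
    tp53 = draw_var("tp53"),
    ki67_index = dplyr::case_when(
      ki67_bin == "<=10%" ~ round(runif(n, 0.005, 0.10), 3),
      ki67_bin == ">10%" ~ round(runif(n, 0.105, 0.60), 3),
      .default = NA_real_
    ),
    epilepsy = draw_var("epilepsy"),
    # linear boundaries hug tortuosity 1; curved ones spread upward
    tortuosity = round(ifelse(shape == "C",
      1.05 + rexp(n, 1 / 0.25),
      1 + abs(rnorm(n, 0, 0.03))
    ), 4),
    shape_label = shape
  )

  gen_model <- switch(model,
    riskL = risk_model_L(),
    riskC = risk_model_C(),
    null = {
      m <- risk_model_L()
      m$coefficients[] <- 0
      m$name <- "null"
      m
    }
  )
  lp <- risk_lp_with_na(cohort, gen_model)
  t_event <- rexp(n, rate = baseline_hazard * exp(lp))
  t_cens <- runif(n, 0, censor_max)
  cohort$pfs_months <- round(pmin(t_event, t_cens), 2)
  cohort$event <- as.integer(t_event <= t_cens)
  structure(cohort,
    true_lp = lp,
    generator = list(
      model = model, coefficients = gen_model$coefficients,
      baseline_hazard = baseline_hazard, censor_max = censor_max,
      p_curved = p_curved, exact_margins = exact_margins, seed = seed
    )
  )
}

# Linear predictor tolerating missing covariate values (missing -> reference
# level 0), for generation from exact-margin cohorts with missingness.
risk_lp_with_na <- function(cohort, model) {
  vals <- vapply(names(model$coefficients), function(v) {
    expr <- rlang::parse_expr(model$coding[[v]])
    x <- as.integer(rlang::eval_tidy(expr, data = cohort))
    x[is.na(x)] <- 0L
    x
  }, integer(nrow(cohort)))
  drop(vals %*% model$coefficients)
}

#' Small hand-checkable survival fixtures
#'
#' Named record sets whose Kaplan-Meier and log-rank results can be worked
#' by hand:
#'
#' * `"km4"` — 4 records, events at t = 1, 2, 3, 4 (survival halves at 2).
#' * `"km6cens"` — 6 records with 2 censored; product-limit table:
#'   S(1) = 5/6, S(3) = 5/8, S(4) = 5/12, S(6) = 0.
#' * `"lr-balanced"` — two identical groups (log-rank statistic 0).
#'
#' @param name Fixture name.
#' @returns Tibble with `id`, `pfs_months`, `event` (and `group` for
#'   log-rank fixtures).
#' @export
make_survival_fixture <- function(name) {
  switch(name,
    km4 = tibble(
      id = paste0("F", 1:4), pfs_months = c(1, 2, 3, 4), event = 1L
    ),
    km6cens = tibble(
      id = paste0("F", 1:6),
      pfs_months = c(1, 2, 3, 4, 5, 6),
      event = c(1L, 0L, 1L, 1L, 0L, 1L)
    ),
    `lr-balanced` = tibble(
      id = paste0("F", 1:8),
      pfs_months = rep(c(2, 4, 6, 8), 2),
      event = rep(c(1L, 1L, 0L, 1L), 2),
      group = rep(c("A", "B"), each = 4)
    ),
    gs_abort("unknown-fixture", paste0("Unknown fixture `", name, "`."))
  )
}
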