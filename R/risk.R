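#' Prognostic risk-score models
#'
#' A risk model is a named linear score over binary-coded ("status")
#' covariates: score = sum_j beta_j x_j with x_j in \{0, 1\}. The coding map
#' is an explicit, overridable set of R expressions evaluated on the cohort
#' (adverse level = 1), so alternative reference codings can be tested. A
#' model may carry a points-scale dichotomization threshold and published
#' validation metrics as metadata; these are recorded values, not asserted
#' numbers.
#'
#' `risk_model_L()` and `risk_model_C()` build the two published
#' progression-risk models for the linear- and curved-boundary subgroups:
#'
#' \deqn{Risk_L = 0.78 Ki67 + 0.54 epilepsy - 0.77 TP53 - 0.90 1p/19q + 0.55 volume}
#' \deqn{Risk_C = 0.04 Ki67 - 0.86 IDH1 + 1.31 age + 1.39 volume + 1.19 tortuosity - 1.70 1p/19q}
#'
#' with adverse coding Ki-67 > 10%, epilepsy present, TP53 mutant, 1p/19q
#' co-deleted, volume > 20.17 cm^3, IDH1 mutant, age > 38 years, and
#' tortuosity above the cohort median.
#'
#' @param name Model name.
#' @param coefficients Named numeric vector of weights.
#' @param coding Named list of strings, one per coefficient: an R expression
#'   on cohort columns evaluating to the 0/1 status.
#' @param threshold Points-scale threshold separating low and high risk
#'   (metadata).
#' @param reference_metrics Named list of published validation metrics
#'   (metadata).
#' @returns A `risk_model` object.
#' @export
risk_model <- function(name, coefficients, coding, threshold = NULL,
                       reference_metrics = NULL) {
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    gs_abort("bad-model", "`coefficients` must be a named vector.")
  }
  if (any(!is.finite(coefficients))) gs_abort("bad-model", "Coefficients must be finite.")
  missing_coding <- setdiff(names(coefficients), names(coding))
  if (length(missing_coding) > 0) {
    gs_abort("bad-model", paste0(
      "Coding map misses covariate(s): ", paste(missing_coding, collapse = ", "), "."
    ))
  }
  structure(
    list(
      name = name, coefficients = coefficients, coding = coding,
      threshold = threshold, reference_metrics = reference_metrics
    ),
    class = "risk_model"
  )
}

#' @rdname risk_model
#' @export
risk_model_L <- function() {
  risk_model(
    name = "Risk_L",
    coefficients = c(
      ki67 = 0.78, epilepsy = 0.54, tp53 = -0.77,
      codel_1p19q = -0.90, volume = 0.55
    ),
    coding = list(
      ki67 = "as.integer(ki67_index > 0.10)",
      epilepsy = "as.integer(epilepsy == 'yes')",
      tp53 = "as.integer(tp53 == 'mutant')",
      codel_1p19q = "as.integer(codel_1p19q == 'co-deleted')",
      volume = "as.integer(volume > 20.17)"
    ),
    threshold = 23,
    reference_metrics = list(
      bootstrap_c = 0.67, cv_mean_c = 0.63, ici = 0.008, e50 = 0.006,
      logrank_p = 0.003
    )
  )
}

#' @rdname risk_model
#' @export
risk_model_C <- function() {
  risk_model(
    name = "Risk_C",
    coefficients = c(
      ki67 = 0.04, idh1 = -0.86, age = 1.31, volume = 1.39,
      tortuosity = 1.19, codel_1p19q = -1.70
    ),
    coding = list(
      ki67 = "as.integer(ki67_index > 0.10)",
      idh1 = "as.integer(idh1 == 'mutant')",
      age = "as.integer(age > 38)",
      volume = "as.integer(volume > 20.17)",
      tortuosity = "as.integer(tortuosity > stats::median(tortuosity, na.rm = TRUE))",
      codel_1p19q = "as.integer(codel_1p19q == 'co-deleted')"
    ),
    threshold = 41,
    reference_metrics = list(
      bootstrap_c = 0.84, cv_mean_c = 0.81, ici = 0.061, e50 = 0.021,
      logrank_p = 0.001
    )
  )
}

#' @export
print.risk_model <- function(x, ...) {
  terms <- sprintf("(%.2f)*%s", x$coefficients, names(x$coefficients))
  cat(sprintf("<risk_model %s>\n  score = %s\n", x$name, paste(terms, collapse = " + ")))
  if (!is.null(x$threshold)) cat("  points threshold:", x$threshold, "\n")
  invisible(x)
}

#' Binary status coding of a cohort under a risk model
#'
#' Evaluates the model's coding map on the cohort, producing the 0/1
#' "status" design matrix of the score.
#'
#' @param cohort Cohort data frame.
#' @param model A [risk_model()].
#' @returns Tibble of 0/1 integer columns, one per model covariate.
#' @export
code_covariates <- function(cohort, model) {
  stopifnot(inherits(model, "risk_model"))
  cols <- lapply(names(model$coefficients), function(v) {
    expr <- rlang::parse_expr(model$coding[[v]])
    val <- tryCatch(rlang::eval_tidy(expr, data = cohort), error = function(e) {
      gs_abort("missing-covariate", paste0(
        "Cannot code `", v, "`: ", conditionMessage(e)
      ))
    })
    if (any(is.na(val))) {
      gs_abort("missing-covariate", paste0("Missing values when coding `", v, "`."))
    }
    as.integer(val)
  })
  tibble::as_tibble(setNames(cols, names(model$coefficients)))
}

#' Linear risk score of each patient
#'
#' Adds the model's linear predictor (dot product of the coded statuses
#' with the coefficients) as a `risk_score` column.
#'
#' @param cohort Cohort data frame.
#' @param model A [risk_model()].
#' @returns `cohort` with an appended `risk_score` column.
#' @examples
#' cohort <- tibble::tibble(
#'   ki67_index = c(0.05, 0.2), epilepsy = c("no", "yes"),
#'   tp53 = c("wild", "mutant"), codel_1p19q = c("intact", "co-deleted"),
#'   volume = c(10, 30)
#' )
#' risk_score(cohort, risk_model_L())$risk_score # 0 and 0.20
#' @export
risk_score <- function(cohort, model) {
  X <- as.matrix(code_covariates(cohort, model))
  dplyr::mutate(tibble::as_tibble(cohort), risk_score = drop(X %*% model$coefficients))
}

#' Nomogram-style points scale of a risk model
#'
#' Rescales coefficients to integer points: under the default
#' `"nomogram-100"` scheme the covariate with the largest |beta| maps to
#' +/-100 points and every other covariate to
#' `round(100 |beta_j| / max |beta|)` carrying beta's sign. A patient's
#' total points is the sum over their active (status = 1) covariates.
#' Doubling all coefficients leaves the points unchanged.
#'
#' @param model A [risk_model()].
#' @param scale `"nomogram-100"` or `"custom"`.
#' @param factor Points per unit coefficient for `scale = "custom"`.
#' @returns Tibble `term` / `coefficient` / `points`, with the scheme as
#'   attribute `scheme`.
#' @export
to_points <- function(model, scale = c("nomogram-100", "custom"), factor = NULL) {
  scale <- match.arg(scale)
  beta <- model$coefficients
  if (all(beta == 0)) gs_abort("bad-model", "All-zero coefficients have no points scale.")
  pts <- switch(scale,
    "nomogram-100" = round(100 * abs(beta) / max(abs(beta))) * sign(beta),
    "custom" = {
      if (is.null(factor)) gs_abort("bad-scale", "`factor` required for custom scale.")
      round(beta * factor)
    }
  )
  structure(
    tibble(term = names(beta), coefficient = unname(beta), points = unname(pts)),
    scheme = scale
  )
}

#' Points score of each patient
#'
#' @param cohort Cohort data frame.
#' @param model A [risk_model()].
#' @inheritParams to_points
#' @returns `cohort` with an appended `points` column.
#' @export
risk_points <- function(cohort, model, scale = "nomogram-100", factor = NULL) {
  pts <- to_points(model, scale, factor)
  X <- as.matrix(code_covariates(cohort, model))
  dplyr::mutate(tibble::as_tibble(cohort), points = drop(X %*% pts$points))
}

#' Best survival-separating threshold of a score
#'
#' Scans the unique score values as candidate cut-points (low group: score
#' <= cut) and returns the cut maximizing the Mantel-Cox log-rank statistic,
#' subject to both sides holding at least `min_group_fraction` of the
#' patients. Ties prefer the lower threshold. The selected statistic is
#' optimistically biased (it is a maximum over cuts); see the validation
#' tools for honest assessment.
#'
#' @param data Data frame with time and event columns.
#' @param scores Numeric score per row of `data`.
#' @param min_group_fraction Minimum fraction of patients on each side
#'   (default 0.10).
#' @param time_col,event_col Column names as in [km_estimate()].
#' @returns List with `threshold`, `statistic`, `p`, `n_low`, `n_high`.
#' @export
threshold_search <- function(data, scores, min_group_fraction = 0.10,
                             time_col = "pfs_months", event_col = "event") {
  stopifnot(length(scores) == nrow(data))
  cuts <- sort(unique(scores))
  if (length(cuts) < 2) gs_abort("no-admissible-cut", "Need at least two distinct scores.")
  n <- length(scores)
  min_n <- ceiling(min_group_fraction * n)
  best <- NULL
  for (cut in cuts[-length(cuts)]) {
    lo <- scores <= cut
    if (sum(lo) < min_n || sum(!lo) < min_n) next
    dd <- data.frame(
      t = data[[time_col]], e = data[[event_col]],
      group = ifelse(lo, "low", "high")
    )
    lr <- tryCatch(
      logrank_test(dd, "group", "mantel-cox", time_col = "t", event_col = "e"),
      error = function(e) NULL
    )
    if (is.null(lr)) next
    if (is.null(best) || lr$statistic > best$statistic) {
      best <- list(
        threshold = cut, statistic = lr$statistic, p = lr$p,
        n_low = sum(lo), n_high = sum(!lo)
      )
    }
  }
  if (is.null(best)) gs_abort("no-admissible-cut", "No cut satisfies the group-size constraint.")
  best
}
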