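#' Cox proportional-hazards fit
#'
#' Thin wrapper around [survival::coxph()] (Efron tie handling, convergence
#' at gradient < 1e-9 or 100 iterations) that standardizes the interface
#' used throughout the modeling pipeline and flags monotone-likelihood
#' (perfect separation) fits, whose coefficients diverge.
#'
#' @param data Data frame with time, event and covariate columns.
#' @param covariates Character vector of covariate column names (numeric or
#'   0/1 coded). Empty vector fits the null model.
#' @param time_col,event_col Column names as in [km_estimate()].
#' @returns A `cox_fit` object. [generics::tidy()] returns
#'   `term`/`estimate`/`std.error`/`statistic`/`p.value`,
#'   [generics::glance()] the model-level summary.
#' @export
cox_fit <- function(data, covariates, time_col = "pfs_months", event_col = "event") {
  time <- data[[time_col]]
  event <- as.integer(data[[event_col]])
  if (sum(event) < 1) gs_abort("no-events", "Need at least one event.")
  df <- data.frame(.time = time, .event = event)
  for (v in covariates) df[[v]] <- as.numeric(data[[v]])
  rhs <- if (length(covariates) == 0) "1" else paste(sprintf("`%s`", covariates), collapse = " + ")
  fml <- stats::as.formula(paste0("survival::Surv(.time, .event) ~ ", rhs))
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron",
      control = survival::coxph.control(eps = 1e-9, iter.max = 100)
    ),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(
    list(
      model = fit, covariates = covariates, separation = separation,
      n = nrow(df), n_event = sum(event),
      time_col = time_col, event_col = event_col
    ),
    class = "cox_fit"
  )
}

#' @export
tidy.cox_fit <- function(x, ...) {
  if (length(x$covariates) == 0) {
    return(tibble(
      term = character(), estimate = numeric(), std.error = numeric(),
      statistic = numeric(), p.value = numeric()
    ))
  }
  sm <- summary(x$model)$coefficients
  tibble(
    term = x$covariates,
    estimate = unname(sm[, "coef"]),
    std.error = unname(sm[, "se(coef)"]),
    statistic = unname(sm[, "z"]),
    p.value = unname(sm[, "Pr(>|z|)"])
  )
}

#' @export
glance.cox_fit <- function(x, ...) {
  ll <- x$model$loglik
  tibble(
    n = x$n, n_event = x$n_event,
    loglik = ll[length(ll)], loglik_null = ll[1],
    concordance = unname(x$model$concordance["concordance"]),
    separation = x$separation
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "<cox_fit: %d covariates, %d records, %d events%s>\n",
    length(x$covariates), x$n, x$n_event,
    if (x$separation) ", separation flagged" else ""
  ))
  if (length(x$covariates)) print(as.data.frame(tidy(x)), row.names = FALSE)
  invisible(x)
}

#' Linear predictor of a Cox fit on (new) data
#'
#' @param x A `cox_fit`.
#' @param newdata Data frame with the covariate columns.
#' @returns Numeric vector of uncentered linear predictors (x' beta).
#' @export
cox_lp <- function(x, newdata) {
  if (length(x$covariates) == 0) {
    return(rep(0, nrow(newdata)))
  }
  beta <- tidy(x)$estimate
  X <- as.matrix(as.data.frame(lapply(newdata[x$covariates], as.numeric)))
  drop(X %*% beta)
}

#' Stepwise Cox model selection by Wald tests
#'
#' Forward selection with backward pruning: at each forward step the
#' candidate with the smallest Wald p-value is entered if p < `p_enter`
#' (ties broken by declared candidate order); after every entry, included
#' covariates whose Wald p exceeds `p_remove` are removed, worst first.
#' The full selection path is logged. Candidates are expected to be
#' pre-screened for collinearity (see [vif_screen()]).
#'
#' @param data Data frame with time, event and candidate columns.
#' @param candidates Character vector of candidate covariates, in declared
#'   order.
#' @param p_enter,p_remove Entry and removal thresholds (defaults 0.05 and
#'   0.10; `p_enter <= p_remove` required).
#' @param time_col,event_col Column names as in [km_estimate()].
#' @returns A `stepwise_fit`: list with `fit` (final [cox_fit()]),
#'   `selected`, `path` (tibble step/action/term/p), `null_model` flag.
#' @export
stepwise_wald <- function(data, candidates, p_enter = 0.05, p_remove = 0.10,
                          time_col = "pfs_months", event_col = "event") {
  if (p_enter > p_remove) gs_abort("bad-thresholds", "`p_enter` must be <= `p_remove`.")
  selected <- character()
  path <- list()
  step <- 0L
  max_steps <- 2L * length(candidates) + 5L # guard against enter/remove cycling
  repeat {
    if (step >= max_steps) break
    changed <- FALSE
    # forward: best Wald p among candidates not yet in the model
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0) {
      entry_p <- vapply(pool, function(v) {
        fit <- cox_fit(data, c(selected, v), time_col, event_col)
        td <- tidy(fit)
        td$p.value[td$term == v]
      }, numeric(1))
      best <- which(entry_p == min(entry_p))[1] # ties: declared order
      if (entry_p[best] < p_enter) {
        selected <- c(selected, pool[best])
        step <- step + 1L
        path[[length(path) + 1]] <- tibble(
          step = step, action = "enter", term = pool[best], p = entry_p[best]
        )
        changed <- TRUE
      }
    }
    # backward: prune anything whose Wald p rose above p_remove
    repeat {
      if (length(selected) == 0) break
      td <- tidy(cox_fit(data, selected, time_col, event_col))
      worst <- which.max(td$p.value)
      if (td$p.value[worst] > p_remove) {
        step <- step + 1L
        path[[length(path) + 1]] <- tibble(
          step = step, action = "remove", term = td$term[worst], p = td$p.value[worst]
        )
        selected <- setdiff(selected, td$term[worst])
      } else {
        break
      }
    }
    if (!changed) break
  }
  structure(
    list(
      fit = cox_fit(data, selected, time_col, event_col),
      selected = selected,
      path = if (length(path)) dplyr::bind_rows(path) else
        tibble(step = integer(), action = character(), term = character(), p = numeric()),
      null_model = length(selected) == 0
    ),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf(
    "<stepwise_fit: %s>\n",
    if (x$null_model) "null model (no candidate passed entry)" else
      paste("selected:", paste(x$selected, collapse = ", "))
  ))
  invisible(x)
}

#' @export
tidy.stepwise_fit <- function(x, ...) tidy(x$fit)

#' @export
glance.stepwise_fit <- function(x, ...) {
  dplyr::mutate(glance(x$fit), n_selected = length(x$selected))
}
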