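#' Kaplan-Meier estimate of progression-free survival
#'
#' Product-limit estimator with Greenwood standard errors, wrapped from
#' [survival::survfit()]. The median is the earliest observed time at which
#' the survival function drops to 0.5 or below; it is `NA` when that level
#' is never reached.
#'
#' @param data Data frame with follow-up time and event indicator columns.
#' @param time_col,event_col Column names (defaults `"pfs_months"`,
#'   `"event"`; event 1 = recurrence/progression, 0 = censored).
#' @returns A `km_fit` object; [generics::tidy()] gives the step table
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `surv`, `std_err`, `lower`,
#'   `upper`), [generics::glance()] the summary row with the median.
#' @export
km_estimate <- function(data, time_col = "pfs_months", event_col = "event") {
  time <- data[[time_col]]
  event <- as.integer(data[[event_col]])
  if (length(time) < 1) gs_abort("no-records", "Need at least one record.")
  if (any(time < 0)) gs_abort("negative-time", "Follow-up times must be >= 0.")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(survfit = fit, n = length(time), n_event = sum(event)),
    class = "km_fit"
  )
}

#' @export
tidy.km_fit <- function(x, ...) {
  f <- x$survfit
  tibble(
    time = f$time, n_risk = f$n.risk, n_event = f$n.event,
    n_censor = f$n.censor, surv = f$surv,
    std_err = f$surv * f$std.err, # Greenwood SE on the survival scale
    lower = f$lower, upper = f$upper
  )
}

#' @export
glance.km_fit <- function(x, ...) {
  tab <- tidy(x)
  med <- tab$time[tab$surv <= 0.5][1]
  tibble(
    n = x$n, n_event = x$n_event,
    median = if (length(med) == 0) NA_real_ else med
  )
}

#' @export
print.km_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<km_fit: %d records, %d events, median %s>\n", g$n, g$n_event,
    if (is.na(g$median)) "not reached" else sprintf("%.3g months", g$median)
  ))
  invisible(x)
}

#' Weighted log-rank test between survival groups
#'
#' K-sample log-rank test with either Mantel-Cox weights (weight 1 at every
#' event time) or Breslow-Wilcoxon weights (weight = total number at risk,
#' emphasizing early differences). The statistic is
#' U' V^{-1} U over the first K - 1 groups, with the usual hypergeometric
#' variance at each distinct event time, referred to a chi-square with
#' K - 1 degrees of freedom.
#'
#' @param data Data frame with time, event and group columns.
#' @param group_col Column defining the groups (>= 2 levels).
#' @param weighting `"mantel-cox"` (default) or `"breslow-wilcoxon"`.
#' @param time_col,event_col Column names as in [km_estimate()].
#' @returns List with `statistic`, `df`, `p`, `weighting`, and the
#'   per-event-time accumulation table `detail`.
#' @export
logrank_test <- function(data, group_col = "group",
                         weighting = c("mantel-cox", "breslow-wilcoxon"),
                         time_col = "pfs_months", event_col = "event") {
  weighting <- match.arg(weighting)
  time <- data[[time_col]]
  event <- as.integer(data[[event_col]])
  group <- factor(data[[group_col]])
  if (nlevels(group) < 2) gs_abort("bad-groups", "Need at least two groups.")
  if (any(table(group) == 0)) gs_abort("bad-groups", "A group has zero subjects.")
  if (sum(event) < 1) gs_abort("no-events", "Need at least one event.")
  K <- nlevels(group)
  tj <- sort(unique(time[event == 1]))
  U <- numeric(K)
  V <- matrix(0, K, K)
  detail <- vector("list", length(tj))
  for (j in seq_along(tj)) {
    t0 <- tj[j]
    at_risk <- time >= t0
    nj <- sum(at_risk)
    ngj <- vapply(levels(group), function(g) sum(at_risk & group == g), numeric(1))
    dj <- sum(time == t0 & event == 1)
    dgj <- vapply(levels(group), function(g) sum(time == t0 & event == 1 & group == g), numeric(1))
    w <- if (weighting == "mantel-cox") 1 else nj
    Ej <- dj * ngj / nj
    U <- U + w * (dgj - Ej)
    if (nj > 1) {
      p_g <- ngj / nj
      Vj <- (diag(p_g) - outer(p_g, p_g)) * dj * (nj - dj) / (nj - 1)
      V <- V + w^2 * Vj
    }
    detail[[j]] <- tibble(
      time = t0, n_risk = nj, n_event = dj,
      observed = list(dgj), expected = list(Ej), weight = w
    )
  }
  idx <- seq_len(K - 1)
  stat <- tryCatch(
    drop(t(U[idx]) %*% solve(V[idx, idx, drop = FALSE], U[idx])),
    error = function(e) 0
  )
  list(
    statistic = stat, df = K - 1,
    p = pchisq(stat, df = K - 1, lower.tail = FALSE),
    weighting = weighting, detail = dplyr::bind_rows(detail)
  )
}

#' Harrell's concordance index
#'
#' Probability that, of a comparable patient pair, the one with the higher
#' risk score progresses first. A pair is comparable when the earlier time
#' is an event (or, for tied times, exactly one member has the event); tied
#' scores receive half credit.
#'
#' @param data Data frame with time and event columns.
#' @param scores Numeric risk scores, one per row of `data` (higher = worse
#'   prognosis).
#' @param time_col,event_col Column names as in [km_estimate()].
#' @returns List with `c_index`, `n_pairs` (comparable pairs), `n_concordant`,
#'   `n_tied`.
#' @export
harrell_c <- function(data, scores, time_col = "pfs_months", event_col = "event") {
  time <- data[[time_col]]
  event <- as.integer(data[[event_col]])
  stopifnot(length(scores) == length(time))
  # ordered pairs (i, j) with i the earlier-event member
  earlier <- outer(time, time, "<") & (event == 1)
  tied_time <- outer(time, time, "==") & outer(event == 1, event == 0, "&")
  comp <- earlier | tied_time
  conc <- comp & outer(scores, scores, ">")
  ties <- comp & outer(scores, scores, "==")
  n_pairs <- sum(comp)
  if (n_pairs == 0) {
    return(list(c_index = NA_real_, n_pairs = 0L, n_concordant = 0L, n_tied = 0L))
  }
  list(
    c_index = (sum(conc) + 0.5 * sum(ties)) / n_pairs,
    n_pairs = n_pairs, n_concordant = sum(conc), n_tied = sum(ties)
  )
}
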