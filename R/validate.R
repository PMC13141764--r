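#' Bootstrap optimism-corrected concordance
#'
#' Harrell's optimism correction: the modeling procedure (a Cox fit on the
#' given covariates) is repeated on `B` bootstrap resamples; each replicate's
#' optimism is its concordance on the resample minus its concordance on the
#' original data, and the corrected C is the apparent C minus the mean
#' optimism. Resamples without events (or where the fit fails) are skipped
#' and counted.
#'
#' @param data Data frame with time, event and covariate columns.
#' @param covariates Character vector of model covariates.
#' @param B Number of bootstrap replicates (>= 100 recommended; smaller
#'   values are accepted for quick checks).
#' @param seed Integer seed; resampling is fully reproducible.
#' @param time_col,event_col Column names as in [km_estimate()].
#' @returns A `validation_report` list: `apparent_c`, `optimism`,
#'   `corrected_c`, `B`, `B_used`, `n_skipped`, `seed`, `replicates`
#'   (tibble boot_c / orig_c / optimism).
#' @export
bootstrap_validate <- function(data, covariates, B = 200, seed = 1L,
                               time_col = "pfs_months", event_col = "event") {
  if (B < 1) gs_abort("bad-b", "`B` must be >= 1.")
  data <- tibble::as_tibble(data)
  full <- cox_fit(data, covariates, time_col, event_col)
  apparent <- harrell_c(data, cox_lp(full, data), time_col, event_col)$c_index
  set.seed(seed)
  n <- nrow(data)
  reps <- purrr::map_dfr(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- data[idx, ]
    if (sum(as.integer(boot[[event_col]])) < 1) {
      return(tibble(boot_c = NA_real_, orig_c = NA_real_, optimism = NA_real_))
    }
    fit_b <- tryCatch(cox_fit(boot, covariates, time_col, event_col),
      error = function(e) NULL
    )
    if (is.null(fit_b)) {
      return(tibble(boot_c = NA_real_, orig_c = NA_real_, optimism = NA_real_))
    }
    boot_c <- harrell_c(boot, cox_lp(fit_b, boot), time_col, event_col)$c_index
    orig_c <- harrell_c(data, cox_lp(fit_b, data), time_col, event_col)$c_index
    tibble(boot_c = boot_c, orig_c = orig_c, optimism = boot_c - orig_c)
  })
  used <- sum(!is.na(reps$optimism))
  optimism <- mean(reps$optimism, na.rm = TRUE)
  structure(
    list(
      apparent_c = apparent, optimism = optimism,
      corrected_c = apparent - optimism,
      B = B, B_used = used, n_skipped = B - used, seed = seed,
      replicates = reps
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report: apparent C %.3f, optimism %.3f, corrected C %.3f (B = %d, %d used)>\n",
    x$apparent_c, x$optimism, x$corrected_c, x$B, x$B_used
  ))
  invisible(x)
}

#' Predicted event probability at a horizon from a Cox fit
#'
#' Breslow baseline cumulative hazard H0 evaluated at the horizon, giving
#' P(event by horizon | x) = 1 - exp(-H0 exp(x' beta)).
#'
#' @param fit A [cox_fit()].
#' @param newdata Data frame with the covariate columns.
#' @param horizon Time (months).
#' @returns Numeric vector of event probabilities.
#' @export
predict_event_prob <- function(fit, newdata, horizon) {
  bh <- survival::basehaz(fit$model, centered = FALSE)
  h0 <- c(0, bh$hazard)[findInterval(horizon, bh$time) + 1]
  1 - exp(-h0 * exp(cox_lp(fit, newdata)))
}

#' Calibration error of predicted event probabilities
#'
#' Compares predicted event probabilities at a horizon against a smoothed
#' observed probability: event indicators at the horizon are
#' inverse-censoring weighted (weights 1/G from the Kaplan-Meier estimate of
#' the censoring distribution) and smoothed on the predicted risk with a
#' weighted local-linear (loess) fit. ICI is the mean and E50 the median of
#' |predicted - smoothed observed| over subjects whose horizon status is
#' known.
#'
#' @param predicted Predicted event probabilities by the horizon.
#' @param data Data frame with time and event columns.
#' @param horizon Evaluation time (months).
#' @param span Loess span (default 0.75).
#' @param time_col,event_col Column names as in [km_estimate()].
#' @returns List with `ici`, `e50`, `n_used`, and the per-subject `detail`
#'   tibble.
#' @export
calibration_error <- function(predicted, data, horizon, span = 0.75,
                              time_col = "pfs_months", event_col = "event") {
  time <- data[[time_col]]
  event <- as.integer(data[[event_col]])
  stopifnot(length(predicted) == length(time))
  if (horizon <= 0 || horizon > max(time)) {
    gs_abort("bad-horizon", "`horizon` must lie within the observed follow-up.")
  }
  # censoring KM, evaluated just before t
  cf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cf$time, c(1, cf$surv), right = TRUE) # right-continuous eval gives G(t-)
  y <- dplyr::case_when(
    time <= horizon & event == 1 ~ 1,
    time > horizon ~ 0,
    .default = NA # censored before the horizon: status unknown
  )
  w <- dplyr::case_when(
    time <= horizon & event == 1 ~ 1 / pmax(G(time), 1e-8),
    time > horizon ~ 1 / pmax(G(horizon), 1e-8),
    .default = 0
  )
  ok <- !is.na(y)
  if (sum(ok) < 10) gs_abort("too-few-cases", "Too few subjects with known horizon status.")
  sm <- if (sd(predicted[ok]) < 1e-10) {
    rep(weighted.mean(y[ok], w[ok]), sum(ok))
  } else {
    fit <- suppressWarnings(
      loess(y ~ p,
        data = data.frame(y = y[ok], p = predicted[ok]),
        weights = w[ok], degree = 1, span = span,
        family = "gaussian"
      )
    )
    pmin(1, pmax(0, predict(fit, newdata = data.frame(p = predicted[ok]))))
  }
  abs_err <- abs(predicted[ok] - sm)
  list(
    ici = mean(abs_err, na.rm = TRUE), e50 = median(abs_err, na.rm = TRUE),
    n_used = sum(ok),
    detail = tibble(
      predicted = predicted[ok], observed_smooth = sm,
      weight = w[ok], status = y[ok]
    )
  )
}

#' Cross-validated concordance and calibration
#'
#' Event-stratified k-fold cross-validation of a Cox model: events and
#' censored records are split into k folds separately (seeded), the model is
#' refit on each training set and scored on the held-out fold. Reports the
#' mean held-out concordance across folds and the pooled calibration (ICI,
#' E50) of the predicted event probabilities at the horizon against the
#' smoothed observed probabilities (see [calibration_error()]).
#'
#' @param data Data frame with time, event and covariate columns.
#' @param covariates Character vector of model covariates.
#' @param k Number of folds (default 5).
#' @param horizon Calibration horizon in months (default 36).
#' @param seed Integer seed for the fold assignment.
#' @param time_col,event_col Column names as in [km_estimate()].
#' @returns A `cv_report` list: `mean_c`, `fold_c`, `ici`, `e50`,
#'   `horizon`, `k`, `seed`, `folds` (assignment vector), `predictions`
#'   (pooled per-subject tibble).
#' @export
crossvalidate <- function(data, covariates, k = 5, horizon = 36, seed = 1L,
                          time_col = "pfs_months", event_col = "event") {
  if (k < 2) gs_abort("bad-k", "`k` must be >= 2.")
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  event <- as.integer(data[[event_col]])
  set.seed(seed)
  folds <- integer(n)
  for (cls in unique(event)) {
    idx <- sample(which(event == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(vapply(seq_len(k), function(f) sum(event[folds == f]), numeric(1)) == 0)) {
    gs_abort("fold-without-events", "A fold holds no events; use a smaller k.")
  }
  fold_c <- numeric(k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- data[folds != f, ]
    test <- data[folds == f, ]
    fit <- cox_fit(train, covariates, time_col, event_col)
    lp <- cox_lp(fit, test)
    fold_c[f] <- harrell_c(test, lp, time_col, event_col)$c_index
    preds[[f]] <- tibble(
      row = which(folds == f), fold = f, lp = lp,
      predicted = predict_event_prob(fit, test, horizon),
      time = test[[time_col]], event = as.integer(test[[event_col]])
    )
  }
  pooled <- dplyr::arrange(dplyr::bind_rows(preds), .data$row)
  cal <- calibration_error(pooled$predicted, pooled,
    horizon = horizon,
    time_col = "time", event_col = "event"
  )
  structure(
    list(
      mean_c = mean(fold_c, na.rm = TRUE), fold_c = fold_c,
      ici = cal$ici, e50 = cal$e50, horizon = horizon, k = k, seed = seed,
      folds = folds, predictions = pooled, calibration = cal$detail
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report: %d-fold, mean C %.3f, ICI %.3f, E50 %.3f at %g months>\n",
    x$k, x$mean_c, x$ici, x$e50, x$horizon
  ))
  invisible(x)
}
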