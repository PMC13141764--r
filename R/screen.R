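#' Pairwise Spearman rank correlations among covariates
#'
#' Rank correlation with average ranks for ties and a two-tailed p-value
#' from the t approximation, computed on pairwise-complete cases. A constant
#' covariate has no defined correlation and is reported as `NA`.
#'
#' @param cohort Data frame holding the covariates (numeric or coercible).
#' @param covariates Character vector of column names.
#' @returns Tibble with one row per unordered pair: `var1`, `var2`, `rho`,
#'   `p`, `n`.
#' @export
spearman_screen <- function(cohort, covariates) {
  stopifnot(all(covariates %in% names(cohort)))
  pairs <- utils::combn(covariates, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- as.numeric(cohort[[pr[1]]])
    y <- as.numeric(cohort[[pr[2]]])
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble(var1 = pr[1], var2 = pr[2], rho = NA_real_, p = NA_real_, n = n))
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    tibble(var1 = pr[1], var2 = pr[2], rho = unname(ct$estimate), p = ct$p.value, n = n)
  })
}

#' Collinearity screen by Spearman correlation and variance inflation
#'
#' Computes each covariate's variance inflation factor
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the least-squares regression of
#' covariate j on all the others, and excludes covariates that are both
#' highly correlated and highly inflated: a covariate is dropped when it
#' belongs to a pair with |rho| > `rho_cut`, that correlation's p <
#' `p_cut`, and its VIF > `vif_cut`. Within a triggering pair the member
#' with the larger VIF is dropped (ties: the one later in `covariates`);
#' VIFs are recomputed after each drop. A rank-deficient design yields
#' infinite VIFs, which auto-flag the covariate.
#'
#' @param cohort Data frame holding the covariates.
#' @param covariates Character vector of column names (numeric or 0/1
#'   coded).
#' @param rho_cut,p_cut,vif_cut Exclusion thresholds (defaults 0.7, 0.05,
#'   10).
#' @returns List of class `screen_result`: `vif` (tibble covariate/vif for
#'   the retained set), `spearman` (pairwise tibble), `excluded` (tibble
#'   covariate/reason), `kept` (character).
#' @export
vif_screen <- function(cohort, covariates, rho_cut = 0.7, p_cut = 0.05, vif_cut = 10) {
  stopifnot(all(covariates %in% names(cohort)))
  X <- as.data.frame(lapply(cohort[covariates], as.numeric))
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) <= length(covariates)) {
    gs_abort("too-few-cases", "Need more complete cases than covariates.")
  }
  sp <- spearman_screen(X, covariates)
  kept <- covariates
  excluded <- tibble(covariate = character(), reason = character())
  repeat {
    vifs <- vif_values(X, kept)
    trig <- dplyr::filter(
      sp,
      .data$var1 %in% kept, .data$var2 %in% kept,
      !is.na(.data$rho), abs(.data$rho) > rho_cut, .data$p < p_cut
    )
    if (nrow(trig) == 0) break
    cand <- unique(c(trig$var1, trig$var2))
    cand <- cand[vifs[cand] > vif_cut]
    if (length(cand) == 0) break
    # drop the largest-VIF member; ties resolved by declared order (later wins)
    ord <- order(-vifs[cand], -match(cand, covariates))
    drop <- cand[ord[1]]
    excluded <- dplyr::bind_rows(excluded, tibble(
      covariate = drop,
      reason = sprintf("|rho| > %.2g with p < %.2g and VIF %.3g > %.2g", rho_cut, p_cut, vifs[drop], vif_cut)
    ))
    kept <- setdiff(kept, drop)
    if (length(kept) < 2) break
  }
  structure(
    list(
      vif = tibble(covariate = kept, vif = unname(vif_values(X, kept))),
      spearman = sp, excluded = excluded, kept = kept
    ),
    class = "screen_result"
  )
}

vif_values <- function(X, covariates) {
  vapply(setNames(covariates, covariates), function(v) {
    others <- setdiff(covariates, v)
    if (length(others) == 0) {
      return(1)
    }
    # rank-deficient designs are expected here (they flag the covariate);
    # silence lm's perfect-fit warning
    fit <- lm(stats::reformulate(others, response = v), data = X)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\nretained covariates and VIF:\n")
  print(as.data.frame(x$vif), row.names = FALSE)
  if (nrow(x$excluded)) {
    cat("excluded:\n")
    print(as.data.frame(x$excluded), row.names = FALSE)
  } else {
    cat("no covariates excluded\n")
  }
  invisible(x)
}
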