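#' Dichotomization cut-points for the cohort analysis
#'
#' The continuous clinical variables are split at fixed, clinically anchored
#' cut-points: age at 38 years, tumor volume at 20.17 cm^3 and the Ki-67
#' labeling index at 10%. Override individual entries to test alternative
#' splits.
#'
#' @param age,volume,ki67 Cut-points (years, cm^3, fraction).
#' @returns Named list of cut-points.
#' @export
shape_dictionary <- function(age = 38, volume = 20.17, ki67 = 0.10) {
  list(age = age, volume = volume, ki67 = ki67)
}

#' Cross-tabulate a cohort variable against boundary shape
#'
#' Builds the 2 x c(L, C) contingency table for one variable. Numeric
#' variables are dichotomized at `cutpoint` into `<=` / `>` levels;
#' categorical variables use `level_order` (defaults to their sorted unique
#' values). Patients with a missing value are dropped; the number dropped is
#' attached as attribute `n_dropped`.
#'
#' @param cohort Data frame with a `shape_label` column (values `"L"`,
#'   `"C"`) and the variable of interest.
#' @param variable Column name (string).
#' @param level_order Character vector declaring the row order.
#' @param cutpoint Numeric cut-point for a numeric variable.
#' @returns A `contingency_table`: integer matrix with row labels = levels
#'   and column labels `L`, `C`.
#' @examples
#' cohort <- tibble::tibble(
#'   shape_label = rep(c("L", "C"), each = 4),
#'   epilepsy = c("yes", "yes", "no", "no", "yes", "no", "no", "no")
#' )
#' build_contingency(cohort, "epilepsy", level_order = c("yes", "no"))
#' @export
build_contingency <- function(cohort, variable, level_order = NULL, cutpoint = NULL) {
  if (!variable %in% names(cohort)) {
    gs_abort("unknown-variable", paste0("Column `", variable, "` not found in cohort."))
  }
  if (!"shape_label" %in% names(cohort)) {
    gs_abort("missing-shape", "Cohort needs a `shape_label` column.")
  }
  v <- cohort[[variable]]
  if (is.numeric(v)) {
    if (is.null(cutpoint)) gs_abort("missing-cutpoint", "Numeric variable needs a `cutpoint`.")
    level_order <- c(paste0("<=", cutpoint), paste0(">", cutpoint))
    v <- ifelse(is.na(v), NA_character_, ifelse(v <= cutpoint, level_order[1], level_order[2]))
  }
  v <- as.character(v)
  if (is.null(level_order)) level_order <- sort(unique(v[!is.na(v)]))
  if (length(level_order) == 0) gs_abort("degenerate-table", "No observed levels to tabulate.")
  shape <- as.character(cohort$shape_label)
  keep <- !is.na(v) & !is.na(shape)
  tab <- vapply(c("L", "C"), function(sh) {
    vapply(level_order, function(lv) sum(v[keep] == lv & shape[keep] == sh), integer(1))
  }, integer(length(level_order)))
  tab <- matrix(as.integer(tab),
    nrow = length(level_order),
    dimnames = list(level_order, c("L", "C"))
  )
  if (sum(tab) == 0) gs_abort("degenerate-table", "Contingency table is all zero.")
  structure(tab, class = c("contingency_table", "matrix", "array"), n_dropped = sum(!keep))
}

#' Odds ratio with Woolf confidence interval for a 2 x 2 table
#'
#' Computes the cross-product odds ratio OR = (a d) / (b c) on the oriented
#' table together with the 95% Woolf (log-normal) interval
#' exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)) and the Pearson
#' chi-square test. Orientation is always explicit: `"row2-first"` swaps the
#' rows before computation (equivalently, inverts the OR), because printed
#' association tables do not always share one reference coding. Zero cells
#' fall back to the Haldane-Anscombe +0.5 correction, flagged in the output.
#'
#' @param table 2 x 2 numeric matrix (e.g. a [build_contingency()] result).
#' @param orientation `"row1-first"` (default) or `"row2-first"`.
#' @param correct Apply the Yates continuity correction to the chi-square
#'   test (default `FALSE`).
#' @returns A one-row tibble: `or`, `ci_low`, `ci_high`, `chi2`, `p`,
#'   `orientation`, `haldane`.
#' @examples
#' odds_ratio(matrix(c(22, 139, 12, 157), 2, 2))
#' @export
odds_ratio <- function(table, orientation = c("row1-first", "row2-first"),
                       correct = FALSE) {
  orientation <- match.arg(orientation)
  tab <- unclass(as.matrix(table))
  if (!all(dim(tab) == c(2, 2))) gs_abort("bad-table", "Need a 2 x 2 table.")
  if (any(tab < 0)) gs_abort("bad-table", "Cells must be non-negative.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    gs_abort("degenerate-table", "A margin of the table is zero.")
  }
  if (orientation == "row2-first") tab <- tab[2:1, ]
  haldane <- any(tab == 0)
  tt <- if (haldane) tab + 0.5 else tab
  a <- tt[1, 1]
  b <- tt[1, 2]
  c_ <- tt[2, 1]
  d <- tt[2, 2]
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  chi <- chi_square(tab, correct = correct)
  tibble(
    or = or,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se),
    chi2 = chi$statistic,
    p = chi$p,
    orientation = orientation,
    haldane = haldane
  )
}

#' Pearson chi-square test of independence
#'
#' @param table r x c contingency table (matrix).
#' @param correct Yates continuity correction for 2 x 2 tables (default
#'   `FALSE`).
#' @returns List with `statistic`, `df`, `p`.
#' @export
chi_square <- function(table, correct = FALSE) {
  tab <- unclass(as.matrix(table))
  if (any(tab < 0)) gs_abort("bad-table", "Cells must be non-negative.")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) gs_abort("zero-expected", "A cell has zero expected count.")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter), p = unname(ct$p.value))
}

#' Printed cohort summary counts (association worked example)
#'
#' Per-variable 2 x 2 counts of the 330-patient cohort summary table
#' (linear vs curved boundary), with the printed odds ratio, the orientation
#' under which the cross-product reproduces it, and the printed p-value
#' band. The epilepsy row is flagged `consistent = FALSE`: its printed OR
#' (1.21) does not match its own counts under either orientation
#' (cross-product 1.12), so it is excluded from reproduction checks.
#'
#' These counts are also the default conditional frequencies of the cohort
#' generator, see [make_cohort()].
#'
#' @returns Tibble with columns `variable`, `level1`, `level2`, `l1`, `c1`,
#'   `l2`, `c2` (counts: level1/level2 by L/C), `or_printed`, `orientation`,
#'   `consistent`.
#' @export
table1_counts <- function() {
  tibble::tribble(
    ~variable, ~level1, ~level2, ~l1, ~c1, ~l2, ~c2, ~or_printed, ~orientation, ~consistent,
    "age", "<=38", ">38", 91L, 58L, 70L, 111L, 0.40, "row2-first", TRUE,
    "gender", "male", "female", 85L, 92L, 76L, 77L, 0.94, "row1-first", TRUE,
    "side", "left", "right", 78L, 89L, 83L, 80L, 0.84, "row1-first", TRUE,
    "volume", "<=20.17", ">20.17", 22L, 12L, 139L, 157L, 2.07, "row1-first", TRUE,
    "histology", "OGS", "non-OGS", 46L, 71L, 74L, 65L, 0.57, "row1-first", TRUE,
    "who_grade", "2", "3", 108L, 117L, 53L, 52L, 0.91, "row1-first", TRUE,
    "idh1", "mutant", "wild", 73L, 85L, 14L, 15L, 0.92, "row1-first", TRUE,
    "codel_1p19q", "co-deleted", "intact", 31L, 49L, 72L, 63L, 0.55, "row1-first", TRUE,
    "idh_mut_1p19q", "with-codel", "without-codel", 9L, 44L, 34L, 65L, 0.39, "row1-first", TRUE,
    "atrx", "mutant", "wild", 59L, 49L, 43L, 63L, 0.57, "row2-first", TRUE,
    "mgmt", "methylated", "unmethylated", 52L, 53L, 17L, 14L, 0.81, "row1-first", TRUE,
    "tp53", "mutant", "wild", 71L, 58L, 58L, 88L, 0.54, "row2-first", TRUE,
    "ki67", "<=10%", ">10%", 38L, 64L, 70L, 67L, 0.57, "row1-first", TRUE,
    "epilepsy", "yes", "no", 95L, 95L, 66L, 74L, 1.21, "row1-first", FALSE
  )
}

#' Univariate association of every cohort variable with boundary shape
#'
#' Reproduces the cohort-summary association analysis: for each variable,
#' the 2 x 2 table against the L/C shape label, the chi-square p-value and
#' the odds ratio with its Woolf interval. Numeric variables are
#' dichotomized at the [shape_dictionary()] cut-points; complete-case per
#' variable, with the dropped count reported.
#'
#' @param cohort A cohort tibble (see [make_cohort()] for the column
#'   layout).
#' @param dictionary Cut-points from [shape_dictionary()].
#' @param orientations Named character vector of per-variable OR
#'   orientations; defaults to the declared orientations of
#'   [table1_counts()], `"row1-first"` for variables not listed.
#' @returns Tibble with one row per variable: counts per cell, `chi2`, `p`,
#'   `or`, `ci_low`, `ci_high`, `n_dropped`.
#' @export
associate_shape <- function(cohort, dictionary = shape_dictionary(),
                            orientations = NULL) {
  t1 <- table1_counts()
  if (is.null(orientations)) {
    orientations <- setNames(t1$orientation, t1$variable)
  }
  specs <- list(
    age = list(cut = dictionary$age), volume = list(cut = dictionary$volume),
    ki67_index = list(cut = dictionary$ki67),
    gender = list(levels = c("male", "female")),
    side = list(levels = c("left", "right")),
    histology = list(levels = c("OGS", "non-OGS")),
    who_grade = list(levels = c("2", "3")),
    idh1 = list(levels = c("mutant", "wild")),
    codel_1p19q = list(levels = c("co-deleted", "intact")),
    atrx = list(levels = c("mutant", "wild")),
    mgmt = list(levels = c("methylated", "unmethylated")),
    tp53 = list(levels = c("mutant", "wild")),
    epilepsy = list(levels = c("yes", "no"))
  )
  specs <- specs[names(specs) %in% names(cohort)]
  purrr::map_dfr(names(specs), function(v) {
    sp <- specs[[v]]
    tab <- build_contingency(cohort, v, level_order = sp$levels, cutpoint = sp$cut)
    key <- if (v == "ki67_index") "ki67" else v
    orient <- unname(orientations[key] %||% "row1-first")
    if (is.na(orient)) orient <- "row1-first"
    res <- odds_ratio(tab, orientation = orient)
    tibble(
      variable = v,
      level1 = rownames(tab)[1], level2 = rownames(tab)[2],
      l1 = tab[1, 1], c1 = tab[1, 2], l2 = tab[2, 1], c2 = tab[2, 2],
      chi2 = res$chi2, p = res$p,
      or = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
      orientation = orient,
      n_dropped = attr(tab, "n_dropped")
    )
  })
}
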