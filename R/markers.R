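#' Pathology marker thresholds
#'
#' Positive-call thresholds on the raw assay fraction, all inclusive (a
#' measurement exactly at the threshold is positive): IDH1 focal
#' immunostaining >= 30% immunoreactive tumor cells; ATRX and TP53 >= 10%
#' stained nuclei; 1p/19q co-deletion >= 25% of locus-specific probe
#' signals with concurrent loss; MGMT >= 10% mean methylation across CpG
#' sites.
#'
#' @returns Named numeric vector of thresholds on the 0-1 fraction scale.
#' @export
marker_thresholds <- function() {
  c(IDH1 = 0.30, ATRX = 0.10, TP53 = 0.10, `1p/19q` = 0.25, MGMT = 0.10)
}

#' Call marker status from a raw assay fraction
#'
#' @param marker Marker name: one of `"IDH1"`, `"ATRX"`, `"TP53"`,
#'   `"1p/19q"` (alias `"1p19q"`), `"MGMT"`. Case-insensitive. Recycled
#'   against `measurement`.
#' @param measurement Fraction in \[0, 1\] (immunoreactive cells, stained
#'   nuclei, probe signals or methylation level, per marker).
#' @returns Character vector, `"positive"` or `"negative"` (`NA` in gives
#'   `NA` out).
#' @examples
#' call_marker_status("IDH1", 0.30) # inclusive threshold -> positive
#' call_marker_status("ATRX", 0.09)
#' @export
call_marker_status <- function(marker, measurement) {
  thr <- marker_thresholds()
  key <- toupper(gsub("1P19Q", "1P/19Q", toupper(marker)))
  names(thr) <- toupper(names(thr))
  if (any(!key %in% names(thr))) {
    gs_abort("unknown-marker", paste0(
      "Unknown marker(s): ", paste(unique(marker[!key %in% names(thr)]), collapse = ", "),
      ". Known: ", paste(names(marker_thresholds()), collapse = ", "), "."
    ))
  }
  bad <- !is.na(measurement) & (measurement < 0 | measurement > 1)
  if (any(bad)) gs_abort("bad-fraction", "`measurement` must lie in [0, 1].")
  ifelse(is.na(measurement), NA_character_,
    ifelse(measurement >= thr[key], "positive", "negative")
  )
}

#' Ki-67 labeling index
#'
#' Proportion of stained tumor nuclei among all tumor nuclei counted in the
#' proliferative field.
#'
#' @param stained Count of stained nuclei, `0 <= stained <= total`.
#' @param total Total nuclei counted, `> 0`.
#' @returns Fraction in \[0, 1\].
#' @examples
#' compute_ki67_index(10, 100)
#' @export
compute_ki67_index <- function(stained, total) {
  if (any(total <= 0)) gs_abort("empty-field", "`total` nuclei must be positive.")
  if (any(stained < 0) || any(stained > total)) {
    gs_abort("bad-count", "`stained` must lie in [0, total].")
  }
  stained / total
}
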