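#' Boundary curves
#'
#' A boundary curve is an ordered polyline in physical (mm) coordinates,
#' stored as a tibble with columns `x`, `y` and the cumulative arc length `s`
#' (with `s[1] = 0`). It represents the tumor--basal-ganglia interface arc on
#' one axial slice. Closed curves (full contours) carry `closed = TRUE`; the
#' first and last point of a closed curve are distinct (the closing segment is
#' implicit).
#'
#' @param x,y Numeric coordinate vectors in mm.
#' @param closed Is the polyline a closed contour?
#' @returns A `boundary_curve` tibble with columns `x`, `y`, `s`.
#' @examples
#' boundary_curve(c(0, 1, 2), c(0, 0, 0))
#' @export
boundary_curve <- function(x, y, closed = FALSE) {
  if (length(x) != length(y)) gs_abort("bad-curve", "`x` and `y` must have equal length.")
  if (length(x) < 3) gs_abort("degenerate-arc", "A boundary curve needs at least 3 points.")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    gs_abort("bad-curve", "Curve coordinates must be finite.")
  }
  step <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(step == 0)) gs_abort("bad-curve", "Consecutive curve points must be distinct.")
  out <- tibble(x = as.numeric(x), y = as.numeric(y), s = c(0, cumsum(step)))
  structure(out, class = c("boundary_curve", class(out)), closed = isTRUE(closed))
}

#' @rdname boundary_curve
#' @param curve A `boundary_curve`.
#' @export
is_closed <- function(curve) isTRUE(attr(curve, "closed"))

#' @rdname boundary_curve
#' @export
curve_length <- function(curve) {
  L <- curve$s[nrow(curve)]
  if (is_closed(curve)) {
    n <- nrow(curve)
    L <- L + sqrt((curve$x[1] - curve$x[n])^2 + (curve$y[1] - curve$y[n])^2)
  }
  L
}

#' Chord length between the endpoints of an open curve
#'
#' @param curve An open `boundary_curve`.
#' @returns Euclidean distance in mm between first and last point.
#' @export
curve_chord <- function(curve) {
  if (is_closed(curve)) gs_abort("undefined-chord", "A closed curve has no endpoint chord.")
  n <- nrow(curve)
  sqrt((curve$x[n] - curve$x[1])^2 + (curve$y[n] - curve$y[1])^2)
}

#' Tortuosity of an open boundary arc
#'
#' Tortuosity is the ratio L / D of the arc length L to the endpoint chord D.
#' A straight segment has tortuosity exactly 1; every other open curve exceeds
#' 1.
#'
#' @param curve An open `boundary_curve`.
#' @returns A unitless scalar >= 1.
#' @examples
#' tortuosity(boundary_curve(c(0, 1, 2), c(0, 0, 0)))
#' @export
tortuosity <- function(curve) {
  if (is_closed(curve)) gs_abort("undefined-chord", "Tortuosity is undefined for closed curves.")
  D <- curve_chord(curve)
  if (D == 0) gs_abort("undefined-chord", "Coincident endpoints: chord is zero.")
  curve_length(curve) / D
}

#' Resample a curve at equal arc-length spacing
#'
#' Linear interpolation along the polyline; the endpoints are preserved
#' exactly. Used before curvature estimation and rasterization so that
#' downstream estimators see a uniform parameterization.
#'
#' @param curve A `boundary_curve`.
#' @param n_points Number of output points (>= 3).
#' @returns A `boundary_curve` with `n_points` rows.
#' @export
resample_arclength <- function(curve, n_points) {
  if (n_points < 3) gs_abort("bad-n-points", "`n_points` must be at least 3.")
  pts <- curve_points_closed(curve)
  L <- pts$s[nrow(pts)]
  if (L <= 0) gs_abort("zero-length-curve", "Cannot resample a zero-length curve.")
  s_new <- seq(0, L, length.out = if (is_closed(curve)) n_points + 1L else n_points)
  x_new <- approx(pts$s, pts$x, xout = s_new, ties = "ordered")$y
  y_new <- approx(pts$s, pts$y, xout = s_new, ties = "ordered")$y
  if (is_closed(curve)) {
    x_new <- x_new[-length(x_new)]
    y_new <- y_new[-length(y_new)]
  } else {
    # pin endpoints against interpolation round-off
    x_new[c(1, n_points)] <- curve$x[c(1, nrow(curve))]
    y_new[c(1, n_points)] <- curve$y[c(1, nrow(curve))]
  }
  keep <- c(TRUE, sqrt(diff(x_new)^2 + diff(y_new)^2) > 0)
  boundary_curve(x_new[keep], y_new[keep], closed = is_closed(curve))
}

# Point table with the closing segment made explicit for closed curves.
curve_points_closed <- function(curve) {
  pts <- tibble(x = curve$x, y = curve$y, s = curve$s)
  if (is_closed(curve)) {
    n <- nrow(pts)
    close_step <- sqrt((pts$x[1] - pts$x[n])^2 + (pts$y[1] - pts$y[n])^2)
    pts <- dplyr::bind_rows(pts, tibble(x = pts$x[1], y = pts$y[1], s = pts$s[n] + close_step))
  }
  pts
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf(
    "<boundary_curve: %d points, %s, length %.3f mm>\n",
    nrow(x), if (is_closed(x)) "closed" else "open", curve_length(x)
  ))
  NextMethod()
}
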