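#' Single-slice binary tumor mask
#'
#' Wraps a 2D binary segmentation (one axial slice) together with the pixel
#' spacing and the medial-direction hint used to pick out the
#' tumor--basal-ganglia interface. Pixel `[i, j]` (row i, column j, 1-based)
#' sits at physical coordinates `x = (j - 1) * spacing[2]`,
#' `y = (i - 1) * spacing[1]` in mm; `medial_hint` is a direction in this
#' (x, y) plane pointing from the tumor centroid toward the basal ganglia.
#'
#' Only the largest 4-connected foreground component is retained, so a mask
#' with stray islands still yields a single well-defined contour.
#'
#' @param pixels Logical or 0/1 matrix (rows x cols).
#' @param spacing Length-2 numeric, physical size of one pixel in mm as
#'   `c(row, col)`. Default 1 mm isotropic.
#' @param medial_hint Length-2 numeric direction `c(dx, dy)`; normalized
#'   internally. Default `c(1, 0)` (medial structures to the image right).
#' @param slice_index Optional integer recording which axial slice this is.
#' @returns A `mask_slice` object.
#' @export
mask_slice <- function(pixels, spacing = c(1, 1), medial_hint = c(1, 0),
                       slice_index = NA_integer_) {
  if (!is.matrix(pixels)) gs_abort("bad-mask", "`pixels` must be a matrix.")
  px <- matrix(as.integer(pixels != 0), nrow = nrow(pixels))
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  if (length(spacing) != 2 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    gs_abort("bad-spacing", "`spacing` must be two positive numbers (row, col) in mm.")
  }
  if (sum(px) == 0) gs_abort("empty-mask", "Mask has no foreground pixels.")
  hn <- sqrt(sum(medial_hint^2))
  if (length(medial_hint) != 2 || !is.finite(hn) || hn == 0) {
    gs_abort("bad-hint", "`medial_hint` must be a nonzero 2-vector.")
  }
  px <- largest_component(px)
  structure(
    list(
      pixels = px, spacing = as.numeric(spacing),
      medial_hint = as.numeric(medial_hint / hn),
      slice_index = as.integer(slice_index)
    ),
    class = "mask_slice"
  )
}

#' @export
print.mask_slice <- function(x, ...) {
  cat(sprintf(
    "<mask_slice: %d x %d px, spacing %.3g x %.3g mm, %d foreground px, hint (%.2f, %.2f)>\n",
    nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
    sum(x$pixels), x$medial_hint[1], x$medial_hint[2]
  ))
  invisible(x)
}

# Largest 4-connected foreground component, by iterative label propagation
# (vectorized max over shifted copies; iterations bounded by component
# diameter).
largest_component <- function(px) {
  lab <- matrix(seq_along(px), nrow = nrow(px)) * px
  repeat {
    up <- rbind(lab[-1, , drop = FALSE], 0)
    down <- rbind(0, lab[-nrow(lab), , drop = FALSE])
    left <- cbind(lab[, -1, drop = FALSE], 0)
    right <- cbind(0, lab[, -ncol(lab), drop = FALSE])
    new <- pmax(lab, up, down, left, right) * px
    if (all(new == lab)) break
    lab <- new
  }
  ids <- lab[lab > 0]
  keep <- as.integer(names(which.max(table(ids))))
  matrix(as.integer(lab == keep), nrow = nrow(px))
}

#' Extract the medial boundary arc from a mask
#'
#' Traces the full tumor contour with marching squares at the 0.5 level and
#' keeps the longest contiguous stretch whose outward normals point to within
#' `angular_window / 2` degrees of the medial hint. This is a deterministic,
#' orientation-based stand-in for the manual tracing of the interface between
#' the tumor and the basal ganglia: the medial-facing part of the contour is,
#' by construction, the part whose outward normal points toward the medial
#' structures.
#'
#' @param mask A [mask_slice()].
#' @param angular_window Full angular width in degrees (0, 180] of the
#'   accepted normal directions around `medial_hint`. Default 90.
#' @returns An open [boundary_curve()] in mm, ordered counterclockwise along
#'   the parent contour.
#' @export
extract_medial_boundary <- function(mask, angular_window = 90) {
  stopifnot(inherits(mask, "mask_slice"))
  if (!is.finite(angular_window) || angular_window <= 0 || angular_window > 180) {
    gs_abort("bad-window", "`angular_window` must be in (0, 180] degrees.")
  }
  contour <- mask_contour(mask)
  # wide-support tangents: the marching-squares contour is a 1 px staircase,
  # so point-wise differences make the normal field oscillate; differencing
  # over ~5 px of arc length gives the macroscopic normal direction
  step <- mean(sqrt(diff(contour$x)^2 + diff(contour$y)^2))
  k <- max(1L, ceiling(2.5 * max(mask$spacing) / step))
  tx <- tangent_ccw(contour$x, k)
  ty <- tangent_ccw(contour$y, k)
  nrm <- sqrt(tx^2 + ty^2)
  nx <- ty / nrm
  ny <- -tx / nrm
  dot <- nx * mask$medial_hint[1] + ny * mask$medial_hint[2]
  ok <- !is.na(dot) & dot >= cos(angular_window / 2 * pi / 180)
  if (!any(ok)) gs_abort("no-medial-arc", "No contour points face the medial direction.")
  idx <- longest_circular_run(ok)
  if (length(idx) < 3) gs_abort("degenerate-arc", "Medial arc has fewer than 3 points.")
  boundary_curve(contour$x[idx], contour$y[idx], closed = FALSE)
}

# Full closed contour of the mask (marching squares at level 0.5), CCW,
# in mm. The mask is zero-padded so the contour always closes.
mask_contour <- function(mask) {
  px <- mask$pixels
  pad <- matrix(0L, nrow = nrow(px) + 2, ncol = ncol(px) + 2)
  pad[2:(nrow(px) + 1), 2:(ncol(px) + 1)] <- px
  xs <- (seq_len(ncol(pad)) - 2) * mask$spacing[2]
  ys <- (seq_len(nrow(pad)) - 2) * mask$spacing[1]
  cl <- grDevices::contourLines(x = xs, y = ys, z = t(pad), levels = 0.5)
  if (length(cl) == 0) gs_abort("empty-mask", "No contour found.")
  lens <- vapply(cl, function(p) sum(sqrt(diff(p$x)^2 + diff(p$y)^2)), numeric(1))
  p <- cl[[which.max(lens)]]
  x <- p$x
  y <- p$y
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]
    y <- y[-n]
  }
  # marching squares can emit repeated vertices; drop them so tangents are
  # well defined
  keep <- c(TRUE, diff(x)^2 + diff(y)^2 > 0)
  x <- x[keep]
  y <- y[keep]
  # force counterclockwise orientation (positive shoelace area)
  area <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  if (area < 0) {
    x <- rev(x)
    y <- rev(y)
  }
  list(x = x, y = y)
}

# Circular central-difference tangent with half-support k points.
tangent_ccw <- function(v, k = 1L) {
  n <- length(v)
  k <- min(k, floor((n - 1) / 2))
  idx <- seq_len(n)
  fwd <- ((idx - 1 + k) %% n) + 1
  bwd <- ((idx - 1 - k) %% n) + 1
  v[fwd] - v[bwd]
}

# Indices of the longest circularly contiguous run of TRUE.
longest_circular_run <- function(ok) {
  n <- length(ok)
  if (all(ok)) return(seq_len(n))
  start <- which(!ok)[1]
  rot <- c(seq(start, n), seq_len(start - 1))
  r <- rle(ok[rot])
  ends <- cumsum(r$lengths)
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]
  rot[seq(ends[best] - r$lengths[best] + 1, ends[best])]
}
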