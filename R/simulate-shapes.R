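#' Specification of a synthetic boundary shape
#'
#' Describes a shape family with known analytic geometry, used to exercise
#' the boundary pipeline without any imaging data. Families:
#'
#' * `"straight-edge"` — half-plane mask whose medial edge is a vertical
#'   straight segment (tortuosity 1, total curvature 0).
#' * `"arc"` — filled disk; the medial boundary is a circular arc of radius
#'   `radius` mm. `angle` = 360 gives the full closed circle.
#' * `"sinusoid"` — half-plane mask bounded by
#'   x = x0 + amplitude * sin(2 pi y / wavelength).
#' * `"koch"` — Koch-curve polyline after `iterations` construction steps
#'   (similarity dimension log 4 / log 3); rasterized as a curve, not a
#'   region.
#' * `"clothoid"` — curve with linearly increasing curvature
#'   kappa(s) = rate * s; rasterized as a curve.
#'
#' @param family One of the five families above.
#' @param radius Arc radius in mm (arc family; default 20).
#' @param angle Subtended angle of the arc in degrees (default 90; 360 =
#'   closed circle).
#' @param amplitude,wavelength Sinusoid amplitude and wavelength in mm.
#' @param iterations Koch construction iterations (default 4).
#' @param length Initiator / segment length in mm (straight-edge, koch,
#'   clothoid).
#' @param rate Clothoid curvature slope dkappa/ds in 1/mm^2 (default 0.01).
#' @param jitter Gaussian point jitter SD in mm applied to the returned
#'   ground-truth curve (default 0).
#' @param size Raster side in px (default 256).
#' @param spacing Pixel size in mm (default 1, isotropic).
#' @param seed Seed for the jitter (default 1).
#' @returns A `shape_spec` list.
#' @export
shape_spec <- function(family = c("straight-edge", "arc", "sinusoid", "koch", "clothoid"),
                       radius = 20, angle = 90, amplitude = 8, wavelength = 64,
                       iterations = 4, length = 100, rate = 0.01,
                       jitter = 0, size = 256, spacing = 1, seed = 1L) {
  family <- match.arg(family)
  if (jitter < 0) gs_abort("bad-spec", "`jitter` must be >= 0.")
  if (size < 16) gs_abort("bad-spec", "`size` must be at least 16 px.")
  structure(
    list(
      family = family, radius = radius, angle = angle, amplitude = amplitude,
      wavelength = wavelength, iterations = iterations, length = length,
      rate = rate, jitter = jitter, size = size, spacing = spacing,
      seed = as.integer(seed)
    ),
    class = "shape_spec"
  )
}

#' Generate a synthetic boundary shape
#'
#' Builds the rasterized mask, the analytic ground-truth boundary curve and
#' the closed-form descriptor values (where they exist) for a [shape_spec()].
#' Masks are binary region indicators sampled at pixel centers with no
#' anti-aliasing, matching segmentation-mask inputs; for the `koch` and
#' `clothoid` families the "mask" is the rasterized curve itself (these
#' families exist to test curve estimators, not region extraction).
#'
#' @param spec A [shape_spec()].
#' @returns A list with elements `mask` ([mask_slice()]), `curve`
#'   ([boundary_curve()], jittered if `spec$jitter > 0`) and `truth` (named
#'   list of analytic descriptor values; `NA` where no closed form exists).
#' @examples
#' shp <- make_shape(shape_spec("arc", radius = 20, angle = 180))
#' shp$truth$tortuosity # pi / 2
#' @export
make_shape <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  sp <- spec$spacing
  n <- spec$size
  xc <- (seq_len(n) - 1) * sp # columns -> x
  yc <- (seq_len(n) - 1) * sp # rows    -> y
  half_extent <- (n - 1) * sp
  out <- switch(spec$family,
    "straight-edge" = {
      x0 <- round(n / 2) * sp
      px <- outer(yc, xc, function(y, x) x <= x0 - sp / 2)
      ymax <- min(spec$length, half_extent)
      yy <- seq(0, ymax, length.out = max(101, ceiling(ymax / sp) + 1))
      list(
        mask = mask_slice(px, c(sp, sp), c(1, 0)),
        curve = boundary_curve(rep(x0 - sp / 2, length(yy)), yy),
        truth = list(
          tortuosity = 1, total_curvature = 0, max_curvature = 0,
          average_curvature = 0, curvature_variation = 0, fd = 1
        )
      )
    },
    "arc" = {
      r <- spec$radius
      cx <- half_extent / 2
      cy <- half_extent / 2
      if (r >= half_extent / 2) gs_abort("shape-too-large", "Arc radius exceeds the raster.")
      px <- outer(yc, xc, function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
      closed <- spec$angle >= 360
      th_half <- min(spec$angle, 360) / 2 * pi / 180
      th <- seq(-th_half, th_half, length.out = 721)
      if (closed) th <- th[-length(th)]
      theta <- spec$angle * pi / 180
      list(
        mask = mask_slice(px, c(sp, sp), c(1, 0)),
        curve = boundary_curve(cx + r * cos(th), cy + r * sin(th), closed = closed),
        truth = list(
          tortuosity = if (closed) NA_real_ else (theta / 2) / sin(theta / 2),
          total_curvature = theta, max_curvature = 1 / r,
          average_curvature = 1 / r, curvature_variation = 0, fd = 1
        )
      )
    },
    "sinusoid" = {
      x0 <- round(n / 2) * sp
      edge <- function(y) x0 + spec$amplitude * sin(2 * pi * y / spec$wavelength)
      px <- outer(yc, xc, function(y, x) x <= edge(y))
      yy <- seq(0, half_extent, length.out = 20 * n)
      xx <- edge(yy)
      L <- sum(sqrt(diff(xx)^2 + diff(yy)^2))
      list(
        mask = mask_slice(px, c(sp, sp), c(1, 0)),
        curve = boundary_curve(xx, yy),
        truth = list(
          tortuosity = L / half_extent, total_curvature = NA_real_,
          max_curvature = spec$amplitude * (2 * pi / spec$wavelength)^2,
          average_curvature = NA_real_, curvature_variation = NA_real_,
          fd = 1
        )
      )
    },
    "koch" = {
      pts <- koch_polyline(spec$iterations)
      xx <- pts$x * spec$length
      yy <- pts$y * spec$length
      list(
        mask = rasterize_curve(xx, yy, sp),
        curve = boundary_curve(xx, yy),
        truth = list(
          tortuosity = (4 / 3)^spec$iterations, total_curvature = NA_real_,
          max_curvature = NA_real_, average_curvature = NA_real_,
          curvature_variation = NA_real_, fd = log(4) / log(3)
        )
      )
    },
    "clothoid" = {
      s_max <- spec$length
      ss <- seq(0, s_max, length.out = 4000)
      theta <- spec$rate * ss^2 / 2
      ds <- ss[2] - ss[1]
      xx <- c(0, cumsum(cos(theta[-length(theta)]) * ds))
      yy <- c(0, cumsum(sin(theta[-length(theta)]) * ds))
      list(
        mask = rasterize_curve(xx, yy, sp),
        curve = boundary_curve(xx, yy),
        truth = list(
          tortuosity = NA_real_, total_curvature = spec$rate * s_max^2 / 2,
          max_curvature = spec$rate * s_max, average_curvature = spec$rate * s_max / 2,
          curvature_variation = spec$rate, fd = 1
        )
      )
    }
  )
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    cv <- out$curve
    out$curve <- boundary_curve(
      cv$x + rnorm(nrow(cv), 0, spec$jitter),
      cv$y + rnorm(nrow(cv), 0, spec$jitter),
      closed = is_closed(cv)
    )
  }
  out
}

# Koch curve polyline on a unit initiator along +x.
koch_polyline <- function(iterations) {
  dirs <- 0
  for (i in seq_len(iterations)) {
    dirs <- c(vapply(dirs, function(d) c(d, d + pi / 3, d - pi / 3, d), numeric(4)))
  }
  step <- (1 / 3)^iterations
  x <- c(0, cumsum(cos(dirs) * step))
  y <- c(0, cumsum(sin(dirs) * step))
  list(x = x, y = y)
}

# Curve drawn as occupied pixels (1 px wide), shifted into the positive
# quadrant with a small margin.
rasterize_curve <- function(x, y, sp) {
  margin <- 4 * sp
  x <- x - min(x) + margin
  y <- y - min(y) + margin
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  s_f <- seq(0, s[length(s)], length.out = max(2000, ceiling(s[length(s)] / sp * 4)))
  xf <- approx(s, x, xout = s_f, ties = "ordered")$y
  yf <- approx(s, y, xout = s_f, ties = "ordered")$y
  ncol_px <- ceiling((max(xf) + margin) / sp)
  nrow_px <- ceiling((max(yf) + margin) / sp)
  px <- matrix(0L, nrow = nrow_px, ncol = ncol_px)
  px[cbind(pmin(nrow_px, floor(yf / sp) + 1), pmin(ncol_px, floor(xf / sp) + 1))] <- 1L
  # curve rasters are 8-connected; bridge diagonal steps so the largest
  # 4-connected component keeps the whole curve
  mask_slice(bridge_diagonals(px), c(sp, sp), c(1, 0))
}

bridge_diagonals <- function(px) {
  nr <- nrow(px)
  nc <- ncol(px)
  ij <- which(px == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(ij))) {
    i <- ij[k, 1]
    j <- ij[k, 2]
    if (i < nr && j < nc && px[i + 1, j + 1] == 1L && px[i + 1, j] == 0L && px[i, j + 1] == 0L) {
      px[i + 1, j] <- 1L
    }
    if (i > 1 && j < nc && px[i - 1, j + 1] == 1L && px[i - 1, j] == 0L && px[i, j + 1] == 0L) {
      px[i - 1, j] <- 1L
    }
  }
  px
}
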