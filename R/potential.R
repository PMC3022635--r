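# Opportunities of one facility type joined to municipality coordinates,
# restricted to positive counts.
.opportunity_frame <- function(region, facilities, facility_type) {
  stopifnot(inherits(region, "data.frame"), inherits(facilities, "data.frame"))
  types <- unique(facilities$facility_type)
  if (!facility_type %in% types) {
    stop("unknown facility type '", facility_type, "'; available: ",
         paste(sort(types), collapse = ", "))
  }
  f <- facilities[facilities$facility_type == facility_type, , drop = FALSE]
  missing <- setdiff(f$municipality_id, region$id)
  if (length(missing)) {
    stop("facility rows reference unknown municipalities: ",
         paste(missing, collapse = ", "))
  }
  idx <- match(f$municipality_id, region$id)
  data.frame(x = region$x[idx], y = region$y[idx],
             count = f$count)[f$count > 0, , drop = FALSE]
}

#' Potential accessibility at arbitrary points
#'
#' The potential (Hansen-type) accessibility index at a point `i` is the sum
#' of opportunity counts over destination municipalities, each weighted by the
#' impedance function of the straight-line distance:
#' \deqn{\Phi_i = \sum_j O_j \, f(d_{ij}),}
#' with `f` truncated to zero beyond the spec's span. A point with no
#' opportunity inside the span has potential 0; an opportunity co-located
#' with the point contributes its full count (`f(0) = 1`).
#'
#' The computation is vectorized over points in chunks; results are a pure
#' sum and do not depend on chunking or evaluation order beyond floating-point
#' associativity.
#'
#' @param points a two-column matrix or data frame of planar `x`, `y`
#'   coordinates in meters.
#' @param region a [municipality_table()] giving destination coordinates.
#' @param facilities a [facility_table()] of opportunity counts.
#' @param facility_type which facility type to sum over.
#' @param spec an [impedance_spec()].
#' @return numeric vector of potentials, one per point.
#' @examples
#' reg <- municipality_table("a", 0, 0, 100)
#' fac <- facility_table("a", "bakeries", 1)
#' potential_at_points(cbind(0, 0), reg, fac, "bakeries",
#'                     impedance_preset("bakeries"))  # 1
#' @export
potential_at_points <- function(points, region, facilities, facility_type,
                                spec) {
  stopifnot(inherits(spec, "impedance_spec"))
  points <- as.matrix(as.data.frame(points)[, 1:2])
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("point coordinates must be finite")
  opp <- .opportunity_frame(region, facilities, facility_type)
  n <- nrow(points)
  if (nrow(opp) == 0L) return(numeric(n))
  out <- numeric(n)
  # chunked so points x opportunities stays within a modest memory footprint
  chunk <- max(1L, floor(2e7 / nrow(opp)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- outer(points[s:e, 1], opp$x, "-")
    dy <- outer(points[s:e, 2], opp$y, "-")
    w <- impedance_weight(spec, sqrt(dx * dx + dy * dy))
    dim(w) <- dim(dx)
    out[s:e] <- as.numeric(w %*% opp$count)
  }
  out
}

#' Potential accessibility at municipality administrative centres
#'
#' Evaluates [potential_at_points()] at every municipality centre of the
#' region, so that the index can be compared with per-municipality counts or
#' fed to the commuter extension. The self-contribution enters at distance 0,
#' i.e. with full weight.
#'
#' @inheritParams potential_at_points
#' @return named numeric vector of potentials keyed by municipality id.
#' @export
potential_at_municipalities <- function(region, facilities, facility_type,
                                        spec) {
  phi <- potential_at_points(cbind(region$x, region$y), region, facilities,
                             facility_type, spec)
  names(phi) <- region$id
  phi
}

#' Potential accessibility on a regular raster grid
#'
#' Computes the potential index at the centers of a regular grid covering the
#' bounding box of the municipality coordinates expanded by `margin` on all
#' sides. The margin mitigates the border effect: near the study-area edge
#' the index is underestimated because outside opportunities are unobserved,
#' so the analysis grid extends beyond the municipalities themselves.
#' The grid origin is anchored at `(min(x) - margin, min(y) - margin)` and
#' cell `(row, col)` is evaluated at the cell center; row 1 is the
#' northernmost row.
#'
#' @inheritParams potential_at_points
#' @param resolution cell size in meters.
#' @param margin extra distance in meters added around the bounding box.
#' @return an object of class `potential_surface`: a list with `values`
#'   (matrix, row 1 north), `origin_x`, `origin_y` (lower-left corner),
#'   `resolution`, `n_rows`, `n_cols`.
#' @export
potential_grid <- function(region, facilities, facility_type, spec,
                           resolution, margin = 0) {
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0,
            is.numeric(margin), length(margin) == 1L, margin >= 0)
  xll <- min(region$x) - margin
  yll <- min(region$y) - margin
  width <- (max(region$x) + margin) - xll
  height <- (max(region$y) + margin) - yll
  if ((width > 0 && resolution > width) ||
      (height > 0 && resolution > height)) {
    stop("resolution (", resolution, " m) exceeds the buffered bounding box ",
         "extent (", width, " x ", height, " m)")
  }
  n_cols <- max(1L, as.integer(ceiling(width / resolution)))
  n_rows <- max(1L, as.integer(ceiling(height / resolution)))
  cx <- xll + (seq_len(n_cols) - 0.5) * resolution
  cy <- yll + (n_rows - seq_len(n_rows) + 0.5) * resolution  # row 1 north
  centers <- cbind(x = rep(cx, each = n_rows), y = rep(cy, times = n_cols))
  phi <- potential_at_points(centers, region, facilities, facility_type, spec)
  values <- matrix(phi, nrow = n_rows, ncol = n_cols)
  structure(list(values = values, origin_x = xll, origin_y = yll,
                 resolution = resolution, n_rows = n_rows, n_cols = n_cols),
            class = "potential_surface")
}

#' Cell-center coordinates of a potential surface
#'
#' @param surface a `potential_surface`.
#' @return a two-column matrix of `x`, `y` cell-center coordinates in the
#'   storage order of `surface$values` (column-major, row 1 north).
#' @export
surface_centers <- function(surface) {
  stopifnot(inherits(surface, "potential_surface"))
  cx <- surface$origin_x +
    (seq_len(surface$n_cols) - 0.5) * surface$resolution
  cy <- surface$origin_y +
    (surface$n_rows - seq_len(surface$n_rows) + 0.5) * surface$resolution
  cbind(x = rep(cx, each = surface$n_rows),
        y = rep(cy, times = surface$n_cols))
}

#' @export
print.potential_surface <- function(x, ...) {
  cat(sprintf(paste0("Potential surface: %d rows x %d cols at %g m",
                     " (lower-left %g, %g)\n"),
              x$n_rows, x$n_cols, x$resolution, x$origin_x, x$origin_y))
  cat(sprintf("values: min %.4g, max %.4g\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.matrix.potential_surface <- function(x, ...) x$values

#' @export
plot.potential_surface <- function(x, ...) {
  cx <- x$origin_x + (seq_len(x$n_cols) - 0.5) * x$resolution
  cy <- x$origin_y + (seq_len(x$n_rows) - 0.5) * x$resolution
  # image() wants increasing y; flip rows (row 1 is north)
  z <- t(x$values[rev(seq_len(x$n_rows)), , drop = FALSE])
  graphics::image(cx, cy, z, xlab = "x (m)", ylab = "y (m)", asp = 1,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
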