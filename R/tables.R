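#' Validated municipality table
#'
#' Builds the canonical table of aggregated spatial units (municipalities):
#' one row per unit with a unique id, planar projected centroid coordinates in
#' meters, a non-negative population count and an urbanisation class. All
#' downstream computations (distances, potentials, commuter indices) treat the
#' administrative centre coordinates as the location of the whole unit.
#'
#' Coordinates must share one planar projected system in meters; the package
#' performs no geodesic computation (it is built for regional-scale analysis)
#' and does not validate the CRS, which can be carried along as the
#' `crs` attribute for bookkeeping.
#'
#' @param id character vector of unique identifiers.
#' @param x,y numeric planar easting/northing, meters.
#' @param population non-negative integer population counts.
#' @param urbanisation_class one of `"major_pole"`, `"secondary_pole"`,
#'   `"suburban"`, `"rural_under_influence"`, `"rural_outside_influence"`,
#'   `"unknown"` (recycled; defaults to `"unknown"`).
#' @param crs optional free-text CRS label stored as an attribute.
#' @return a `data.frame` of class `municipality_table` with columns
#'   `id`, `x`, `y`, `population`, `urbanisation_class`.
#' @examples
#' municipality_table(c("a", "b"), x = c(0, 3000), y = c(0, 4000),
#'                    population = c(100, 2500))
#' @export
municipality_table <- function(id, x, y, population,
                               urbanisation_class = "unknown",
                               crs = NULL) {
  id <- as.character(id)
  n <- length(id)
  if (n == 0L) stop("municipality table must have at least one row")
  x <- as.numeric(x); y <- as.numeric(y)
  population <- as.numeric(population)
  stopifnot(length(x) == n, length(y) == n, length(population) == n)
  if (anyDuplicated(id)) {
    stop("duplicate municipality ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  bad <- !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    stop("non-finite coordinates for municipality ids: ",
         paste(id[bad], collapse = ", "))
  }
  if (any(!is.finite(population) | population < 0)) {
    stop("population must be finite and non-negative")
  }
  urbanisation_class <- rep_len(as.character(urbanisation_class), n)
  ok <- urbanisation_class %in% .urbanisation_levels
  if (any(!ok)) {
    stop("unknown urbanisation class: ",
         paste(unique(urbanisation_class[!ok]), collapse = ", "))
  }
  out <- data.frame(id = id, x = x, y = y, population = population,
                    urbanisation_class = urbanisation_class,
                    stringsAsFactors = FALSE)
  class(out) <- c("municipality_table", "data.frame")
  attr(out, "crs") <- crs
  out
}

.urbanisation_levels <- c("major_pole", "secondary_pole", "suburban",
                          "rural_under_influence", "rural_outside_influence",
                          "unknown")

#' Facility (opportunity) table
#'
#' One row per (municipality, facility type) pair carrying the count of
#' opportunities of that type located in the municipality. These counts are
#' the opportunity weights `O_j` of the potential index; opportunities are
#' located at the municipality administrative centre (aggregated data).
#'
#' @param municipality_id character vector of municipality ids.
#' @param facility_type character vector of facility type labels.
#' @param count non-negative integer counts.
#' @param region optional `municipality_table`; when given, every
#'   `municipality_id` must resolve against it.
#' @return a `data.frame` of class `facility_table`.
#' @export
facility_table <- function(municipality_id, facility_type, count,
                           region = NULL) {
  municipality_id <- as.character(municipality_id)
  n <- length(municipality_id)
  facility_type <- rep_len(as.character(facility_type), n)
  count <- as.numeric(count)
  stopifnot(length(count) == n)
  if (any(!is.finite(count) | count < 0)) {
    stop("facility counts must be finite and non-negative")
  }
  key <- paste(municipality_id, facility_type, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (municipality_id, facility_type) rows")
  }
  if (!is.null(region)) {
    missing <- setdiff(municipality_id, region$id)
    if (length(missing)) {
      stop("facility rows reference unknown municipalities: ",
           paste(missing, collapse = ", "))
    }
  }
  out <- data.frame(municipality_id = municipality_id,
                    facility_type = facility_type, count = count,
                    stringsAsFactors = FALSE)
  class(out) <- c("facility_table", "data.frame")
  out
}

#' Commuter flow table
#'
#' Origin to destination commuter counts `C_ik`. Per-origin totals `C_i` are
#' recomputed from the rows whenever they are needed, so the table itself is
#' the single source of truth.
#'
#' @param origin_id,destination_id character vectors of municipality ids.
#' @param commuters non-negative integer counts.
#' @return a `data.frame` of class `flow_table`.
#' @export
flow_table <- function(origin_id, destination_id, commuters) {
  origin_id <- as.character(origin_id)
  destination_id <- as.character(destination_id)
  commuters <- as.numeric(commuters)
  n <- length(origin_id)
  stopifnot(length(destination_id) == n, length(commuters) == n)
  if (any(!is.finite(commuters) | commuters < 0)) {
    stop("commuter counts must be finite and non-negative")
  }
  key <- paste(origin_id, destination_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (origin_id, destination_id) rows")
  }
  out <- data.frame(origin_id = origin_id, destination_id = destination_id,
                    commuters = commuters, stringsAsFactors = FALSE)
  class(out) <- c("flow_table", "data.frame")
  out
}

#' Binned trip-length distribution
#'
#' Counts of observed trips by distance bin. Bin `k` covers
#' `(edge[k-1], edge[k]]` with `edge[0] = 0`; upper edges are strictly
#' increasing and in meters.
#'
#' @param bin_upper_edges strictly increasing upper bin edges, meters.
#' @param counts non-negative trip counts per bin; total must be positive.
#' @return an object of class `trip_length_distribution`.
#' @seealso [survival_curve()], [select_span()]
#' @export
trip_length_distribution <- function(bin_upper_edges, counts) {
  bin_upper_edges <- as.numeric(bin_upper_edges)
  counts <- as.numeric(counts)
  if (length(bin_upper_edges) != length(counts)) {
    stop("bin_upper_edges and counts must have the same length")
  }
  if (length(counts) == 0L || sum(counts) <= 0) {
    stop("trip-length distribution must contain at least one trip")
  }
  if (any(!is.finite(bin_upper_edges)) || any(bin_upper_edges <= 0) ||
      any(diff(bin_upper_edges) <= 0)) {
    stop("bin upper edges must be positive, finite and strictly increasing")
  }
  if (any(!is.finite(counts) | counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  structure(list(bin_upper_edges = bin_upper_edges, counts = counts),
            class = "trip_length_distribution")
}

#' @export
print.trip_length_distribution <- function(x, ...) {
  cat("Trip-length distribution:", sum(x$counts), "trips in",
      length(x$counts), "bins up to",
      format(max(x$bin_upper_edges)), "m\n")
  invisible(x)
}

#' Euclidean distance matrix between municipality centres
#'
#' Planar (Euclidean) distances in meters between two sets of points given by
#' their administrative-centre coordinates. At regional scale straight-line
#' distance is a good stand-in for network distance and travel time, which is
#' what makes this cheap metric acceptable for the potential index.
#'
#' @param origins,destinations `municipality_table`s (or data frames with
#'   `id`, `x`, `y` columns). `destinations` defaults to `origins`.
#' @return numeric matrix (meters) with `dimnames` set to the ids; symmetric
#'   with a zero diagonal when `destinations` is `origins`.
#' @examples
#' m <- municipality_table(c("a", "b"), c(0, 3000), c(0, 4000), c(1, 1))
#' distance_matrix(m)  # off-diagonal 5000
#' @export
distance_matrix <- function(origins, destinations = origins) {
  for (tab in list(origins, destinations)) {
    bad <- !is.finite(tab$x) | !is.finite(tab$y)
    if (any(bad)) {
      stop("non-finite coordinates for ids: ",
           paste(tab$id[bad], collapse = ", "))
    }
  }
  dx <- outer(origins$x, destinations$x, "-")
  dy <- outer(origins$y, destinations$y, "-")
  d <- sqrt(dx * dx + dy * dy)
  dimnames(d) <- list(origins$id, destinations$id)
  d
}
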