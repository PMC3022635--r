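#' Commute-length time-budget weighting
#'
#' The commuter extension assumes the time-budget available for an activity
#' (e.g. food shopping) shrinks as the home-work commute grows. The fraction
#' of the budget consumed by a commute of length `d` is
#' \deqn{\gamma(d) = (d / d_{max})^{\theta}, \quad d \le d_{max},}
#' rising from 0 for people living and working in the same place to 1 at the
#' maximum observed commuting distance, beyond which no time is left and the
#' availability factor `1 - gamma` is zero.
#'
#' @param theta exponent `>= 0` linking commute length to lost time-budget;
#'   the default 1 (a linear loss) follows from the near-proportionality of
#'   travel time and straight-line distance at regional scale.
#' @param max_d threshold distance in meters at which the budget is
#'   exhausted; the default 65 km is the maximum commuting distance observed
#'   in the study region the model was developed for.
#' @return an object of class `trip_weight_spec`.
#' @seealso [trip_length_weight()], [commuter_potential()]
#' @export
trip_weight_spec <- function(theta = 1, max_d = 65000) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta),
            theta >= 0,
            is.numeric(max_d), length(max_d) == 1L, is.finite(max_d),
            max_d > 0)
  structure(list(theta = theta, max_d = max_d), class = "trip_weight_spec")
}

#' @export
print.trip_weight_spec <- function(x, ...) {
  cat(sprintf("Trip-length weighting: gamma(d) = (d/%g)^%g, zero budget beyond %g m\n",
              x$max_d, x$theta, x$max_d))
  invisible(x)
}

#' @rdname trip_weight_spec
#' @param spec a `trip_weight_spec`.
#' @param d commute distances in meters, `>= 0`.
#' @return `trip_length_weight`: the consumed budget fraction `gamma(d)` in
#'   `[0, 1]`; distances beyond `max_d` return 1.
#' @examples
#' trip_length_weight(trip_weight_spec(), 32500)  # 0.5
#' @export
trip_length_weight <- function(spec, d) {
  stopifnot(inherits(spec, "trip_weight_spec"))
  d <- as.numeric(d)
  if (any(!is.finite(d) | d < 0)) {
    stop("commute distances must be finite and non-negative")
  }
  (pmin(d, spec$max_d) / spec$max_d)^spec$theta
}

#' Cumulative potential for one home-work pair
#'
#' For a commuter living at `i` and working at `k`, opportunities around both
#' ends are cumulated and the sum discounted by the remaining time-budget:
#' \deqn{\Phi C_{ik} = (\Phi_i + \Phi_k)\,(1 - \gamma(d_{ik})).}
#' When home and work coincide the index is exactly twice the resident
#' potential; at or beyond the threshold distance it is 0 whatever the
#' potentials.
#'
#' @param phi_home,phi_work non-negative resident potentials at the home and
#'   work municipalities (same impedance spec for both ends).
#' @param d_ik commute distance in meters.
#' @param spec a [trip_weight_spec()].
#' @return the pair-level cumulative potential.
#' @examples
#' commuter_pair_potential(3.2, 3.2, 0, trip_weight_spec())  # 6.4
#' @export
commuter_pair_potential <- function(phi_home, phi_work, d_ik, spec) {
  phi_home <- as.numeric(phi_home); phi_work <- as.numeric(phi_work)
  if (any(phi_home < 0) || any(phi_work < 0)) {
    stop("potentials must be non-negative")
  }
  (phi_home + phi_work) * (1 - trip_length_weight(spec, d_ik))
}

#' Flow-averaged commuter potential per municipality
#'
#' Aggregates the pair-level index over all work destinations of each origin,
#' weighting by the share of the origin's commuters working there:
#' \deqn{\Phi C_i = \sum_k \frac{C_{ik}}{C_i} (\Phi_i + \Phi_k)(1 - \gamma(d_{ik})).}
#' Distances are straight-line between administrative centres. Origins with
#' no commuters are reported as `NA` (no commuter-based value exists for
#' them), not as 0.
#'
#' Commuters travelling beyond the threshold `max_d` contribute nothing to
#' the numerator but, by default, stay in the denominator `C_i`: their time
#' budget is exhausted, and removing them would silently inflate the average.
#' Set `long_commutes = "drop"` to exclude them from both. Flows to
#' destinations absent from the region table are an error by default;
#' `external_destinations = "drop"` removes them from numerator and
#' denominator with a count reported in the `n_dropped_flows` attribute
#' (mirroring data situations where out-of-region workplaces are unobserved).
#'
#' @param region a [municipality_table()].
#' @param flows a [flow_table()] of commuter counts.
#' @param phi named vector of resident potentials keyed by municipality id,
#'   as returned by [potential_at_municipalities()].
#' @param spec a [trip_weight_spec()].
#' @param external_destinations `"error"` or `"drop"`.
#' @param long_commutes `"keep"` (default) or `"drop"`.
#' @return named numeric vector of commuter potentials over `region$id`
#'   (`NA` where an origin has no commuters), with attributes
#'   `n_commuters` (named, per-origin totals used as denominators) and
#'   `n_dropped_flows` (rows removed by the external-destination policy).
#' @export
commuter_potential <- function(region, flows, phi, spec,
                               external_destinations = c("error", "drop"),
                               long_commutes = c("keep", "drop")) {
  external_destinations <- match.arg(external_destinations)
  long_commutes <- match.arg(long_commutes)
  stopifnot(inherits(spec, "trip_weight_spec"))
  ids <- region$id
  if (is.null(names(phi)) || !all(ids %in% names(phi))) {
    stop("phi must be named with a potential for every municipality id")
  }
  unknown_o <- setdiff(flows$origin_id, ids)
  if (length(unknown_o)) {
    stop("flows reference unknown origin municipalities: ",
         paste(unknown_o, collapse = ", "))
  }
  unknown_d <- setdiff(flows$destination_id, ids)
  n_dropped <- 0L
  if (length(unknown_d)) {
    if (external_destinations == "error") {
      stop("flows reference unknown destination municipalities: ",
           paste(unknown_d, collapse = ", "))
    }
    drop <- flows$destination_id %in% unknown_d
    n_dropped <- sum(drop)
    message("dropping ", n_dropped,
            " flow rows to destinations outside the region table")
    flows <- flows[!drop, , drop = FALSE]
  }
  oi <- match(flows$origin_id, ids)
  di <- match(flows$destination_id, ids)
  d_ik <- sqrt((region$x[oi] - region$x[di])^2 +
               (region$y[oi] - region$y[di])^2)
  if (long_commutes == "drop") {
    keep <- d_ik <= spec$max_d
    flows <- flows[keep, , drop = FALSE]
    oi <- oi[keep]; di <- di[keep]; d_ik <- d_ik[keep]
  }
  ci <- numeric(length(ids))
  tot <- tapply(flows$commuters, factor(flows$origin_id, levels = ids), sum)
  ci[!is.na(tot)] <- tot[!is.na(tot)]
  pair <- flows$commuters *
    commuter_pair_potential(unname(phi[ids[oi]]), unname(phi[ids[di]]),
                            d_ik, spec)
  num <- numeric(length(ids))
  s <- tapply(pair, factor(flows$origin_id, levels = ids), sum)
  num[!is.na(s)] <- s[!is.na(s)]
  out <- ifelse(ci > 0, num / ci, NA_real_)
  names(out) <- ids
  names(ci) <- ids
  attr(out, "n_commuters") <- ci
  attr(out, "n_dropped_flows") <- n_dropped
  out
}
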