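#' Specification of a synthetic study region
#'
#' Parameters for the synthetic-region generator, whose defaults emulate the
#' structure of a French *departement*-scale study zone: 526 municipalities on
#' a 60 x 80 km rectangle (4800 km^2), a single dominant urban pole plus
#' secondary poles holding the largest populations, log-normal municipal
#' populations (about 86% of municipalities under 2000 inhabitants at the
#' default `meanlog = 6.4`, `sdlog = 1.1`), and per-capita facility
#' intensities that reproduce the strongly zero-inflated counts typical of
#' food-outlet censuses: roughly half the municipalities without a bakery and
#' ~87% without a hyper/supermarket.
#'
#' @param n_municipalities number of municipalities, `>= 2`.
#' @param extent `c(width, height)` of the region rectangle, meters.
#' @param n_poles number of urban poles (first = major pole).
#' @param population_meanlog,population_sdlog log-normal population
#'   parameters.
#' @param facility_intensity named vector of expected facilities per
#'   inhabitant, one entry per facility type.
#' @param commuter_fraction share of the population commuting out for work.
#' @param flow_decay rate of the negative-exponential distance deterrence
#'   used for destination choice in [generate_flows()], per meter.
#' @param seed integer seed making every generator call reproducible.
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(n_municipalities = 526,
                        extent = c(60000, 80000),
                        n_poles = 4,
                        population_meanlog = 6.4,
                        population_sdlog = 1.1,
                        facility_intensity = c(bakeries = 1 / 900,
                                               grocery_stores = 1 / 2000,
                                               hyper_supermarkets = 1 / 7000),
                        commuter_fraction = 0.4,
                        flow_decay = 5e-5,
                        seed = 1L) {
  stopifnot(n_municipalities >= 2, length(extent) == 2L, all(extent > 0),
            n_poles >= 1, n_poles < n_municipalities,
            population_sdlog > 0, all(facility_intensity >= 0),
            !is.null(names(facility_intensity)),
            commuter_fraction >= 0, commuter_fraction <= 1,
            flow_decay >= 0, is.finite(seed))
  structure(list(n_municipalities = as.integer(n_municipalities),
                 extent = as.numeric(extent), n_poles = as.integer(n_poles),
                 population_meanlog = population_meanlog,
                 population_sdlog = population_sdlog,
                 facility_intensity = facility_intensity,
                 commuter_fraction = commuter_fraction,
                 flow_decay = flow_decay, seed = as.integer(seed)),
            class = "region_spec")
}

#' Generate a synthetic region and its facilities
#'
#' Draws municipality coordinates uniformly over the extent (poles placed
#' first), assigns the largest log-normal population draws to the poles, and
#' draws per-type facility counts from a Poisson law with mean
#' `intensity * population` — small rates produce the large zero class seen
#' in real facility censuses for rare outlet types. Urbanisation classes are
#' derived from pole status and distance to the nearest pole (suburban within
#' 10 km, rural under influence within 25 km, rural outside influence
#' beyond). Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [region_spec()].
#' @return a list with components `municipalities` (a
#'   [municipality_table()]) and `facilities` (a [facility_table()]).
#' @export
generate_region <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  set.seed(spec$seed)
  n <- spec$n_municipalities
  x <- stats::runif(n, 0, spec$extent[1])
  y <- stats::runif(n, 0, spec$extent[2])
  pop <- sort(stats::rlnorm(n, spec$population_meanlog,
                            spec$population_sdlog), decreasing = TRUE)
  # poles are drawn first and take the largest populations
  pop_assign <- numeric(n)
  pop_assign[seq_len(spec$n_poles)] <- pop[seq_len(spec$n_poles)]
  pop_assign[-seq_len(spec$n_poles)] <-
    sample(pop[-seq_len(spec$n_poles)])
  pop <- ceiling(pop_assign)
  id <- sprintf("m%03d", seq_len(n))
  pole_d <- sqrt(outer(x, x[seq_len(spec$n_poles)], "-")^2 +
                 outer(y, y[seq_len(spec$n_poles)], "-")^2)
  nearest <- apply(pole_d, 1, min)
  cls <- ifelse(nearest < 10000, "suburban",
                ifelse(nearest < 25000, "rural_under_influence",
                       "rural_outside_influence"))
  cls[1] <- "major_pole"
  if (spec$n_poles > 1) cls[2:spec$n_poles] <- "secondary_pole"
  region <- municipality_table(id, x, y, pop, cls)
  types <- names(spec$facility_intensity)
  fac <- do.call(rbind, lapply(types, function(tp) {
    data.frame(municipality_id = id, facility_type = tp,
               count = stats::rpois(n, spec$facility_intensity[[tp]] * pop),
               stringsAsFactors = FALSE)
  }))
  facilities <- facility_table(fac$municipality_id, fac$facility_type,
                               fac$count, region = region)
  list(municipalities = region, facilities = facilities)
}

#' Generate hub-dominated commuting flows
#'
#' For each origin, the commuter total is a fixed fraction of its population
#' and destinations are drawn from a multinomial with probabilities
#' proportional to `destination_population * exp(-flow_decay * d)` — a
#' gravity-type destination choice that concentrates flows on the large
#' poles, emulating a dominant regional employment centre. Deterministic for
#' a fixed `seed`.
#'
#' @param region a [municipality_table()].
#' @param spec a [region_spec()] (uses `commuter_fraction`, `flow_decay`).
#' @param seed seed; defaults to `spec$seed + 1` so region and flows differ.
#' @return a [flow_table()] (rows with zero commuters omitted).
#' @export
generate_flows <- function(region, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "region_spec"))
  set.seed(seed)
  d <- distance_matrix(region)
  w <- region$population * exp(-spec$flow_decay * d)  # column k weight pop_k
  totals <- round(spec$commuter_fraction * region$population)
  rows <- vector("list", nrow(region))
  for (i in seq_len(nrow(region))) {
    if (totals[i] <= 0) next
    prob <- region$population * exp(-spec$flow_decay * d[i, ])
    cnt <- as.integer(stats::rmultinom(1, totals[i], prob))
    keep <- cnt > 0
    if (!any(keep)) next
    rows[[i]] <- data.frame(origin_id = region$id[i],
                            destination_id = region$id[keep],
                            commuters = cnt[keep],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no commuters generated; raise commuter_fraction")
  flow_table(out$origin_id, out$destination_id, out$commuters)
}

#' Generate a binned trip-length sample from a destination-choice model
#'
#' Samples shopping trips under the behavioural reading of the potential
#' model: origin municipalities are drawn proportionally to population and,
#' conditional on the origin, a destination is drawn with probability
#' proportional to `O_j * f(d_ij)` where `O_j` is the opportunity count and
#' `f` the impedance function. Euclidean trip lengths are recorded and binned
#' (a zero-length trip falls in the first bin). As `n_trips` grows, the
#' survival curve of the output converges to a mixture over origins governed
#' by `f` and the spatial arrangement of opportunities, so calibrating on it
#' is a parameter-recovery experiment whose fidelity depends on the geometry
#' (see the package vignette on the spatial-structure effect).
#'
#' @param region a [municipality_table()].
#' @param facilities a [facility_table()].
#' @param facility_type which opportunity type trips are made for.
#' @param spec an [impedance_spec()] used as the destination-choice decay.
#' @param n_trips number of trips to sample, `>= 1`.
#' @param bin_width bin width in meters, `> 0`.
#' @param seed integer seed.
#' @return a [trip_length_distribution()].
#' @export
generate_trips <- function(region, facilities, facility_type, spec,
                           n_trips, bin_width = 1000, seed = 1L) {
  stopifnot(inherits(spec, "impedance_spec"), n_trips >= 1, bin_width > 0)
  opp <- .opportunity_frame(region, facilities, facility_type)
  if (nrow(opp) == 0L) {
    stop("region has no opportunities of type '", facility_type, "'")
  }
  if (all(region$population <= 0)) {
    stop("region has no population to originate trips")
  }
  set.seed(seed)
  origin_draws <- sample.int(nrow(region), n_trips, replace = TRUE,
                             prob = region$population)
  per_origin <- tabulate(origin_draws, nbins = nrow(region))
  max_bin <- 0L
  bin_counts <- integer(0)
  for (i in which(per_origin > 0L)) {
    d <- sqrt((region$x[i] - opp$x)^2 + (region$y[i] - opp$y)^2)
    prob <- opp$count * impedance_weight(spec, d)
    if (sum(prob) <= 0) {
      stop("origin ", region$id[i], " has zero choice probability for all ",
           "destinations (span too small?)")
    }
    cnt <- as.integer(stats::rmultinom(1, per_origin[i], prob))
    bins <- pmax(1L, as.integer(ceiling(d / bin_width)))
    need <- max(bins)
    if (need > max_bin) {
      bin_counts <- c(bin_counts, integer(need - max_bin))
      max_bin <- need
    }
    add <- vapply(split(cnt, bins), sum, numeric(1))
    idx <- as.integer(names(add))
    bin_counts[idx] <- bin_counts[idx] + add
  }
  trip_length_distribution(seq_len(max_bin) * bin_width, bin_counts)
}
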