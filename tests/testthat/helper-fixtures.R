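# Fixtures and independent scalar oracles used across the suite.
# Oracles are deliberately naive (double loops) so they stay independent of
# the vectorized implementations they check.

make_region <- function(n, seed = 1, extent = c(40000, 40000)) {
  set.seed(seed)
  municipality_table(
    id = sprintf("m%02d", seq_len(n)),
    x = runif(n, 0, extent[1]),
    y = runif(n, 0, extent[2]),
    population = rpois(n, 800))
}

make_facilities <- function(region, type = "shops", seed = 2,
                            lambda = 1.5) {
  set.seed(seed)
  facility_table(region$id, type, rpois(nrow(region), lambda),
                 region = region)
}

# scalar double-loop potential, Eq-by-eq transliteration
oracle_potential <- function(points, region, facilities, facility_type,
                             spec) {
  f <- facilities[facilities$facility_type == facility_type, ]
  sapply(seq_len(nrow(points)), function(i) {
    tot <- 0
    for (r in seq_len(nrow(f))) {
      j <- match(f$municipality_id[r], region$id)
      d <- sqrt((points[i, 1] - region$x[j])^2 +
                (points[i, 2] - region$y[j])^2)
      w <- impedance_weight(spec, d)
      tot <- tot + f$count[r] * w
    }
    tot
  })
}

# scalar double-loop commuter potential
oracle_commuter <- function(region, flows, phi, tw) {
  out <- rep(NA_real_, nrow(region))
  names(out) <- region$id
  for (i in seq_len(nrow(region))) {
    rows <- which(flows$origin_id == region$id[i])
    ci <- sum(flows$commuters[rows])
    if (ci <= 0) next
    acc <- 0
    for (r in rows) {
      k <- match(flows$destination_id[r], region$id)
      d <- sqrt((region$x[i] - region$x[k])^2 +
                (region$y[i] - region$y[k])^2)
      g <- (min(d, tw$max_d) / tw$max_d)^tw$theta
      acc <- acc + (flows$commuters[r] / ci) *
        (phi[region$id[i]] + phi[region$id[k]]) * (1 - g)
    }
    out[i] <- acc
  }
  out
}

ge_spec <- function(alpha = 2.14e-6, beta = 1.6, span = NULL) {
  impedance_spec("generalized_exponential", alpha = alpha, beta = beta,
                 span = span)
}

# survival curve taken straight from a known decay, bypassing binning
exact_curve <- function(alpha, beta, d = seq(1000, 20000, by = 1000)) {
  structure(list(distances = c(0, d),
                 probabilities = c(1, exp(-alpha * d^beta))),
            class = "survival_curve")
}

# Parameter-recovery geometry: one populated origin, opportunity-bearing
# destinations at near-continuous graded distances with radial density
# r^(beta-1), which cancels the spatial-structure effect so the trip-length
# survival curve follows the generating decay family by construction.
recovery_region <- function(n_dest = 400, radius = 20000, beta = 1.6) {
  u <- (seq_len(n_dest) - 0.5) / n_dest
  r <- radius * u^(1 / beta)
  th <- (seq_len(n_dest) - 1) * 2 * pi * 0.381966  # golden-angle spread
  region <- municipality_table(
    id = c("origin", sprintf("d%03d", seq_len(n_dest))),
    x = c(0, r * cos(th)), y = c(0, r * sin(th)),
    population = c(1000, rep(0, n_dest)))
  facilities <- facility_table(region$id, "shops",
                               c(0, rep(1, n_dest)), region = region)
  list(municipalities = region, facilities = facilities)
}

write_smoke_config <- function(dir, n = 50, resolution = 500) {
  cfgp <- file.path(dir, "run.yaml")
  writeLines(c(
    "seed: 11",
    "simulate:",
    sprintf("  n_municipalities: %d", n),
    "  extent: [15000, 15000]",
    "  n_poles: 2",
    "  n_trips: 5000",
    "inputs:",
    sprintf("  municipalities: %s/municipalities.csv", dir),
    sprintf("  facilities: %s/facilities.csv", dir),
    sprintf("  flows: %s/flows.csv", dir),
    sprintf("  trips: %s/trips.csv", dir),
    "facility_type: bakeries",
    "impedance:",
    "  preset: bakeries",
    "grid:",
    sprintf("  resolution: %d", resolution),
    "  margin: 1000",
    "commuter:",
    "  theta: 1",
    "  max_d: 65000",
    "outputs:",
    sprintf("  dir: %s", dir)), cfgp)
  cfgp
}
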