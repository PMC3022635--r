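test_that("time-budget weight hits its anchor points", {
  tw <- trip_weight_spec(theta = 1, max_d = 65000)
  expect_equal(trip_length_weight(tw, 0), 0)
  expect_equal(trip_length_weight(tw, 65000), 1)
  expect_equal(trip_length_weight(tw, 32500), 0.5)
  expect_equal(trip_length_weight(tw, 100000), 1)  # beyond the threshold
  expect_error(trip_length_weight(tw, -1), "non-negative")
  # theta = 1 is linear in d up to the threshold
  d <- seq(0, 65000, by = 5000)
  expect_equal(trip_length_weight(tw, d), d / 65000)
  tw2 <- trip_weight_spec(theta = 2, max_d = 10000)
  expect_equal(trip_length_weight(tw2, 5000), 0.25)
})

test_that("pair potential doubles at coincidence and dies at the threshold", {
  tw <- trip_weight_spec()
  expect_equal(commuter_pair_potential(3.2, 3.2, 0, tw), 6.4)
  expect_equal(commuter_pair_potential(7, 9, 65000, tw), 0)
  tw10 <- trip_weight_spec(theta = 1, max_d = 10000)
  expect_equal(commuter_pair_potential(1, 2, 2500, tw10), 2.25)
  expect_error(commuter_pair_potential(-1, 0, 0, tw), "non-negative")
})

test_that("all-commuters-at-home gives twice the resident potential", {
  reg <- make_region(5, seed = 20)
  phi <- c(m01 = 1.5, m02 = 2, m03 = 0.5, m04 = 3, m05 = 0)
  flows <- flow_table(reg$id, reg$id, rep(10, 5))
  phic <- commuter_potential(reg, flows, phi, trip_weight_spec())
  expect_equal(unname(phic), unname(2 * phi), ignore_attr = TRUE)
})

test_that("destinations at or beyond the threshold contribute nothing", {
  reg <- municipality_table(c("o", "d1", "d2"), c(0, 70000, 0),
                            c(0, 0, 70000), c(100, 100, 100))
  phi <- c(o = 2, d1 = 5, d2 = 5)
  flows <- flow_table(c("o", "o"), c("d1", "d2"), c(10, 10))
  phic <- commuter_potential(reg, flows, phi, trip_weight_spec())
  expect_equal(unname(phic["o"]), 0)
  # dropping long commutes leaves the origin with no denominator at all
  phic2 <- commuter_potential(reg, flows, phi, trip_weight_spec(),
                              long_commutes = "drop")
  expect_true(is.na(phic2["o"]))
})

test_that("flow-averaged commuter potential matches the scalar oracle", {
  reg <- make_region(20, seed = 21)
  fac <- make_facilities(reg, seed = 22)
  spec <- ge_spec(2.14e-6, 1.6, span = 12000)
  phi <- potential_at_municipalities(reg, fac, "shops", spec)
  set.seed(23)
  pairs <- expand.grid(origin_id = reg$id, destination_id = reg$id,
                       stringsAsFactors = FALSE)
  pairs <- pairs[sample.int(nrow(pairs), 60), ]
  flows <- flow_table(pairs$origin_id, pairs$destination_id,
                      rpois(60, 20))
  tw <- trip_weight_spec(theta = 1, max_d = 30000)
  phic <- commuter_potential(reg, flows, phi, tw)
  expect_equal(phic, oracle_commuter(reg, flows, phi, tw),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_named(phic, reg$id)
})

test_that("commuter potential respects its structural bounds", {
  reg <- make_region(15, seed = 24)
  fac <- make_facilities(reg, seed = 25)
  spec <- ge_spec(2.14e-6, 1.6, span = 12000)
  phi <- potential_at_municipalities(reg, fac, "shops", spec)
  set.seed(26)
  flows <- flow_table(rep(reg$id, each = 3),
                      unlist(lapply(seq_len(15), function(i)
                        sample(reg$id, 3))),
                      rpois(45, 15) + 1)
  tw <- trip_weight_spec()
  phic <- commuter_potential(reg, flows, phi, tw)
  ok <- !is.na(phic)
  expect_true(all(phic[ok] >= 0))
  expect_true(all(phic[ok] <= 2 * max(phi) + 1e-12))
  # flow weights are convex: per-origin shares sum to one
  ci <- attr(phic, "n_commuters")
  shares <- tapply(flows$commuters, flows$origin_id, sum)
  expect_equal(as.numeric(ci[names(shares)]), as.numeric(shares))
})

test_that("longer commutes never raise the index, linearly when theta = 1", {
  tw <- trip_weight_spec(theta = 1, max_d = 65000)
  phi <- c(home = 4, work = 6)
  d <- seq(0, 80000, by = 2000)
  v <- commuter_pair_potential(phi["home"], phi["work"], d, tw)
  expect_true(all(diff(v) <= 1e-12))
  inside <- d <= 65000
  expect_equal(unname(v[inside]), 10 * (1 - d[inside] / 65000))
  # origin-level: single destination at growing distance
  reg_at <- function(dd) municipality_table(c("o", "k"), c(0, dd), c(0, 0),
                                            c(10, 10))
  vals <- sapply(c(0, 10000, 30000, 64000), function(dd) {
    commuter_potential(reg_at(dd), flow_table("o", "k", 5),
                       c(o = 1, k = 2), tw)[["o"]]
  })
  expect_true(all(diff(vals) < 0))
})

test_that("unknown flow ids and origins without commuters are handled", {
  reg <- make_region(4, seed = 27)
  phi <- setNames(rep(1, 4), reg$id)
  bad_o <- flow_table("ghost", reg$id[1], 5)
  expect_error(commuter_potential(reg, bad_o, phi, trip_weight_spec()),
               "ghost")
  bad_d <- flow_table(reg$id[1], "ghost", 5)
  expect_error(commuter_potential(reg, bad_d, phi, trip_weight_spec()),
               "ghost")
  # drop policy removes external destinations but reports them
  mixed <- flow_table(c(reg$id[1], reg$id[1]), c(reg$id[2], "ghost"),
                      c(4, 6))
  expect_message(
    phic <- commuter_potential(reg, mixed, phi, trip_weight_spec(),
                               external_destinations = "drop"),
    "1 flow rows")
  expect_equal(attr(phic, "n_dropped_flows"), 1L)
  expect_equal(unname(attr(phic, "n_commuters")[reg$id[1]]), 4)
  # origins with no flows have no commuter value, flagged NA not 0
  expect_true(is.na(phic[reg$id[3]]))
})
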