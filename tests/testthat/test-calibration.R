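test_that("survival curve is one minus the empirical CDF at bin edges", {
  # half the trips exceed 1 km
  sc <- survival_curve(trip_length_distribution(c(1000, 2000), c(5, 5)))
  expect_equal(sc$distances, c(0, 1000))
  expect_equal(sc$probabilities, c(1, 0.5))
  # all trips within the first bin: zero tail dropped, anchor kept
  sc1 <- survival_curve(trip_length_distribution(1000, 10))
  expect_equal(sc1$distances, 0)
  expect_equal(sc1$probabilities, 1)
  # direct counting oracle on a random sample
  set.seed(7)
  lengths <- rgamma(5000, shape = 2, scale = 3000)
  edges <- seq(1000, ceiling(max(lengths) / 1000) * 1000, by = 1000)
  counts <- table(cut(lengths, c(0, edges)))
  sc2 <- survival_curve(trip_length_distribution(edges, as.numeric(counts)))
  for (k in seq_along(sc2$distances)) {
    expect_equal(sc2$probabilities[k],
                 mean(lengths > sc2$distances[k]), tolerance = 1e-12)
  }
  expect_true(all(diff(sc2$probabilities) <= 0))
  expect_true(all(sc2$probabilities > 0 & sc2$probabilities <= 1))
})

test_that("log-linear grid fit recovers noiseless parameters exactly", {
  fit <- fit_impedance(exact_curve(1e-6, 1.6), method = "loglinear")
  expect_equal(fit$beta, 1.6)
  expect_equal(fit$alpha, 1e-6, tolerance = 1e-10)
  expect_lt(fit$see, 1e-10)
  expect_equal(fit$method, "loglinear_grid")
  expect_equal(nrow(fit$profile), length(seq(0.5, 3, by = 0.05)))
})

test_that("flat and degenerate curves are rejected", {
  flat <- structure(list(distances = c(0, 1000, 2000),
                         probabilities = c(1, 1, 1)),
                    class = "survival_curve")
  expect_error(fit_impedance(flat), "unidentifiable")
  one <- structure(list(distances = c(0, 1000),
                        probabilities = c(1, 0.4)),
                   class = "survival_curve")
  expect_error(fit_impedance(one), "at least two")
})

test_that("noisy curves are recovered within 5% in the median", {
  errs <- sapply(1:12, function(seed) {
    set.seed(seed)
    d <- seq(1000, 20000, by = 1000)
    p <- pmin(exp(-1.2e-6 * d^1.6) * exp(rnorm(length(d), 0, 0.02)), 1)
    sc <- structure(list(distances = c(0, d), probabilities = c(1, p)),
                    class = "survival_curve")
    fit <- fit_impedance(sc, beta_grid = seq(0.5, 3, by = 0.01))
    c(abs(fit$alpha - 1.2e-6) / 1.2e-6, abs(fit$beta - 1.6) / 1.6)
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("nonlinear fit recovers a zero-residual construction", {
  curve <- exact_curve(2e-6, 1.4)
  fit <- fit_impedance(curve, method = "nonlinear", init = c(1e-6, 1))
  expect_equal(fit$alpha, 2e-6, tolerance = 1e-6)
  expect_equal(fit$beta, 1.4, tolerance = 1e-6)
  expect_true(fit$convergence$converged)
  expect_equal(predict(fit, curve$distances), curve$probabilities,
               tolerance = 1e-8)
})

test_that("nonlinear fit defaults to the log-linear solution as init", {
  set.seed(11)
  d <- seq(1000, 20000, by = 1000)
  p <- pmin(exp(-1e-6 * d^1.6) * exp(rnorm(length(d), 0, 0.05)), 1)
  sc <- structure(list(distances = c(0, d), probabilities = c(1, p)),
                  class = "survival_curve")
  ll <- fit_impedance(sc, method = "loglinear")
  nl <- fit_impedance(sc, method = "nonlinear")
  expect_true(nl$convergence$converged)
  # both methods agree on noiseless data
  nl0 <- fit_impedance(exact_curve(1e-6, 1.6), method = "nonlinear")
  ll0 <- fit_impedance(exact_curve(1e-6, 1.6), method = "loglinear")
  expect_equal(coef(nl0), coef(ll0), tolerance = 1e-5)
  expect_error(fit_impedance(sc, method = "nonlinear", init = c(1, -2)),
               "beta > 0")
})

test_that("fit methods expose the usual model-object surface", {
  fit <- fit_impedance(exact_curve(1e-6, 1.6))
  expect_named(coef(fit), c("alpha", "beta"))
  expect_equal(length(residuals(fit)), length(fit$curve$distances))
  expect_lt(max(abs(residuals(fit))), 1e-12)
  spec <- as_impedance_spec(fit, span = 19000)
  expect_s3_class(spec, "impedance_spec")
  expect_equal(spec$span, 19000)
  expect_output(print(fit), "alpha")
  expect_output(summary(fit), "beta grid")
})

test_that("span rule rounds the last observed distance up to the km", {
  expect_equal(select_span(trip_length_distribution(
    c(17200, 18200), c(4, 1))), 19000)
  expect_equal(select_span(trip_length_distribution(
    c(11000, 12000), c(3, 2))), 12000)
  # trailing empty bins do not extend the observed maximum
  expect_equal(select_span(trip_length_distribution(
    c(11000, 12000, 13000), c(3, 2, 0))), 12000)
})
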