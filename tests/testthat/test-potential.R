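test_that("potential at a co-located opportunity is the raw count", {
  reg <- municipality_table("a", 1000, 2000, 50)
  fac <- facility_table("a", "shops", 1)
  spec <- ge_spec(2.14e-6, 1.6)
  expect_equal(potential_at_points(cbind(1000, 2000), reg, fac, "shops",
                                   spec), 1)
  # beyond the span nothing contributes
  hyper <- ge_spec(1.156e-6, 1.6, span = 19000)
  expect_equal(potential_at_points(cbind(1000 + 25000, 2000), reg, fac,
                                   "shops", hyper), 0)
})

test_that("unknown facility types are rejected with the available list", {
  reg <- make_region(3)
  fac <- make_facilities(reg, type = "bakeries")
  expect_error(potential_at_points(cbind(0, 0), reg, fac, "pharmacies",
                                   ge_spec()),
               "bakeries")
})

test_that("vectorized potential equals the naive double loop", {
  reg <- make_region(30, seed = 5)
  fac <- make_facilities(reg, seed = 6)
  spec <- ge_spec(1.156e-6, 1.6, span = 19000)
  set.seed(9)
  pts <- cbind(runif(5, 0, 40000), runif(5, 0, 40000))
  expect_equal(potential_at_points(pts, reg, fac, "shops", spec),
               oracle_potential(pts, reg, fac, "shops", spec),
               tolerance = 1e-9)
  # per-municipality variant, 50 municipalities
  reg2 <- make_region(50, seed = 7)
  fac2 <- make_facilities(reg2, seed = 8)
  phi <- potential_at_municipalities(reg2, fac2, "shops", spec)
  expect_named(phi, reg2$id)
  expect_equal(unname(phi),
               oracle_potential(cbind(reg2$x, reg2$y), reg2, fac2, "shops",
                                spec),
               tolerance = 1e-9)
})

test_that("an isolated municipality keeps only its own opportunities", {
  reg <- municipality_table(c("a", "b"), c(0, 30000), c(0, 0), c(10, 10))
  fac <- facility_table(c("a", "b"), c("shops", "shops"), c(3, 0))
  spec <- ge_spec(1.156e-6, 1.6, span = 19000)
  phi <- potential_at_municipalities(reg, fac, "shops", spec)
  expect_equal(unname(phi), c(3, 0))
})

test_that("potential is additive and homogeneous in opportunity counts", {
  reg <- make_region(20, seed = 3)
  spec <- ge_spec(2.14e-6, 1.6, span = 12000)
  set.seed(4)
  c1 <- rpois(20, 1); c2 <- rpois(20, 2)
  f1 <- facility_table(reg$id, "shops", c1)
  f2 <- facility_table(reg$id, "shops", c2)
  fsum <- facility_table(reg$id, "shops", c1 + c2)
  pts <- cbind(runif(4, 0, 40000), runif(4, 0, 40000))
  expect_equal(potential_at_points(pts, reg, f1, "shops", spec) +
                 potential_at_points(pts, reg, f2, "shops", spec),
               potential_at_points(pts, reg, fsum, "shops", spec),
               tolerance = 1e-12)
  f3 <- facility_table(reg$id, "shops", 3 * c1)
  expect_equal(potential_at_points(pts, reg, f3, "shops", spec),
               3 * potential_at_points(pts, reg, f1, "shops", spec),
               tolerance = 1e-12)
  # adding an opportunity within span never decreases any potential
  fplus <- facility_table(reg$id, "shops", c1 + c(1, rep(0, 19)))
  expect_true(all(potential_at_points(pts, reg, fplus, "shops", spec) >=
                    potential_at_points(pts, reg, f1, "shops", spec)))
})

test_that("span truncation only removes mass and vanishes as span grows", {
  reg <- make_region(25, seed = 10)
  fac <- make_facilities(reg, seed = 11)
  pts <- cbind(runif(6, 0, 40000), runif(6, 0, 40000))
  full <- potential_at_points(pts, reg, fac, "shops", ge_spec())
  for (span in c(5000, 15000, 40000)) {
    trunc <- potential_at_points(pts, reg, fac, "shops",
                                 ge_spec(span = span))
    expect_true(all(trunc <= full + 1e-12))
  }
  wide <- potential_at_points(pts, reg, fac, "shops",
                              ge_spec(span = 1e7))
  expect_equal(wide, full, tolerance = 1e-12)
})

test_that("grid values equal point potentials at cell centers", {
  reg <- make_region(15, seed = 12, extent = c(10000, 8000))
  fac <- make_facilities(reg, seed = 13)
  spec <- ge_spec(2.14e-6, 1.6, span = 12000)
  surf <- potential_grid(reg, fac, "shops", spec, resolution = 1000,
                         margin = 2000)
  centers <- surface_centers(surf)
  expect_equal(as.numeric(surf$values),
               potential_at_points(centers, reg, fac, "shops", spec))
  expect_equal(as.numeric(surf$values),
               oracle_potential(centers, reg, fac, "shops", spec),
               tolerance = 1e-9)
  # geometry: buffered bounding box, ceil-divided
  expect_equal(surf$origin_x, min(reg$x) - 2000)
  expect_equal(surf$n_cols,
               ceiling((diff(range(reg$x)) + 4000) / 1000))
  expect_true(all(surf$values >= 0) && all(is.finite(surf$values)))
})

test_that("coarser aligned grids reproduce finer-grid values", {
  reg <- municipality_table(c("a", "b"), c(0, 8000), c(0, 6000), c(5, 5))
  fac <- facility_table(c("a", "b"), c("shops", "shops"), c(2, 1))
  spec <- ge_spec(2.14e-6, 1.6)
  fine <- potential_grid(reg, fac, "shops", spec, resolution = 1000)
  coarse <- potential_grid(reg, fac, "shops", spec, resolution = 3000)
  fc <- surface_centers(fine); cc <- surface_centers(coarse)
  keyf <- paste(fc[, 1], fc[, 2]); keyc <- paste(cc[, 1], cc[, 2])
  shared <- intersect(keyf, keyc)
  expect_gt(length(shared), 0)
  expect_equal(as.numeric(coarse$values)[match(shared, keyc)],
               as.numeric(fine$values)[match(shared, keyf)])
})

test_that("degenerate and invalid grids are handled", {
  reg <- municipality_table("a", 500, 500, 10)
  fac <- facility_table("a", "shops", 4)
  spec <- ge_spec(2.14e-6, 1.6)
  one <- potential_grid(reg, fac, "shops", spec, resolution = 100,
                        margin = 0)
  expect_equal(dim(one$values), c(1L, 1L))
  expect_equal(as.numeric(one$values),
               potential_at_points(surface_centers(one), reg, fac, "shops",
                                   spec))
  reg2 <- municipality_table(c("a", "b"), c(0, 3000), c(0, 3000), c(1, 1))
  fac2 <- facility_table(c("a", "b"), c("shops", "shops"), c(1, 1))
  expect_error(potential_grid(reg2, fac2, "shops", spec, resolution = 5000),
               "exceeds")
})
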