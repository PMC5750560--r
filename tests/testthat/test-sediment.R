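test_that("dissolved fraction follows the partitioning closed form", {
  expect_equal(dissolved_fraction(100, 0, 0.05), 100)       # no sorption
  expect_equal(dissolved_fraction(100, 2e4, 0.05), 50)      # kd*1e-3*S = 1
  expect_equal(dissolved_fraction(90, 1e4, 0.05), 90 / 1.5) # factor 0.667
  expect_error(dissolved_fraction(-1, 10, 0.05), "non-negative")
  # never exceeds the total
  kd <- sample_dist(dist_lognormal(5000, 3), 200, seed = 2)
  expect_true(all(dissolved_fraction(100, kd, 0.05) <= 100))
})

test_that("build-up factor matches its closed form and integral definition", {
  # closed form for Co-60 over 30 years: (1 - 2^(-30/5.27)) / (ln2*30/5.27)
  r <- 30 / 5.27
  expect_equal(buildup_factor(co60$decay_constant, 30),
               (1 - 2^(-r)) / (log(2) * r), tolerance = 1e-12)
  expect_equal(buildup_factor(co60$decay_constant, 30), 0.247,
               tolerance = 0.01)

  # numerical oracle: (1/T) integral_0^T exp(-lambda t) dt
  for (nuc in tiny_db) {
    Ts <- 30 * 3.1536e7
    num <- stats::integrate(function(t) exp(-nuc$decay_constant * t),
                            0, Ts, rel.tol = 1e-13)$value / Ts
    expect_equal(buildup_factor(nuc$decay_constant, 30), num,
                 tolerance = 1e-10)
  }

  # long-lived limit and small-argument stability
  expect_equal(buildup_factor(0, 30), 1)
  expect_equal(buildup_factor(1e-20, 30), 1, tolerance = 1e-10)
  # monotone decreasing in lambda
  lams <- 10^seq(-12, -7, length.out = 20)
  bs <- vapply(lams, buildup_factor, 0, time_y = 30)
  expect_true(all(diff(bs) < 0))
})

test_that("bottom-sediment concentration composes Kd, top layer and build-up", {
  p <- sediment_params(dist_point(5000))
  B <- buildup_factor(co60$decay_constant, 30)
  expect_equal(bottom_sediment_concentration(100, co60, p),
               0.1 * 5000 * 1e-3 * 100 * B)
  expect_equal(bottom_sediment_concentration(0, co60, p), 0)

  # monotone increasing in Kd; decreasing in lambda
  c1 <- bottom_sediment_concentration(100, co60, p, kd = 1000)
  c2 <- bottom_sediment_concentration(100, co60, p, kd = 2000)
  expect_gt(c2, c1)
  expect_gt(bottom_sediment_concentration(100, cs137, p),
            bottom_sediment_concentration(100, co60, p))
})

test_that("suspended load can only reduce the sediment concentration", {
  p <- sediment_params(dist_point(5000), suspended_load_kg_m3 = 0.05)
  with_load <- bottom_sediment_concentration(
    dissolved_fraction(100, 5000, 0.05), co60, p)
  no_load <- bottom_sediment_concentration(100, co60, p)
  expect_lte(with_load, no_load)
})
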