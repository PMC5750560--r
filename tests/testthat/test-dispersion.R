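lake <- reservoir_scenario(2e6, 0.1)
river <- river_scenario(40, 0.8, 0.2)
coast <- coast_scenario(1, 0.1)

test_that("scenario constructors enforce their invariants", {
  expect_error(reservoir_scenario(-1, 1), "positive")
  expect_error(river_scenario(40, 0.8, 0.2, flow_m3_s = 10),
               "inconsistent")
  expect_silent(river_scenario(40, 0.8, 0.2, flow_m3_s = 6.5))
  expect_error(coast_scenario(1, 0.1, release_offshore_m = -5), ">= 0")
})

test_that("all three models are linear (degree-1 homogeneous) in Q", {
  for (fun in list(
    function(Q) lake_concentration(Q, co60, lake),
    function(Q) river_concentration(Q, co60, river, 500, TRUE),
    function(Q) coastal_concentration(Q, co60, coast, 1000, 100))) {
    expect_equal(fun(108), 2 * fun(54))
    expect_equal(fun(0), 0)
  }
})

test_that("lake box model reduces to Q/outflow without decay and is homogeneous", {
  expect_equal(lake_concentration(54, 0, lake), 54 / 0.1)
  # no receptor dependence is possible: the model has no receptor argument
  expect_equal(lake_concentration(54, co60, lake),
               54 / (0.1 + co60$decay_constant * 2e6))
})

test_that("lake equilibrium matches the long-time ODE solution", {
  skip_if_not_installed("deSolve")
  # independent oracle: V dC/dt = Q - (outflow + lambda V) C, integrated out
  Q <- 54; V <- 2e6; q <- 0.1; lam <- co60$decay_constant
  out <- deSolve::ode(c(C = 0), times = c(0, 5e9),
                      function(t, y, p) list(Q / V - (q / V + lam) * y[1]))
  expect_equal(unname(out[2, "C"]),
               lake_concentration(Q, co60, lake), tolerance = 1e-6)
})

test_that("river model handles shores, mixing distance and decay limits", {
  L <- mixing_length(river)
  expect_equal(L, 7 * 40^2 / 0.8)   # 14,000 m

  # fully mixed, no decay: Q/flow regardless of shore
  xs <- L * c(1, 1.5)
  for (x in xs) {
    expect_equal(river_concentration(54, 0, river, x, TRUE),
                 54 / river$flow_m3_s, tolerance = 1e-12)
    expect_equal(river_concentration(54, 0, river, x, FALSE),
                 54 / river$flow_m3_s, tolerance = 1e-12)
  }

  # same shore >= opposite shore before L; ratio is sqrt(L/x)
  same <- river_concentration(54, co60, river, 500, TRUE)
  opp <- river_concentration(54, co60, river, 500, FALSE)
  expect_gt(same, opp)
  expect_equal(same / opp, sqrt(L / 500))

  # opposite-shore concentrations at 500 m and 2000 m agree when transit
  # decay is negligible relative to the Co-60 half-life
  expect_equal(river_concentration(54, co60, river, 500, FALSE),
               river_concentration(54, co60, river, 2000, FALSE),
               tolerance = 1e-3)

  # monotone non-increasing in distance at fixed shore
  d <- seq(100, 2 * L, length.out = 50)
  cs <- vapply(d, function(x) river_concentration(54, co60, river, x, TRUE),
               0)
  expect_true(all(diff(cs) <= 1e-12))

  expect_error(river_concentration(54, co60, river, 0), "not applicable")
})

test_that("same-shore partial mixing factor is continuous at L", {
  L <- mixing_length(river)
  just_below <- river_concentration(54, 0, river, L * (1 - 1e-9), TRUE)
  at_L <- river_concentration(54, 0, river, L, TRUE)
  expect_lt(abs(just_below - at_L) / at_L, 1e-6)
})

test_that("coastal plume behaves across the receptor grid", {
  # shoreline receptor, no decay: monotone decreasing alongshore
  xs <- seq(100, 10000, length.out = 40)
  cs <- vapply(xs,
               function(x) coastal_concentration(54, 0, coast, x, 0), 0)
  expect_true(all(diff(cs) < 0))
  expect_true(all(cs > 0) && all(is.finite(cs)))

  expect_error(coastal_concentration(54, co60, coast, -10, 0),
               "down-current")

  # offshore release doubles up by reflection at y = 0 only when y0 = 0
  off <- coast_scenario(1, 0.1, release_offshore_m = 200)
  expect_lt(coastal_concentration(54, 0, off, 1000, 0),
            coastal_concentration(54, 0, coast, 1000, 0))
})

test_that("a stable tracer never yields less than a decaying nuclide", {
  for (pair in list(
    c(lake_concentration(54, 0, lake), lake_concentration(54, co60, lake)),
    c(river_concentration(54, 0, river, 3000, TRUE),
      river_concentration(54, co60, river, 3000, TRUE)),
    c(coastal_concentration(54, 0, coast, 2000, 100),
      coastal_concentration(54, co60, coast, 2000, 100))))
    expect_gte(pair[1], pair[2])
})
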