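test_that("triangular fit takes series min/mean/max as parameters", {
  st <- fit_triangular_source(almaraz_co60_series)
  expect_identical(st$release_rate$kind, "triangular")
  expect_equal(st$release_rate$min, 39)
  expect_equal(st$release_rate$mode, 54)   # series mean as central value
  expect_equal(st$release_rate$max, 66)

  # river Sr-90 block: min 8, mean 21, max 51
  s2 <- discharge_series("Asco", "Sr-90", c(8, 13, 16, 17, 51))
  st2 <- fit_triangular_source(s2)
  expect_equal(c(st2$release_rate$min, st2$release_rate$mode,
                 st2$release_rate$max), c(8, 21, 51))
})

test_that("match_mean convention makes the distribution mean equal the series mean", {
  st <- fit_triangular_source(almaraz_co60_series,
                              mode_convention = "match_mean")
  expect_equal(st$release_rate$mode, 3 * 54 - 39 - 66)
  expect_equal(dist_mean(st$release_rate), 54)
})

test_that("a zero-spread series degenerates to a point source with warning", {
  s <- discharge_series("X", "Co-60", c(5, 5, 5, 5, 5))
  expect_warning(st <- fit_triangular_source(s), "point")
  expect_identical(st$release_rate$kind, "point")
  expect_equal(st$release_rate$value, 5)
})

test_that("the fit is scale-equivariant and the mode lies within bounds", {
  set.seed(4)
  for (i in 1:20) {
    rates <- stats::runif(5, 1, 100)
    st <- fit_triangular_source(discharge_series("f", "n", rates))
    expect_gte(st$release_rate$mode, st$release_rate$min)
    expect_lte(st$release_rate$mode, st$release_rate$max)
    k <- 3.7
    stk <- fit_triangular_source(discharge_series("f", "n", k * rates))
    expect_equal(stk$release_rate$min, k * st$release_rate$min)
    expect_equal(stk$release_rate$mode, k * st$release_rate$mode)
    expect_equal(stk$release_rate$max, k * st$release_rate$max)
  }
})

test_that("series validation rejects too-short or negative data", {
  expect_error(discharge_series("f", "n", 5), "at least 2")
  expect_error(discharge_series("f", "n", c(1, -2)), "non-negative")
})

test_that("discharge CSVs are grouped and fitted per facility and nuclide", {
  path <- withr_local_tempfile()
  writeLines(c("facility,nuclide,year,rate_Bq_per_s",
               paste("Almaraz,Co-60", 1999:2003,
                     c(39, 48, 57, 60, 66), sep = ","),
               paste("Almaraz,Cs-137", 1999:2003,
                     c(15, 22, 28, 30, 35), sep = ",")), path)
  sts <- read_discharge_csv(path)
  expect_length(sts, 2)
  expect_equal(sts[["Almaraz:Co-60"]]$release_rate$mode, 54)
  expect_equal(sts[["Almaraz:Cs-137"]]$release_rate$mode, 26)
})
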