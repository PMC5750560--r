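test_that("decay constants follow from half-lives with a 365-day year", {
  # hand oracle: ln2 / (28.8 y * 3.1536e7 s/y)
  expect_equal(sr90$decay_constant, log(2) / (28.8 * 3.1536e7),
               tolerance = 1e-12)
  expect_equal(sr90$decay_constant, 7.63e-10, tolerance = 1e-3)
  for (nuc in tiny_db)
    expect_equal(exp(-nuc$decay_constant * nuc$half_life_y * 3.1536e7),
                 0.5, tolerance = 1e-9)
})

test_that("packaged database loads the three studied nuclides", {
  db <- load_nuclide_db()
  expect_setequal(names(db), c("Co-60", "Cs-137", "Sr-90"))
  expect_equal(db[["Co-60"]]$half_life_y, 5.27)
  expect_equal(db[["Sr-90"]]$half_life_y, 28.8)
  expect_equal(db[["Cs-137"]]$half_life_y, 30.1)
  expect_s3_class(db[["Co-60"]]$kd_freshwater, "dist_spec")
  expect_identical(db[["Co-60"]]$kd_freshwater$kind, "lognormal")
  expect_gt(dist_mode(db[["Co-60"]]$kd_marine), 0)
})

test_that("write/load round-trip reproduces identical values", {
  path <- withr_local_tempfile()
  write_nuclide_db(tiny_db, path)
  back <- load_nuclide_db(path)
  for (nm in names(tiny_db)) {
    expect_equal(back[[nm]]$half_life_y, tiny_db[[nm]]$half_life_y)
    expect_equal(back[[nm]]$decay_constant, tiny_db[[nm]]$decay_constant)
    expect_equal(dist_mode(back[[nm]]$kd_freshwater),
                 dist_mode(tiny_db[[nm]]$kd_freshwater))
  }
})

test_that("malformed databases fail with informative errors", {
  bad <- withr_local_tempfile()
  writeLines(c("name,half_life_y,kd_fresh_gm_L_per_kg,kd_marine_gm_L_per_kg,kd_gsd",
               "Co-60,5.27,5000,3e5,2.5", "Co-60,5.27,5000,3e5,2.5"), bad)
  expect_error(load_nuclide_db(bad), "duplicate")

  bad2 <- withr_local_tempfile()
  writeLines(c("name,half_life_y", "Co-60,5.27"), bad2)
  expect_error(load_nuclide_db(bad2), "missing columns")

  bad3 <- withr_local_tempfile()
  writeLines(c("name,half_life_y,kd_fresh_gm_L_per_kg,kd_marine_gm_L_per_kg,kd_gsd",
               "X-1,-2,5000,3e5,2.5"), bad3)
  expect_error(load_nuclide_db(bad3), "row 1")
})

test_that("a missing Kd spread falls back to a point distribution", {
  # one warning per medium (freshwater and marine)
  warns <- testthat::capture_warnings(
    nuc <- nuclide("Co-60", 5.27, 5000, 3e5, NA))
  expect_length(warns, 2)
  expect_match(warns, "point distribution", all = TRUE)
  expect_identical(nuc$kd_freshwater$kind, "point")
  expect_identical(nuc$kd_marine$kind, "point")
})
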