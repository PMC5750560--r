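# Small in-code fixtures shared across test files.

co60 <- nuclide("Co-60", 5.27, kd_fresh_gm = 5000, kd_marine_gm = 3e5,
                kd_gsd = 2.5)
cs137 <- nuclide("Cs-137", 30.1, kd_fresh_gm = 1e4, kd_marine_gm = 3e3,
                 kd_gsd = 2.5)
sr90 <- nuclide("Sr-90", 28.8, kd_fresh_gm = 1000, kd_marine_gm = 8,
                kd_gsd = 2.5)
tiny_db <- list("Co-60" = co60, "Cs-137" = cs137, "Sr-90" = sr90)

# Annual series whose min/mean/max reproduce the published triangular
# parameters for the reservoir Co-60 release (39 / 54 / 66 Bq/s).
almaraz_co60_series <- discharge_series("Almaraz", "Co-60",
                                        c(39, 48, 57, 60, 66))

lake_fixture <- function(...) {
  assessment_config(
    scenario = reservoir_scenario(1950032, 0.097128117),
    source_terms = list(source_term("Co-60", dist_triangular(39, 54, 66))),
    receptors = list(list(label = "Arrocampo")),
    nuclides = tiny_db, ...)
}

river_fixture <- function(receptors = list(
                            list(label = "R500s", distance_m = 500,
                                 same_shore = TRUE),
                            list(label = "R500d", distance_m = 500,
                                 same_shore = FALSE)), ...) {
  assessment_config(
    scenario = river_scenario(40, 0.8, 0.19804777),
    source_terms = list(source_term("Co-60", dist_triangular(34, 51, 72))),
    receptors = receptors, nuclides = tiny_db, ...)
}

scenario_path <- function(name)
  system.file("extdata", name, package = "aquaprog")

withr_local_tempfile <- function() tempfile()
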