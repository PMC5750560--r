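#' Parse a distribution literal
#'
#' Converts a config-style list such as
#' `list(kind = "triangular", min = 39, mode = 54, max = 66)` into a
#' [dist_spec]; `dist_to_list()` is its inverse.
#'
#' @param x named list with a `kind` and kind-specific parameters.
#' @return A [dist_spec] (`parse_dist`) or a plain list (`dist_to_list`).
#' @export
parse_dist <- function(x) {
  if (is.null(x$kind)) stop("distribution literal needs a kind",
                            call. = FALSE)
  switch(x$kind,
    point = dist_point(x$value),
    triangular = dist_triangular(x$min, x$mode, x$max),
    lognormal = dist_lognormal(x$gm, x$gsd),
    uniform = dist_uniform(x$lo, x$hi),
    stop("unknown distribution kind: ", x$kind, call. = FALSE))
}

#' @rdname parse_dist
#' @param spec a [dist_spec].
#' @export
dist_to_list <- function(spec) {
  validate_dist(spec)
  unclass(spec)
}

.scenario_keys <- list(
  lake = c("type", "volume_m3", "outflow_m3_s"),
  river = c("type", "width_m", "depth_m", "velocity_m_s", "flow_m3_s"),
  coast = c("type", "depth_m", "current_m_s", "release_offshore_m",
            "dispersion_coeff"))

#' Load a scenario configuration from YAML
#'
#' Reads and fully validates a scenario file; every problem found is
#' reported in one aggregated error.  Unknown keys are rejected to catch
#' unit typos.  The YAML layout is:
#'
#' ```yaml
#' site: Almaraz
#' water_body: {type: lake, volume_m3: 2.0e6, outflow_m3_s: 0.1}
#' source_terms:
#'   - nuclide: Co-60
#'     distribution: {kind: triangular, min: 39, mode: 54, max: 66}
#' sediment: {suspended_load_kg_m3: 0.05, accumulation_time_y: 30}
#' mc: {n_draws: 10000, seed: 42}
#' receptors:
#'   - {label: Reservoir}
#' measured: measured.csv
#' ```
#'
#' A missing `mc$seed` falls back to 42 with a warning.  A `measured` entry
#' names a measured-range CSV relative to the config file and is attached
#' as `config$measured`.
#'
#' @param path YAML file path.
#' @param nuclides nuclide database (defaults to the packaged one).
#' @return An [assessment_config()].
#' @export
load_scenario <- function(path, nuclides = load_nuclide_db()) {
  if (!file.exists(path)) stop("scenario file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  errs <- character()
  note <- function(...) errs <<- c(errs, paste0(...))

  known_top <- c("site", "water_body", "source_terms", "sediment", "mc",
                 "receptors", "measured")
  extra <- setdiff(names(raw), known_top)
  if (length(extra)) note("unknown top-level key(s): ",
                          paste(extra, collapse = ", "))

  wb <- raw$water_body
  scenario <- NULL
  if (is.null(wb) || is.null(wb$type) ||
      !wb$type %in% names(.scenario_keys)) {
    note("water_body.type must be one of lake, river, coast")
  } else {
    extra <- setdiff(names(wb), .scenario_keys[[wb$type]])
    if (length(extra)) note("unknown water_body key(s) for type ", wb$type,
                            ": ", paste(extra, collapse = ", "))
    scenario <- tryCatch(switch(wb$type,
      lake = reservoir_scenario(wb$volume_m3, wb$outflow_m3_s),
      river = river_scenario(wb$width_m, wb$depth_m, wb$velocity_m_s,
                             wb$flow_m3_s),
      coast = coast_scenario(wb$depth_m, wb$current_m_s,
                             release_offshore_m =
                               wb$release_offshore_m %||% 0,
                             dispersion_coeff =
                               wb$dispersion_coeff %||% 0.0124)),
      error = function(e) { note("water_body: ", conditionMessage(e)); NULL })
  }

  sts <- lapply(seq_along(raw$source_terms), function(i) {
    st <- raw$source_terms[[i]]
    tryCatch(source_term(st$nuclide, parse_dist(st$distribution)),
             error = function(e) {
               note("source_terms[", i, "]: ", conditionMessage(e)); NULL })
  })
  sts <- Filter(Negate(is.null), sts)
  if (!length(sts)) note("no valid source_terms")

  mc <- raw$mc %||% list()
  if (is.null(mc$seed)) {
    warning("mc.seed missing in ", basename(path), "; defaulting to 42",
            call. = FALSE)
    mc$seed <- 42L
  }
  if (is.null(mc$n_draws)) mc$n_draws <- 10000L

  sed <- raw$sediment %||% list()
  if (!is.null(sed$kd_overrides))
    sed$kd_overrides <- lapply(sed$kd_overrides, parse_dist)

  if (length(errs))
    stop("invalid scenario ", basename(path), ":\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)

  config <- assessment_config(
    scenario = scenario, source_terms = sts,
    receptors = raw$receptors %||% list(list(label = "receptor")),
    nuclides = nuclides, sediment = sed,
    n_draws = mc$n_draws, seed = mc$seed,
    site = raw$site %||% NA_character_)
  if (!is.null(raw$measured)) {
    mpath <- file.path(dirname(path), raw$measured)
    config$measured <- read_measured_ranges(mpath)
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

manifest_lines <- function(seed = NA, n_draws = NA, site = NA) {
  c(paste0("# aquaprog ",
           as.character(utils::packageVersion("aquaprog"))),
    paste0("# created: ",
           format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("# site: ", site),
    paste0("# seed: ", seed),
    paste0("# n_draws: ", n_draws))
}

#' Write prognosis results to CSV
#'
#' Writes one row per nuclide x receptor with both full-precision columns
#' (`mean`, `sd`, `ci_lo`, `ci_hi`) and 2-significant-figure display
#' columns, preceded by a `#`-commented run manifest (package version,
#' timestamp, seed, draw count).
#'
#' @param prognosis a `sediment_prognosis`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(prognosis, path) {
  stopifnot(inherits(prognosis, "sediment_prognosis"))
  sm <- prognosis$summary
  if (!nrow(sm)) stop("empty results", call. = FALSE)
  full <- c("mean", "sd", "ci_lo", "ci_hi")
  body <- data.frame(nuclide = sm$nuclide, receptor = sm$receptor,
                     stringsAsFactors = FALSE)
  for (col in full) body[[col]] <- sprintf("%.17g", sm[[col]])
  for (col in full) body[[paste0(col, "_2sf")]] <-
    format(signif(sm[[col]], 2))
  body$n_draws <- sm$n_draws
  body$seed <- sm$seed
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(manifest_lines(sm$seed[1], sm$n_draws[1],
                            prognosis$config$site), con)
  utils::write.csv(body, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a results CSV
#'
#' @param path CSV written by [write_results()].
#' @return Data frame with the full-precision numeric columns restored.
#' @export
read_results <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                         stringsAsFactors = FALSE)
  for (col in c("mean", "sd", "ci_lo", "ci_hi"))
    tab[[col]] <- as.numeric(tab[[col]])
  tab
}

#' Write a model-measurement comparison report to CSV
#'
#' @param comparison data frame from [compare_prognosis()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  if (!nrow(comparison)) stop("empty comparison", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(manifest_lines(), con)
  utils::write.csv(comparison, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
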