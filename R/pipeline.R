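#' Assemble an assessment configuration
#'
#' Binds together everything a probabilistic prognosis run needs: the
#' water-body scenario, the source terms, the receptor list, the nuclide
#' database and the sediment-model settings.
#'
#' Receptors are lists with a `label` plus, for rivers, `distance_m` and
#' `same_shore`, and for coasts, `alongshore_m` and `offshore_m`; a lake
#' receptor needs only a label (the box model is homogeneous).
#'
#' By default Kd is sampled per draw from its lognormal distribution in
#' freshwater scenarios and held at the geometric mean in marine scenarios;
#' override with `sediment$kd_stochastic`.  The default suspended load is
#' 0.05 kg/m^3 for freshwater and 0.01 kg/m^3 for coastal water.
#'
#' @param scenario a `water_scenario` from [reservoir_scenario()],
#'   [river_scenario()] or [coast_scenario()].
#' @param source_terms list of [source_term] objects.
#' @param receptors list of receptor descriptors (see Details).
#' @param nuclides named list of [nuclide] objects; defaults to the packaged
#'   database.
#' @param sediment list of sediment settings: `suspended_load_kg_m3`,
#'   `accumulation_time_y`, `top_layer_fraction`, `kd_stochastic`,
#'   `kd_overrides` (named list of [dist_spec] per nuclide).
#' @param n_draws default Monte-Carlo draws per run (>= 100).
#' @param seed default root seed.
#' @param site optional site label for reports.
#' @return An object of class `assessment_config`.
#' @export
assessment_config <- function(scenario, source_terms, receptors,
                              nuclides = load_nuclide_db(),
                              sediment = list(), n_draws = 10000, seed = 42,
                              site = NA_character_) {
  stopifnot(inherits(scenario, "water_scenario"))
  if (!length(source_terms) ||
      !all(vapply(source_terms, inherits, TRUE, "source_term")))
    stop("source_terms must be a non-empty list of source_term objects",
         call. = FALSE)
  if (n_draws < 100)
    stop("n_draws must be >= 100 for stable summaries", call. = FALSE)
  for (st in source_terms)
    if (is.null(nuclides[[st$nuclide]]))
      stop("source-term nuclide not in nuclide DB: ", st$nuclide,
           call. = FALSE)
  receptors <- lapply(receptors, validate_receptor, type = scenario$type)
  defaults <- list(
    suspended_load_kg_m3 = if (scenario$type == "coast") 0.01 else 0.05,
    accumulation_time_y = 30,
    top_layer_fraction = 0.1,
    kd_stochastic = scenario$type != "coast",
    kd_overrides = list())
  sediment <- utils::modifyList(defaults, sediment)
  structure(list(site = site, scenario = scenario,
                 source_terms = source_terms, receptors = receptors,
                 nuclides = nuclides, sediment = sediment,
                 mc = list(n_draws = as.integer(n_draws),
                           seed = as.integer(seed))),
            class = "assessment_config")
}

validate_receptor <- function(r, type) {
  if (is.null(r$label)) stop("every receptor needs a label", call. = FALSE)
  if (type == "river") {
    if (is.null(r$distance_m) || r$distance_m <= 0)
      stop("river receptor '", r$label, "' needs distance_m > 0",
           call. = FALSE)
    if (is.null(r$same_shore)) r$same_shore <- TRUE
  } else if (type == "coast") {
    if (is.null(r$alongshore_m) || r$alongshore_m <= 0)
      stop("coast receptor '", r$label, "' needs alongshore_m > 0",
           call. = FALSE)
    if (is.null(r$offshore_m) || r$offshore_m < 0)
      stop("coast receptor '", r$label, "' needs offshore_m >= 0",
           call. = FALSE)
  }
  r
}

# Receptor-specific water concentration, vectorised over Q.
receptor_concentration <- function(Q, nuc, scenario, receptor) {
  switch(scenario$type,
    lake = lake_concentration(Q, nuc, scenario),
    river = river_concentration(Q, nuc, scenario, receptor$distance_m,
                                receptor$same_shore),
    coast = coastal_concentration(Q, nuc, scenario, receptor$alongshore_m,
                                  receptor$offshore_m))
}

# Kd sampling distribution for one nuclide under a config.
config_kd_dist <- function(config, nuclide_name) {
  ov <- config$sediment$kd_overrides[[nuclide_name]]
  spec <- if (!is.null(ov)) ov
          else kd_dist_for(config$nuclides[[nuclide_name]],
                           config$scenario$type)
  if (!config$sediment$kd_stochastic) spec <- dist_point(dist_mode(spec))
  spec
}

#' Run a probabilistic sediment prognosis
#'
#' Propagates the source-term and Kd uncertainty through the dispersion and
#' sediment models by Monte Carlo.  Per draw the evaluation order is: sample
#' the release rate Q, sample Kd, evaluate the dispersion model, partition
#' dissolved activity, evaluate the bottom-sediment model.  Draw streams are
#' seeded per (stage, nuclide) from the root seed, so results for a nuclide
#' or receptor never change when another nuclide or receptor is added, and
#' the same root seed reproduces results bit for bit.
#'
#' @param config an [assessment_config()].
#' @param n_draws,seed overrides of the config's Monte-Carlo settings.
#' @return An object of class `sediment_prognosis`: a list with `summary`
#'   (data frame with one row per nuclide x receptor: `nuclide`, `receptor`,
#'   `mean`, `sd`, `ci_lo`, `ci_hi`, `n_draws`, `seed`, all concentrations
#'   in Bq/kg dry sediment), `draws` (nested list of the per-draw sediment
#'   concentrations) and `config`.
#' @seealso [summary.sediment_prognosis()], [plot.sediment_prognosis()],
#'   [compare_prognosis()]
#' @export
run_assessment <- function(config, n_draws = NULL, seed = NULL) {
  stopifnot(inherits(config, "assessment_config"))
  n <- if (is.null(n_draws)) config$mc$n_draws else as.integer(n_draws)
  if (n < 100) stop("n_draws must be >= 100", call. = FALSE)
  seed <- if (is.null(seed)) config$mc$seed else as.integer(seed)
  sed <- config$sediment
  rows <- list(); draws <- list()
  for (st in config$source_terms) {
    nuc <- config$nuclides[[st$nuclide]]
    q <- sample_dist(st$release_rate, n,
                     seed = derive_seed(seed, "source", st$nuclide))
    kd <- sample_dist(config_kd_dist(config, st$nuclide), n,
                      seed = derive_seed(seed, "kd", st$nuclide))
    params <- sediment_params(
      kd = dist_point(dist_mode(config_kd_dist(config, st$nuclide))),
      suspended_load_kg_m3 = sed$suspended_load_kg_m3,
      accumulation_time_y = sed$accumulation_time_y,
      top_layer_fraction = sed$top_layer_fraction)
    draws[[st$nuclide]] <- list()
    for (rec in config$receptors) {
      cw <- receptor_concentration(q, nuc, config$scenario, rec)
      cdis <- dissolved_fraction(cw, kd, sed$suspended_load_kg_m3)
      cbs <- bottom_sediment_concentration(cdis, nuc, params, kd = kd)
      s <- summarize_draws(cbs, seed = seed)
      draws[[st$nuclide]][[rec$label]] <- cbs
      rows[[length(rows) + 1L]] <- data.frame(
        nuclide = st$nuclide, receptor = rec$label,
        mean = s$mean, sd = s$sd, ci_lo = s$ci_lo, ci_hi = s$ci_hi,
        n_draws = s$n, seed = seed, stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, rows), draws = draws,
                 config = config),
            class = "sediment_prognosis")
}

#' Deterministic model evaluation at the central input values
#'
#' Evaluates the full dispersion + sediment chain once per nuclide and
#' receptor with every stochastic input held at its central value (the
#' triangular mode for release rates, the geometric mean for Kd).  This is
#' the evaluation used for fixture calibration.
#'
#' @param config an [assessment_config()].
#' @return Data frame with columns `nuclide`, `receptor`, `value` (Bq/kg).
#' @export
deterministic_run <- function(config) {
  stopifnot(inherits(config, "assessment_config"))
  sed <- config$sediment
  rows <- list()
  for (st in config$source_terms) {
    nuc <- config$nuclides[[st$nuclide]]
    q <- dist_mode(st$release_rate)
    kd <- dist_mode(config_kd_dist(config, st$nuclide))
    params <- sediment_params(
      kd = dist_point(kd),
      suspended_load_kg_m3 = sed$suspended_load_kg_m3,
      accumulation_time_y = sed$accumulation_time_y,
      top_layer_fraction = sed$top_layer_fraction)
    for (rec in config$receptors) {
      cw <- receptor_concentration(q, nuc, config$scenario, rec)
      cdis <- dissolved_fraction(cw, kd, sed$suspended_load_kg_m3)
      rows[[length(rows) + 1L]] <- data.frame(
        nuclide = st$nuclide, receptor = rec$label,
        value = bottom_sediment_concentration(cdis, nuc, params, kd = kd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Calibrate scenario hydrology against target concentrations
#'
#' Adjusts the named free scenario parameters so that the deterministic
#' model output ([deterministic_run()]) matches the target sediment
#' concentrations, minimising the sum of squared log ratios.  Used once, to
#' build site fixtures when the true hydrology is unknown; ordinary runs
#' never self-calibrate.
#'
#' For rivers the free parameters are the geometry fields (`width_m`,
#' `depth_m`, `velocity_m_s`); the flow is re-derived from the geometry so
#' hydraulic consistency — and any fixed complete-mixing-distance
#' constraint expressed through width and depth — is preserved.
#'
#' @param config an [assessment_config()].
#' @param targets data frame with columns `nuclide`, `receptor`, `value`
#'   (Bq/kg) naming the deterministic outputs to match.
#' @param free character vector of scenario field names to optimise (may be
#'   empty: the config is returned unchanged with its residual).
#' @return List with elements `config` (calibrated), `par` (named vector of
#'   fitted parameters), `residual` (sum of squared log ratios) and
#'   `fitted` (deterministic outputs at the solution).
#' @export
calibrate_scenario <- function(config, targets, free = character()) {
  stopifnot(inherits(config, "assessment_config"),
            is.data.frame(targets),
            all(c("nuclide", "receptor", "value") %in% names(targets)))
  if (nrow(targets) < 1) stop("need at least one target", call. = FALSE)
  allowed <- switch(config$scenario$type,
    lake = c("volume_m3", "outflow_m3_s"),
    river = c("width_m", "depth_m", "velocity_m_s"),
    coast = c("depth_m", "current_m_s", "dispersion_coeff"))
  if (!all(free %in% allowed))
    stop("free parameters for a ", config$scenario$type,
         " scenario must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  if (length(free) > nrow(targets))
    stop("unidentifiable calibration: ", length(free), " free parameter(s) [",
         paste(free, collapse = ", "), "] but only ", nrow(targets),
         " target(s); fixed fields: ",
         paste(setdiff(allowed, free), collapse = ", "), call. = FALSE)

  with_pars <- function(logpar) {
    scen <- config$scenario
    scen[free] <- as.list(exp(logpar))
    config$scenario <- rebuild_scenario(scen)
    config
  }
  objective <- function(logpar) {
    det <- deterministic_run(with_pars(logpar))
    key <- paste(det$nuclide, det$receptor, sep = ":")
    idx <- match(paste(targets$nuclide, targets$receptor, sep = ":"), key)
    if (anyNA(idx))
      stop("target not produced by the model: ",
           paste(paste(targets$nuclide, targets$receptor)[is.na(idx)],
                 collapse = "; "), call. = FALSE)
    sum((log(det$value[idx]) - log(targets$value))^2)
  }

  if (!length(free)) {
    res <- objective(numeric(0))
    return(list(config = config, par = numeric(0), residual = res,
                fitted = deterministic_run(config)))
  }
  start <- log(unlist(config$scenario[free]))
  opt <- stats::optim(start, objective, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  out <- with_pars(opt$par)
  list(config = out, par = stats::setNames(exp(opt$par), free),
       residual = opt$value, fitted = deterministic_run(out))
}

# Re-run the scenario constructor so derived quantities (river flow) and
# invariants stay consistent after a field update.
rebuild_scenario <- function(scen) {
  switch(scen$type,
    lake = reservoir_scenario(scen$volume_m3, scen$outflow_m3_s),
    river = river_scenario(scen$width_m, scen$depth_m, scen$velocity_m_s),
    coast = coast_scenario(scen$depth_m, scen$current_m_s,
                           scen$release_offshore_m, scen$dispersion_coeff))
}

#' @export
print.sediment_prognosis <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Probabilistic sediment prognosis%s (%s scenario)\n",
              if (is.na(cfg$site)) "" else paste0(" - ", cfg$site),
              cfg$scenario$type))
  cat(sprintf("  %d draws, seed %d; concentrations in Bq/kg dry sediment\n",
              x$summary$n_draws[1], x$summary$seed[1]))
  disp <- x$summary
  for (col in c("mean", "sd", "ci_lo", "ci_hi"))
    disp[[col]] <- signif(disp[[col]], 2)
  print(disp[c("nuclide", "receptor", "mean", "sd", "ci_lo", "ci_hi")],
        row.names = FALSE)
  invisible(x)
}

#' Summary of a sediment prognosis
#'
#' @param object a `sediment_prognosis`.
#' @param measured optional measured-range data frame (see
#'   [read_measured_ranges()]); when given, comparison ratios and verdicts
#'   are appended.
#' @param ... passed to [compare_prognosis()].
#' @return The summary data frame, possibly augmented with comparison
#'   columns.
#' @export
summary.sediment_prognosis <- function(object, measured = NULL, ...) {
  if (is.null(measured)) return(object$summary)
  compare_prognosis(object, measured, ...)
}

#' @export
as.data.frame.sediment_prognosis <- function(x, ...) x$summary

#' Re-run a prognosis under new seeds
#'
#' @param object a `sediment_prognosis`.
#' @param nsim number of replicate runs.
#' @param seed root seed for the first replicate; subsequent replicates use
#'   `seed + 1, ...`.
#' @param ... unused.
#' @return A list of `nsim` new `sediment_prognosis` objects.
#' @export
simulate.sediment_prognosis <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$summary$seed[1] + 1L
  lapply(seq_len(nsim) - 1L,
         function(k) run_assessment(object$config, seed = seed + k))
}

#' Histogram of the modelled sediment concentration distribution
#'
#' Plots the Monte-Carlo distribution for one nuclide at one receptor, with
#' the measured environmental range (if supplied) overlaid as a horizontal
#' segment above the axis.
#'
#' @param x a `sediment_prognosis`.
#' @param nuclide nuclide label (default: first).
#' @param receptor receptor label (default: first for that nuclide).
#' @param measured optional measured-range data frame.
#' @param breaks,... passed to [graphics::hist()].
#' @return Invisibly, the histogram object.
#' @export
plot.sediment_prognosis <- function(x, nuclide = NULL, receptor = NULL,
                                    measured = NULL, breaks = 40, ...) {
  if (is.null(nuclide)) nuclide <- names(x$draws)[1]
  if (is.null(receptor)) receptor <- names(x$draws[[nuclide]])[1]
  d <- x$draws[[nuclide]][[receptor]]
  if (is.null(d)) stop("no draws for ", nuclide, " at ", receptor,
                       call. = FALSE)
  h <- graphics::hist(d, breaks = breaks, main = paste(nuclide, "at", receptor),
                      xlab = "Bottom-sediment concentration (Bq/kg dry)", ...)
  if (!is.null(measured)) {
    m <- measured[measured$nuclide == nuclide &
                  (is.na(measured$receptor) | measured$receptor == receptor), ]
    if (nrow(m)) {
      y <- max(h$counts) * 0.05
      graphics::segments(m$lo[1], y, m$hi[1], y, lwd = 4)
      graphics::mtext("measured range", side = 3, line = -1.5, adj = 1,
                      cex = 0.8)
    }
  }
  invisible(h)
}
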