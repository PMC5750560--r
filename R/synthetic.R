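#' Synthetic-data specification
#'
#' Ground-truth settings for generating synthetic discharge series and
#' synthetic measurement ranges, so every pipeline stage can be exercised
#' against a known truth.  The generator emulates the structure of the real
#' inputs: a handful of annual mean release rates with bounded interannual
#' variability, and environmental results reported as a symmetric
#' multiplicative band (the k = 2 coverage convention) around a possibly
#' biased central value, flagged when below the detection limit.
#'
#' @param true_source a [dist_spec]: the true release-rate distribution
#'   from which annual values are drawn.
#' @param n_years number of annual values (>= 2; the study convention is 5).
#' @param measurement_bias multiplicative bias of the measurement central
#'   value relative to truth (1 = unbiased).
#' @param measurement_cv relative half-width parameter of the reported
#'   range (>= 0); the range is `truth * bias * (1 +/- 2 * cv)`.
#' @param detection_limit concentrations whose reported upper bound falls
#'   below this are flagged below-detection (Bq/kg).
#' @param seed integer seed for the discharge draws.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(true_source, n_years = 5, measurement_bias = 1,
                           measurement_cv = 0.25, detection_limit = 0,
                           seed = 1) {
  validate_dist(true_source)
  if (n_years < 2) stop("n_years must be >= 2", call. = FALSE)
  if (measurement_cv < 0) stop("measurement_cv must be >= 0", call. = FALSE)
  if (measurement_bias <= 0)
    stop("measurement_bias must be > 0", call. = FALSE)
  structure(list(true_source = true_source, n_years = as.integer(n_years),
                 measurement_bias = measurement_bias,
                 measurement_cv = measurement_cv,
                 detection_limit = detection_limit,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic annual discharge series
#'
#' Draws `n_years` annual release rates from the true source distribution;
#' reproducible under the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param facility,nuclide labels for the generated series.
#' @return A [discharge_series()].
#' @export
generate_discharge_series <- function(spec, facility = "synthetic",
                                      nuclide = "Co-60") {
  stopifnot(inherits(spec, "synthetic_spec"))
  discharge_series(facility, nuclide,
                   sample_dist(spec$true_source, spec$n_years,
                               seed = spec$seed))
}

#' Generate a synthetic measured range around a known truth
#'
#' The reported range is `truth * bias * (1 - 2*cv)` to
#' `truth * bias * (1 + 2*cv)`, clipped at zero, and flagged
#' below-detection when its upper bound falls under the detection limit.
#'
#' @param truth true sediment concentration (Bq/kg, >= 0).
#' @param spec a [synthetic_spec()].
#' @param nuclide,receptor labels for the generated range.
#' @return A one-row measured-range data frame (see [measured_range()]).
#' @export
generate_measured_range <- function(truth, spec, nuclide = "Co-60",
                                    receptor = NA_character_) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (truth < 0) stop("truth must be >= 0", call. = FALSE)
  centre <- truth * spec$measurement_bias
  lo <- max(0, centre * (1 - 2 * spec$measurement_cv))
  hi <- centre * (1 + 2 * spec$measurement_cv)
  measured_range(nuclide, lo, hi,
                 below_detection = hi < spec$detection_limit,
                 receptor = receptor)
}
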