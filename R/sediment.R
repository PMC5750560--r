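#' Sediment model parameters
#'
#' Parameters of the water-to-bottom-sediment transfer: the distribution
#' coefficient Kd (L/kg, as a sampleable distribution), the suspended
#' sediment load (kg/m^3), the accumulation period (years; the prognosis
#' convention is 30 years of continuous discharge) and the fraction of the
#' sediment-bound activity residing in the sampled top layer.
#'
#' @param kd a [dist_spec] for Kd (L/kg) with positive support.
#' @param suspended_load_kg_m3 suspended sediment load (kg/m^3, > 0).
#' @param accumulation_time_y accumulation period (years, > 0).
#' @param top_layer_fraction fraction of deposited activity in the sampled
#'   top sediment layer (dimensionless, in (0, 1]).
#' @return An object of class `sediment_params`.
#' @export
sediment_params <- function(kd, suspended_load_kg_m3 = 0.05,
                            accumulation_time_y = 30,
                            top_layer_fraction = 0.1) {
  validate_dist(kd)
  pos1(suspended_load_kg_m3, "suspended_load_kg_m3")
  pos1(accumulation_time_y, "accumulation_time_y")
  pos1(top_layer_fraction, "top_layer_fraction")
  if (top_layer_fraction > 1)
    stop("top_layer_fraction must be <= 1", call. = FALSE)
  structure(list(kd = kd, suspended_load_kg_m3 = suspended_load_kg_m3,
                 accumulation_time_y = accumulation_time_y,
                 top_layer_fraction = top_layer_fraction),
            class = "sediment_params")
}

#' Dissolved fraction of the total water concentration
#'
#' Equilibrium partitioning between solution and suspended matter:
#' `C_dissolved = C_total / (1 + Kd * 1e-3 * suspended_load)`, where the
#' factor 1e-3 converts Kd from L/kg to m^3/kg.
#'
#' @param c_total total water concentration(s), Bq/m^3 (>= 0).
#' @param kd distribution coefficient(s), L/kg (>= 0); vectorised.
#' @param suspended_load_kg_m3 suspended sediment load (kg/m^3, >= 0).
#' @return Dissolved concentration(s), Bq/m^3, never exceeding `c_total`.
#' @export
dissolved_fraction <- function(c_total, kd, suspended_load_kg_m3) {
  if (any(c_total < 0) || any(kd < 0) || any(suspended_load_kg_m3 < 0))
    stop("inputs to dissolved_fraction must be non-negative", call. = FALSE)
  c_total / (1 + kd * 1e-3 * suspended_load_kg_m3)
}

#' Time-averaged radioactive build-up factor
#'
#' `B(lambda, T) = (1 - exp(-lambda*T)) / (lambda*T)`, the mean of
#' `exp(-lambda*t)` over a discharge period of `T` years: the fraction of
#' continuously deposited activity that survives decay, averaged over the
#' accumulation period.  `B` is in (0, 1] and tends to 1 for long-lived
#' nuclides (`lambda*T -> 0`).
#'
#' @param lambda decay constant (1/s, >= 0).
#' @param time_y accumulation period (years, > 0).
#' @return The dimensionless build-up factor.
#' @export
buildup_factor <- function(lambda, time_y) {
  if (lambda < 0 || time_y <= 0)
    stop("lambda must be >= 0 and time_y > 0", call. = FALSE)
  lt <- lambda * time_y * .YEAR_SECONDS
  # second-order expansion below 1e-8 avoids 0/0 and cancellation
  if (lt < 1e-8) return(1 - lt / 2)
  (1 - exp(-lt)) / lt
}

#' Bottom-sediment activity concentration
#'
#' Converts the dissolved water concentration at the receptor into the
#' activity concentration of the top bottom-sediment layer (Bq per kg dry
#' sediment):
#' `C_bs = top_layer_fraction * Kd * 1e-3 * C_dissolved * B(lambda, T)`,
#' with [buildup_factor()] accounting for decay during the finite
#' accumulation period.
#'
#' @param c_dissolved dissolved water concentration(s), Bq/m^3 (>= 0).
#' @param nuclide a [nuclide] object or bare decay constant (1/s).
#' @param params a [sediment_params] object.
#' @param kd optional Kd value(s) (L/kg) overriding the central value of
#'   `params$kd` — used to pass per-draw Monte-Carlo samples.
#' @return Sediment concentration(s), Bq/kg dry weight.
#' @examples
#' co <- nuclide("Co-60", 5.27, 5000, 3e5, 2.5)
#' p <- sediment_params(dist_point(5000))
#' bottom_sediment_concentration(100, co, p)
#' @export
bottom_sediment_concentration <- function(c_dissolved, nuclide, params,
                                          kd = NULL) {
  stopifnot(inherits(params, "sediment_params"))
  if (any(c_dissolved < 0))
    stop("c_dissolved must be non-negative", call. = FALSE)
  if (is.null(kd)) kd <- dist_mode(params$kd)
  if (any(kd < 0)) stop("kd must be non-negative", call. = FALSE)
  B <- buildup_factor(lambda_of(nuclide), params$accumulation_time_y)
  params$top_layer_fraction * kd * 1e-3 * c_dissolved * B
}
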