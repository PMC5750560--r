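#' Decay-correct a historical fallout deposit
#'
#' Corrects a deposition density for radioactive decay over the elapsed
#' time: `deposit * 2^(-elapsed / half_life)`.
#'
#' @param deposit deposition density (Bq/m^2, >= 0).
#' @param nuclide a [nuclide] object or a bare half-life in years.
#' @param elapsed_y elapsed time (years, >= 0).
#' @return Decayed deposition density (Bq/m^2).
#' @examples
#' sr <- nuclide("Sr-90", 28.8, 1000, 8, 2.5)
#' decay_correct(400, sr, 47)  # ~130 Bq/m^2
#' @export
decay_correct <- function(deposit, nuclide, elapsed_y) {
  half_life <- if (inherits(nuclide, "nuclide")) nuclide$half_life_y
               else pos1(nuclide, "half-life")
  if (any(deposit < 0)) stop("deposit must be >= 0", call. = FALSE)
  if (elapsed_y < 0) stop("elapsed_y must be >= 0", call. = FALSE)
  deposit * 2^(-elapsed_y / half_life)
}

#' Convert a surface deposit into a soil/sediment concentration
#'
#' Distributes a deposition density uniformly over a surface mixing layer:
#' `deposit / (soil_density * mixing_depth)`.
#'
#' @param deposit deposition density (Bq/m^2, >= 0).
#' @param soil_density bulk density (kg/m^3, > 0).
#' @param mixing_depth mixing-layer depth (m, > 0).
#' @return Mass activity concentration (Bq/kg).
#' @examples
#' deposit_to_concentration(129.1, 1300, 0.05)  # ~1.99 Bq/kg
#' @export
deposit_to_concentration <- function(deposit, soil_density, mixing_depth) {
  if (any(deposit < 0)) stop("deposit must be >= 0", call. = FALSE)
  pos1(soil_density, "soil_density")
  pos1(mixing_depth, "mixing_depth")
  deposit / (soil_density * mixing_depth)
}

#' Global-fallout baseline concentration
#'
#' Convenience composition of [decay_correct()] and
#' [deposit_to_concentration()]: the present-day soil/sediment concentration
#' expected from a historical weapons-fallout deposit, used to judge whether
#' measured Cs-137/Sr-90 levels can be attributed to a nearby facility at
#' all.
#'
#' @inheritParams decay_correct
#' @inheritParams deposit_to_concentration
#' @return List with `deposit_now` (Bq/m^2) and `concentration` (Bq/kg).
#' @export
fallout_baseline <- function(deposit, nuclide, elapsed_y,
                             soil_density = 1300, mixing_depth = 0.05) {
  now <- decay_correct(deposit, nuclide, elapsed_y)
  list(deposit_now = now,
       concentration = deposit_to_concentration(now, soil_density,
                                                mixing_depth))
}
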