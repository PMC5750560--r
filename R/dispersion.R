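#' Water-body scenarios
#'
#' Geometry and hydrology of the receiving water body for the three
#' steady-state screening dispersion models.
#'
#' `reservoir_scenario()` describes a reservoir or lake treated as a single
#' well-mixed box: a volume and an outflow.
#'
#' `river_scenario()` describes a river reach by width, depth and mean
#' velocity; the flow defaults to `width * depth * velocity` and, when given
#' explicitly, must agree with that product within `flow_tol` (relative).
#' The complete lateral mixing distance is `L = 7 * width^2 / depth`
#' (see [mixing_length()]): beyond `L` a bank discharge is uniformly mixed
#' over the cross-section and shore position no longer matters.
#'
#' `coast_scenario()` describes an alongshore current of given depth and
#' speed; the release sits `release_offshore_m` from the shoreline (0 for a
#' shoreline outfall).  The lateral plume spread grows as
#' `sigma_y = dispersion_coeff * x^(7/6)`, the power law implied by
#' scale-dependent (4/3-law) horizontal diffusivity in coastal waters.
#'
#' @param volume_m3 reservoir volume (m^3).
#' @param outflow_m3_s reservoir outflow (m^3/s).
#' @param width_m,depth_m,velocity_m_s river geometry (m, m, m/s).
#' @param flow_m3_s river flow; computed from the geometry when `NULL`.
#' @param flow_tol relative tolerance for the flow/geometry consistency check.
#' @param current_m_s alongshore current speed (m/s).
#' @param release_offshore_m perpendicular distance of the outfall from the
#'   shoreline (m, >= 0).
#' @param dispersion_coeff coastal plume-growth coefficient
#'   (m^(-1/6)); the default 0.0124 represents generic coastal
#'   diffusion data.
#' @return A `water_scenario` object (subclass `lake`, `river` or `coast`).
#' @name water_scenario
NULL

pos1 <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a single positive number", call. = FALSE)
  x
}

#' @rdname water_scenario
#' @export
reservoir_scenario <- function(volume_m3, outflow_m3_s) {
  structure(list(type = "lake",
                 volume_m3 = pos1(volume_m3, "volume_m3"),
                 outflow_m3_s = pos1(outflow_m3_s, "outflow_m3_s")),
            class = c("lake_scenario", "water_scenario"))
}

#' @rdname water_scenario
#' @export
river_scenario <- function(width_m, depth_m, velocity_m_s,
                           flow_m3_s = NULL, flow_tol = 0.05) {
  width_m <- pos1(width_m, "width_m")
  depth_m <- pos1(depth_m, "depth_m")
  velocity_m_s <- pos1(velocity_m_s, "velocity_m_s")
  geom_flow <- width_m * depth_m * velocity_m_s
  if (is.null(flow_m3_s)) flow_m3_s <- geom_flow
  else {
    pos1(flow_m3_s, "flow_m3_s")
    if (abs(flow_m3_s - geom_flow) > flow_tol * geom_flow)
      stop(sprintf(
        "flow (%g m3/s) inconsistent with width*depth*velocity (%g m3/s)",
        flow_m3_s, geom_flow), call. = FALSE)
  }
  structure(list(type = "river", width_m = width_m, depth_m = depth_m,
                 velocity_m_s = velocity_m_s, flow_m3_s = flow_m3_s),
            class = c("river_scenario", "water_scenario"))
}

#' @rdname water_scenario
#' @export
coast_scenario <- function(depth_m, current_m_s, release_offshore_m = 0,
                           dispersion_coeff = 0.0124) {
  if (release_offshore_m < 0)
    stop("release_offshore_m must be >= 0", call. = FALSE)
  structure(list(type = "coast",
                 depth_m = pos1(depth_m, "depth_m"),
                 current_m_s = pos1(current_m_s, "current_m_s"),
                 release_offshore_m = release_offshore_m,
                 dispersion_coeff = pos1(dispersion_coeff,
                                         "dispersion_coeff")),
            class = c("coast_scenario", "water_scenario"))
}

#' @export
print.water_scenario <- function(x, ...) {
  pars <- x[setdiff(names(x), "type")]
  cat(sprintf("<%s scenario: %s>\n", x$type,
              paste(names(pars), signif(unlist(pars), 4),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Complete lateral mixing distance of a river
#'
#' Downstream distance `L = 7 * width^2 / depth` beyond which a bank
#' discharge can be considered uniformly mixed across the river
#' cross-section.
#'
#' @param scen a river scenario from [river_scenario()].
#' @return Distance in metres.
#' @export
mixing_length <- function(scen) {
  stopifnot(inherits(scen, "river_scenario"))
  7 * scen$width_m^2 / scen$depth_m
}

# Decay constant from a nuclide object or a bare non-negative numeric.
lambda_of <- function(nuclide) {
  if (inherits(nuclide, "nuclide")) return(nuclide$decay_constant)
  if (is.numeric(nuclide) && length(nuclide) == 1L && nuclide >= 0)
    return(nuclide)
  stop("nuclide must be a nuclide object or a non-negative decay constant",
       call. = FALSE)
}

#' Screening dispersion models: total water concentration at the receptor
#'
#' Steady-state analytical concentrations (total, i.e. dissolved plus
#' sorbed to suspended matter, Bq/m^3) in the receiving water for a
#' continuous release of `Q` Bq/s.  All three models are linear in `Q`
#' (`Q` may be a vector of Monte-Carlo draws).
#'
#' * **Lake/reservoir** — single well-mixed box at equilibrium:
#'   `C = Q / (outflow + lambda * volume)`; independent of receptor position.
#' * **River** — plug flow with first-order decay over the travel time:
#'   fully mixed (or opposite-shore) concentration
#'   `C = (Q / flow) * exp(-lambda * d / U)`.  A same-shore receptor closer
#'   than the complete mixing distance `L` sees the still-unmixed bank plume;
#'   the fully-mixed value is multiplied by the partial mixing factor
#'   `sqrt(L / d)` (>= 1, continuous at `d = L`).
#' * **Coast** — lateral-Gaussian plume in an alongshore current with
#'   shoreline reflection:
#'   `C = Q * exp(-lambda*x/U) / (sqrt(2*pi) * sigma_y * depth * U) *
#'   (exp(-(y-y0)^2/(2*sigma_y^2)) + exp(-(y+y0)^2/(2*sigma_y^2)))`
#'   with `sigma_y = dispersion_coeff * x^(7/6)`.
#'
#' @param Q release rate(s), Bq/s (numeric vector, >= 0).
#' @param nuclide a [nuclide] object, or a bare decay constant (1/s) —
#'   pass `0` for a stable tracer.
#' @param scen the matching `water_scenario`.
#' @param distance_m river receptor distance downstream of the outfall
#'   (m, > 0).
#' @param same_shore logical; is the river receptor on the discharge shore?
#' @param alongshore_m coastal receptor distance down-current (m, > 0).
#' @param offshore_m coastal receptor distance from the shoreline (m, >= 0).
#' @return Numeric vector of total water concentrations (Bq/m^3), same
#'   length as `Q`.
#' @examples
#' co <- nuclide("Co-60", 5.27, 5000, 3e5, 2.5)
#' lake_concentration(54, co, reservoir_scenario(2e6, 0.1))
#' @name dispersion
NULL

check_Q <- function(Q) {
  if (!is.numeric(Q) || length(Q) < 1L || any(!is.finite(Q)) || any(Q < 0))
    stop("Q must be non-negative release rate(s) in Bq/s", call. = FALSE)
  Q
}

#' @rdname dispersion
#' @export
lake_concentration <- function(Q, nuclide, scen) {
  stopifnot(inherits(scen, "lake_scenario"))
  check_Q(Q) / (scen$outflow_m3_s + lambda_of(nuclide) * scen$volume_m3)
}

#' @rdname dispersion
#' @export
river_concentration <- function(Q, nuclide, scen, distance_m,
                                same_shore = TRUE) {
  stopifnot(inherits(scen, "river_scenario"))
  check_Q(Q)
  if (!is.numeric(distance_m) || length(distance_m) != 1L || distance_m <= 0)
    stop("receptor distance must be > 0 (model not applicable at the outfall)",
         call. = FALSE)
  lambda <- lambda_of(nuclide)
  mixed <- Q / scen$flow_m3_s *
    exp(-lambda * distance_m / scen$velocity_m_s)
  L <- mixing_length(scen)
  factor <- if (isTRUE(same_shore) && distance_m < L)
    sqrt(L / distance_m) else 1
  mixed * factor
}

#' @rdname dispersion
#' @export
coastal_concentration <- function(Q, nuclide, scen, alongshore_m,
                                  offshore_m) {
  stopifnot(inherits(scen, "coast_scenario"))
  check_Q(Q)
  if (!is.numeric(alongshore_m) || length(alongshore_m) != 1L ||
      alongshore_m <= 0)
    stop("receptor must be down-current of the release (alongshore_m > 0)",
         call. = FALSE)
  if (offshore_m < 0) stop("offshore_m must be >= 0", call. = FALSE)
  lambda <- lambda_of(nuclide)
  sigma_y <- scen$dispersion_coeff * alongshore_m^(7 / 6)
  y0 <- scen$release_offshore_m
  lateral <- exp(-(offshore_m - y0)^2 / (2 * sigma_y^2)) +
    exp(-(offshore_m + y0)^2 / (2 * sigma_y^2))
  Q * exp(-lambda * alongshore_m / scen$current_m_s) * lateral /
    (sqrt(2 * pi) * sigma_y * scen$depth_m * scen$current_m_s)
}
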