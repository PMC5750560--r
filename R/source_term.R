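#' Annual discharge series
#'
#' A multi-year series of annual average liquid release rates (Bq/s) for one
#' nuclide at one facility, the raw material from which the release-rate
#' distribution is inferred.
#'
#' @param facility facility label.
#' @param nuclide nuclide label.
#' @param annual_rates numeric vector of non-negative release rates (Bq/s),
#'   one per year, at least two years.
#' @return An object of class `discharge_series`.
#' @export
discharge_series <- function(facility, nuclide, annual_rates) {
  if (!is.numeric(annual_rates) || length(annual_rates) < 2L)
    stop("annual_rates needs at least 2 years", call. = FALSE)
  if (any(!is.finite(annual_rates)) || any(annual_rates < 0))
    stop("annual_rates must be finite and non-negative", call. = FALSE)
  structure(list(facility = facility, nuclide = nuclide,
                 annual_rates = as.numeric(annual_rates)),
            class = "discharge_series")
}

#' Fit a triangular release-rate distribution to a discharge series
#'
#' Builds the source-term distribution from a short series of annual release
#' rates: the observed minimum and maximum become the triangular bounds, and
#' the series arithmetic mean is used as the central tendency estimator.
#' Two conventions for the central value are offered:
#'
#' * `"mode_is_mean"` (default): the series mean is taken directly as the
#'   triangular mode;
#' * `"match_mean"`: the mode is solved from `3 * mean - min - max` so that
#'   the distribution's expectation equals the series mean (clipped to the
#'   bounds with a warning if the solution falls outside).
#'
#' A series with zero spread degenerates to a point distribution, with a
#' warning.
#'
#' @param series a [discharge_series].
#' @param mode_convention central-tendency convention, see Details.
#' @return An object of class `source_term` with fields `nuclide` and
#'   `release_rate` (a [dist_spec], Bq/s).
#' @examples
#' s <- discharge_series("Almaraz", "Co-60", c(39, 48, 56, 61, 66))
#' fit_triangular_source(s)$release_rate
#' @export
fit_triangular_source <- function(series,
                                  mode_convention = c("mode_is_mean",
                                                      "match_mean")) {
  if (!inherits(series, "discharge_series"))
    stop("series must be a discharge_series", call. = FALSE)
  mode_convention <- match.arg(mode_convention)
  r <- series$annual_rates
  lo <- min(r); hi <- max(r); m <- mean(r)
  if (lo == hi) {
    warning("all annual rates identical for ", series$nuclide,
            "; using a point source term", call. = FALSE)
    return(source_term(series$nuclide, dist_point(lo)))
  }
  mode <- if (mode_convention == "mode_is_mean") m else {
    cand <- 3 * m - lo - hi
    if (cand < lo || cand > hi) {
      warning("match_mean mode outside [min, max]; clipping", call. = FALSE)
      cand <- min(max(cand, lo), hi)
    }
    cand
  }
  source_term(series$nuclide, dist_triangular(lo, mode, hi))
}

#' Construct a source term
#'
#' @param nuclide nuclide label.
#' @param release_rate a [dist_spec] for the release rate (Bq/s) with
#'   non-negative support.
#' @return An object of class `source_term`.
#' @export
source_term <- function(nuclide, release_rate) {
  validate_dist(release_rate)
  support_lo <- switch(release_rate$kind,
    point = release_rate$value, triangular = release_rate$min,
    lognormal = 0, uniform = release_rate$lo)
  if (support_lo < 0)
    stop("release-rate support must be non-negative", call. = FALSE)
  structure(list(nuclide = nuclide, release_rate = release_rate),
            class = "source_term")
}

#' Read discharge series from CSV and fit source terms
#'
#' Expects columns `facility,nuclide,year,rate_Bq_per_s`; one triangular
#' source term is fitted per (facility, nuclide) group.
#'
#' @param path CSV path.
#' @param mode_convention passed to [fit_triangular_source()].
#' @return Named list of [source_term] objects (one entry per facility:nuclide).
#' @export
read_discharge_csv <- function(path, mode_convention = "mode_is_mean") {
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                         stringsAsFactors = FALSE)
  required <- c("facility", "nuclide", "year", "rate_Bq_per_s")
  if (!all(required %in% names(tab)))
    stop("discharge CSV must have columns ",
         paste(required, collapse = ","), call. = FALSE)
  groups <- split(tab, paste(tab$facility, tab$nuclide, sep = ":"))
  lapply(groups, function(g)
    fit_triangular_source(
      discharge_series(g$facility[1], g$nuclide[1],
                       g$rate_Bq_per_s[order(g$year)]),
      mode_convention = mode_convention))
}
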