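# Seconds in a 365-day year; fixed for all half-life conversions at
# screening-level precision.
.YEAR_SECONDS <- 3.1536e7

#' Distribution specifications
#'
#' Lightweight sampleable one-dimensional distributions used for every
#' stochastic input of the prognosis: release rates, distribution
#' coefficients, and synthetic-data ground truths.  Four kinds are supported:
#'
#' * `dist_point(value)` — a degenerate distribution (deterministic input);
#' * `dist_triangular(min, mode, max)` — the subjective distribution used for
#'   release rates inferred from a few annual values;
#' * `dist_lognormal(gm, gsd)` — geometric mean / geometric standard
#'   deviation parameterisation, used for sediment distribution coefficients;
#' * `dist_uniform(lo, hi)`.
#'
#' All supports are non-negative for valid parameters, so sampled physical
#' quantities can never go negative.
#'
#' @param value,min,mode,max,gm,gsd,lo,hi numeric distribution parameters.
#'   Triangular requires `min <= mode <= max` and `min < max`; lognormal
#'   `gm > 0`, `gsd >= 1` (`gsd = 1` degenerates to a point at `gm`);
#'   uniform `lo < hi`.
#' @return An object of class `dist_spec`.
#' @examples
#' sample_dist(dist_triangular(39, 54, 66), 5, seed = 1)
#' dist_mean(dist_triangular(39, 54, 66))  # (39 + 54 + 66) / 3
#' @name dist_spec
NULL

new_dist <- function(kind, ...) {
  spec <- structure(c(list(kind = kind), list(...)), class = "dist_spec")
  validate_dist(spec)
  spec
}

#' @rdname dist_spec
#' @export
dist_point <- function(value) new_dist("point", value = value)

#' @rdname dist_spec
#' @export
dist_triangular <- function(min, mode, max)
  new_dist("triangular", min = min, mode = mode, max = max)

#' @rdname dist_spec
#' @export
dist_lognormal <- function(gm, gsd) new_dist("lognormal", gm = gm, gsd = gsd)

#' @rdname dist_spec
#' @export
dist_uniform <- function(lo, hi) new_dist("uniform", lo = lo, hi = hi)

#' Validate a distribution specification
#'
#' Checks the kind-specific parameter invariants and fails before any
#' sampling can occur.
#'
#' @param spec a [dist_spec] object.
#' @return `spec`, invisibly.
#' @export
validate_dist <- function(spec) {
  if (!inherits(spec, "dist_spec"))
    stop("not a dist_spec object", call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  ok <- switch(spec$kind,
    point = num1(spec$value),
    triangular = num1(spec$min) && num1(spec$mode) && num1(spec$max) &&
      spec$min <= spec$mode && spec$mode <= spec$max && spec$min < spec$max,
    lognormal = num1(spec$gm) && num1(spec$gsd) &&
      spec$gm > 0 && spec$gsd >= 1,
    uniform = num1(spec$lo) && num1(spec$hi) && spec$lo < spec$hi,
    stop("unknown distribution kind: ", spec$kind, call. = FALSE)
  )
  if (!ok)
    stop("invalid ", spec$kind, " distribution parameters", call. = FALSE)
  invisible(spec)
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat(sprintf("<dist_spec %s(%s)>\n", x$kind,
              paste(names(pars), unlist(pars), sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Closed-form mean of a distribution specification
#'
#' @param spec a [dist_spec].
#' @return The distribution mean (lognormal: `gm * exp(log(gsd)^2 / 2)`).
#' @export
dist_mean <- function(spec) {
  validate_dist(spec)
  switch(spec$kind,
    point = spec$value,
    triangular = (spec$min + spec$mode + spec$max) / 3,
    lognormal = spec$gm * exp(log(spec$gsd)^2 / 2),
    uniform = (spec$lo + spec$hi) / 2)
}

#' Central (deterministic-mode) value of a distribution specification
#'
#' The value used for deterministic, non-stochastic model runs: the point
#' value, the triangular mode, the lognormal geometric mean (= median), or
#' the uniform midpoint.
#'
#' @param spec a [dist_spec].
#' @return A single numeric value.
#' @export
dist_mode <- function(spec) {
  validate_dist(spec)
  switch(spec$kind,
    point = spec$value,
    triangular = spec$mode,
    lognormal = spec$gm,
    uniform = (spec$lo + spec$hi) / 2)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed (< 2^31 - 1) derived from a root seed and a string
# key, so each (stage, nuclide) pair gets its own reproducible stream and
# adding one nuclide never perturbs another's draws.
derive_seed <- function(root, ...) {
  key <- paste(..., sep = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(root) %% 2147483647 + h) %% 2147483647)
}

#' Draw samples from a distribution specification
#'
#' Triangular draws use the closed-form inverse CDF; lognormal draws use
#' [stats::rlnorm()] with `meanlog = log(gm)`, `sdlog = log(gsd)`.  With a
#' `seed` the draws are reproducible and the caller's RNG stream is left
#' untouched.
#'
#' @param spec a [dist_spec].
#' @param n number of draws (`>= 1`).
#' @param seed optional integer seed; `NULL` continues the current stream.
#' @return Numeric vector of `n` draws within the distribution support.
#' @export
sample_dist <- function(spec, n, seed = NULL) {
  validate_dist(spec)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a single count >= 1", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, switch(spec$kind,
    point = rep.int(spec$value, n),
    triangular = qtriangular(stats::runif(n), spec$min, spec$mode, spec$max),
    lognormal = stats::rlnorm(n, meanlog = log(spec$gm),
                              sdlog = log(spec$gsd)),
    uniform = stats::runif(n, spec$lo, spec$hi)))
}

# Inverse CDF of the triangular(a, c, b) distribution, vectorised over p.
qtriangular <- function(p, a, c, b) {
  fc <- (c - a) / (b - a)
  ifelse(p < fc,
         a + sqrt(p * (b - a) * (c - a)),
         b - sqrt((1 - p) * (b - a) * (b - c)))
}

#' Summarise Monte-Carlo draws
#'
#' Reduces a vector of draws to the statistics reported for each
#' nuclide/receptor cell: mean, sample standard deviation (n-1 denominator),
#' and the empirical 95% interval taken as the 2.5th and 97.5th percentiles
#' of the draws.
#'
#' @param draws numeric vector with at least 2 elements.
#' @param seed seed recorded alongside the summary (bookkeeping only).
#' @return A `conc_summary` list with elements `mean`, `sd`, `ci_lo`,
#'   `ci_hi`, `n`, `seed`.
#' @export
summarize_draws <- function(draws, seed = NA_integer_) {
  if (!is.numeric(draws) || length(draws) < 2L)
    stop("need at least 2 draws to summarise", call. = FALSE)
  q <- unname(stats::quantile(draws, c(0.025, 0.975)))
  structure(list(mean = mean(draws), sd = stats::sd(draws),
                 ci_lo = q[1], ci_hi = q[2],
                 n = length(draws), seed = seed),
            class = "conc_summary")
}

#' @export
print.conc_summary <- function(x, ...) {
  cat(sprintf("mean %.4g  sd %.4g  95%% (%.4g-%.4g)  n = %d\n",
              x$mean, x$sd, x$ci_lo, x$ci_hi, x$n))
  invisible(x)
}
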