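#' Measured environmental concentration range
#'
#' Environmental monitoring results are reported as ranges (lo-hi) rather
#' than single values; when every measurement fell below the detection
#' limit, `below_detection = TRUE` and lo/hi are detection limits, not
#' measurements.
#'
#' @param nuclide nuclide label.
#' @param lo,hi range bounds (Bq/kg dry, `lo <= hi`).
#' @param below_detection logical flag.
#' @param receptor optional receptor label (`NA` = applies to all receptors
#'   of the site).
#' @return One-row data frame with class `measured_range` rows semantics.
#' @export
measured_range <- function(nuclide, lo, hi, below_detection = FALSE,
                           receptor = NA_character_) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo > hi || lo < 0)
    stop("need 0 <= lo <= hi", call. = FALSE)
  data.frame(nuclide = nuclide, receptor = receptor, lo = lo, hi = hi,
             below_detection = isTRUE(below_detection),
             stringsAsFactors = FALSE)
}

#' Read measured ranges from CSV
#'
#' Columns: `nuclide,receptor,lo,hi,below_detection`; `receptor` may be
#' empty (range applies at every receptor).  `#` lines are comments.
#'
#' @param path CSV file path.
#' @return Data frame of measured ranges.
#' @export
read_measured_ranges <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                         stringsAsFactors = FALSE)
  required <- c("nuclide", "lo", "hi", "below_detection")
  if (!all(required %in% names(tab)))
    stop("measured-range CSV needs columns ",
         paste(required, collapse = ","), call. = FALSE)
  if (is.null(tab$receptor)) tab$receptor <- NA_character_
  tab$receptor[!nzchar(trimws(as.character(tab$receptor)))] <- NA_character_
  tab$below_detection <- as.logical(tab$below_detection)
  if (any(tab$lo > tab$hi)) stop("lo > hi in measured ranges", call. = FALSE)
  tab
}

#' Compare one modelled summary against one measured range
#'
#' Computes the conservatism ratios and classifies the comparison:
#'
#' * `ratio_mean_mid` — modelled mean over the midpoint of the measured
#'   range, the headline conservatism ratio;
#' * `ratio_max_max` — upper 95% bound of the model over the measured
#'   maximum.
#'
#' Verdicts at threshold `r` (default 1.5): `conservative` when
#' `ratio_mean_mid >= r`, `comparable` within `[1/r, r)`,
#' `non_conservative` below `1/r`, and `not_comparable` when the
#' measurements were below the detection limit (ratios are then `NA`).
#'
#' @param model_mean modelled mean concentration (Bq/kg).
#' @param model_ci_hi modelled upper 95% bound (Bq/kg).
#' @param lo,hi measured range (Bq/kg).
#' @param below_detection logical.
#' @param threshold classification threshold (> 1).
#' @return One-row data frame with the ratios and the `verdict`.
#' @examples
#' compare_range(51, 131, 12, 40)    # ratio 51/26 ~ 1.96, conservative
#' @export
compare_range <- function(model_mean, model_ci_hi, lo, hi,
                          below_detection = FALSE, threshold = 1.5) {
  if (threshold <= 1) stop("threshold must be > 1", call. = FALSE)
  if (below_detection)
    return(data.frame(ratio_mean_mid = NA_real_, ratio_max_max = NA_real_,
                      verdict = "not_comparable", stringsAsFactors = FALSE))
  mid <- (lo + hi) / 2
  if (mid == 0) stop("measured midpoint is zero", call. = FALSE)
  r1 <- model_mean / mid
  r2 <- if (hi > 0) model_ci_hi / hi else NA_real_
  verdict <- if (r1 >= threshold) "conservative"
             else if (r1 >= 1 / threshold) "comparable"
             else "non_conservative"
  data.frame(ratio_mean_mid = r1, ratio_max_max = r2, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Compare a prognosis against measured ranges
#'
#' Joins the modelled summaries with measured ranges by nuclide (and by
#' receptor when the measured data carry one) and computes conservatism
#' ratios and verdicts for every pair.
#'
#' @param prognosis a `sediment_prognosis` from [run_assessment()].
#' @param measured measured-range data frame ([read_measured_ranges()]).
#' @param threshold passed to [compare_range()].
#' @return Data frame with one row per matched (nuclide, receptor):
#'   modelled mean and interval, measured range, ratios and verdict.
#' @export
compare_prognosis <- function(prognosis, measured, threshold = 1.5) {
  stopifnot(inherits(prognosis, "sediment_prognosis"))
  sm <- prognosis$summary
  rows <- lapply(seq_len(nrow(sm)), function(i) {
    m <- measured[measured$nuclide == sm$nuclide[i] &
                  (is.na(measured$receptor) |
                   measured$receptor == sm$receptor[i]), ]
    if (!nrow(m)) return(NULL)
    cmp <- compare_range(sm$mean[i], sm$ci_hi[i], m$lo[1], m$hi[1],
                         m$below_detection[1], threshold)
    cbind(sm[i, c("nuclide", "receptor", "mean", "ci_lo", "ci_hi")],
          data.frame(measured_lo = m$lo[1], measured_hi = m$hi[1],
                     below_detection = m$below_detection[1]),
          cmp, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no measured range matched any modelled nuclide", call. = FALSE)
  out
}
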