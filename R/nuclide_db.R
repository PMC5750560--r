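#' Nuclide physical constants and sediment distribution coefficients
#'
#' A nuclide record carries the half-life, the decay constant derived from it
#' (`log(2) / half-life` in seconds, with a 365-day year of
#' 3.1536e7 s), and the sediment distribution coefficient (Kd, L/kg)
#' for freshwater and marine media.  Kd uncertainty is represented as a
#' lognormal distribution around the tabulated geometric mean; a geometric
#' standard deviation of 1 collapses it to a point value.
#'
#' @param name nuclide label, e.g. `"Co-60"`.
#' @param half_life_y half-life in years (> 0).
#' @param kd_fresh_gm,kd_marine_gm Kd geometric means (L/kg, > 0).
#' @param kd_gsd geometric standard deviation applied to both media
#'   (`NA` falls back to a point distribution with a warning).
#' @return An object of class `nuclide` with fields `name`, `half_life_y`,
#'   `decay_constant` (1/s), `kd_freshwater`, `kd_marine` (both
#'   [dist_spec]).
#' @examples
#' co <- nuclide("Co-60", 5.27, kd_fresh_gm = 5000, kd_marine_gm = 3e5,
#'               kd_gsd = 2.5)
#' co$decay_constant  # ~4.17e-9 per second
#' @export
nuclide <- function(name, half_life_y, kd_fresh_gm, kd_marine_gm,
                    kd_gsd = NA_real_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("nuclide name must be a non-empty string", call. = FALSE)
  if (!is.numeric(half_life_y) || length(half_life_y) != 1L ||
      !is.finite(half_life_y) || half_life_y <= 0)
    stop("half_life_y must be a single positive number for ", name,
         call. = FALSE)
  kd_dist <- function(gm, medium) {
    if (!is.finite(gm) || gm <= 0)
      stop("Kd geometric mean (", medium, ") must be positive for ", name,
           call. = FALSE)
    if (is.na(kd_gsd)) {
      warning("no Kd GSD for ", name, " (", medium,
              "); using a point distribution at the geometric mean",
              call. = FALSE)
      dist_point(gm)
    } else if (kd_gsd == 1) dist_point(gm) else dist_lognormal(gm, kd_gsd)
  }
  structure(list(
    name = name,
    half_life_y = half_life_y,
    decay_constant = log(2) / (half_life_y * .YEAR_SECONDS),
    kd_freshwater = kd_dist(kd_fresh_gm, "freshwater"),
    kd_marine = kd_dist(kd_marine_gm, "marine")
  ), class = "nuclide")
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide %s  T1/2 = %g y  lambda = %.4g /s>\n",
              x$name, x$half_life_y, x$decay_constant))
  invisible(x)
}

#' Load a nuclide database from CSV
#'
#' Reads a table with columns `name`, `half_life_y`,
#' `kd_fresh_gm_L_per_kg`, `kd_marine_gm_L_per_kg`, `kd_gsd` (and an
#' ignored free-text `source_note`).  Lines starting with `#` are comments.
#'
#' @param path CSV file path; the default is the table shipped with the
#'   package (Co-60, Cs-137, Sr-90).
#' @return A named list of [nuclide] objects, keyed by nuclide name.
#' @export
load_nuclide_db <- function(path = system.file("extdata", "nuclides.csv",
                                               package = "aquaprog")) {
  if (!file.exists(path)) stop("nuclide DB not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                         stringsAsFactors = FALSE)
  required <- c("name", "half_life_y", "kd_fresh_gm_L_per_kg",
                "kd_marine_gm_L_per_kg", "kd_gsd")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("nuclide DB is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$name))
    stop("duplicate nuclide name(s) in DB: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
         call. = FALSE)
  db <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    tryCatch(
      nuclide(row$name, row$half_life_y,
              kd_fresh_gm = row$kd_fresh_gm_L_per_kg,
              kd_marine_gm = row$kd_marine_gm_L_per_kg,
              kd_gsd = row$kd_gsd),
      error = function(e) stop("nuclide DB row ", i, " (", row$name, "): ",
                               conditionMessage(e), call. = FALSE))
  })
  names(db) <- tab$name
  db
}

#' Write a nuclide database to CSV
#'
#' Inverse of [load_nuclide_db()]; loading the written file reproduces the
#' same nuclide objects.
#'
#' @param db named list of [nuclide] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_nuclide_db <- function(db, path) {
  tab <- do.call(rbind, lapply(db, function(nuc) {
    gsd <- if (nuc$kd_freshwater$kind == "lognormal")
      nuc$kd_freshwater$gsd else 1
    data.frame(name = nuc$name, half_life_y = nuc$half_life_y,
               kd_fresh_gm_L_per_kg = dist_mode(nuc$kd_freshwater),
               kd_marine_gm_L_per_kg = dist_mode(nuc$kd_marine),
               kd_gsd = gsd, source_note = "")
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Kd distribution for a nuclide in the medium matching a water-body type.
kd_dist_for <- function(nuc, water_type) {
  if (water_type == "coast") nuc$kd_marine else nuc$kd_freshwater
}
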