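UNIT_TYPES <- c("cell", "colony", "coenobium", "chain", "filament_100um")

SEA_AREAS <- c("BS", "AS", "wGF", "eGF")

OBS_COLUMNS <- c("sample_id", "taxon_id", "unit_type", "units_per_litre",
                 "cells_per_unit", "biovolume_per_unit", "biomass",
                 "max_dimension")

#' Read counting-unit observations
#'
#' One row per taxon and counting-unit type in a sample: abundance
#' (units per litre), cells per counting unit, biovolume per unit
#' (\eqn{\mu m^3}), wet-weight biomass (\eqn{\mu g\,L^{-1}}) and the maximum
#' morphometric dimension of the counting unit (\eqn{\mu m}).
#'
#' @param path CSV path with columns \code{sample_id, taxon_id, unit_type,
#'   units_per_litre, cells_per_unit, biovolume_per_unit, biomass,
#'   max_dimension}.
#' @return validated observation data frame.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observations file not found: ", path)
  obs <- read.csv(path, stringsAsFactors = FALSE)
  validate_observations(obs)
}

#' Validate an observation table
#'
#' @param obs data frame with the observation schema (see
#'   \code{\link{read_observations}}).
#' @return the validated data frame.
#' @export
validate_observations <- function(obs) {
  missing_cols <- setdiff(OBS_COLUMNS, names(obs))
  if (length(missing_cols) > 0)
    stop("observations are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  num_cols <- c("units_per_litre", "cells_per_unit", "biovolume_per_unit",
                "biomass", "max_dimension")
  for (cl in num_cols) {
    obs[[cl]] <- as.numeric(obs[[cl]])
    if (anyNA(obs[[cl]])) stop("non-numeric or missing values in ", cl)
  }
  bad_unit <- setdiff(unique(obs$unit_type), UNIT_TYPES)
  if (length(bad_unit) > 0)
    stop("unknown unit_type token(s): ", paste(bad_unit, collapse = ", "))
  if (any(obs$units_per_litre < 0)) stop("negative units_per_litre")
  if (any(obs$cells_per_unit < 1)) stop("cells_per_unit must be >= 1")
  if (any(obs$biovolume_per_unit < 0)) stop("negative biovolume_per_unit")
  if (any(obs$biomass < 0)) stop("negative biomass")
  if (any(obs$max_dimension <= 0)) stop("max_dimension must be positive")
  bad_cell <- obs$unit_type == "cell" & obs$cells_per_unit != 1
  if (any(bad_cell))
    stop("unit_type 'cell' requires cells_per_unit = 1 (",
         sum(bad_cell), " violating row(s))")
  obs
}

#' Read sample (station) metadata
#'
#' @param path CSV with columns \code{sample_id, station_id, water_body_id,
#'   sea_area, date} (ISO-8601 dates). Stations must nest in exactly one
#'   water body and water bodies in exactly one sea area.
#' @param window_start,window_end month-day bounds (\code{"MM-DD"}) of the
#'   mid/late-summer sampling window used to flag samples.
#' @return data frame with parsed \code{date} and a logical
#'   \code{in_window} column.
#' @export
read_samples <- function(path, window_start = "07-01", window_end = "09-15") {
  if (!file.exists(path)) stop("sample metadata file not found: ", path)
  smp <- read.csv(path, stringsAsFactors = FALSE)
  validate_samples(smp, window_start = window_start, window_end = window_end)
}

#' Validate sample metadata
#'
#' @inheritParams read_samples
#' @param samples data frame with the sample metadata schema.
#' @return the validated data frame with \code{in_window} added.
#' @export
validate_samples <- function(samples, window_start = "07-01",
                             window_end = "09-15") {
  need <- c("sample_id", "station_id", "water_body_id", "sea_area", "date")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols) > 0)
    stop("sample metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample metadata")
  bad_area <- setdiff(unique(samples$sea_area), SEA_AREAS)
  if (length(bad_area) > 0)
    stop("unknown sea_area token(s): ", paste(bad_area, collapse = ", "))
  # nesting: each station in one water body, each water body in one area
  st <- unique(samples[, c("station_id", "water_body_id")])
  if (anyDuplicated(st$station_id))
    stop("station(s) assigned to more than one water body: ",
         paste(st$station_id[duplicated(st$station_id)], collapse = ", "))
  wb <- unique(samples[, c("water_body_id", "sea_area")])
  if (anyDuplicated(wb$water_body_id))
    stop("water body(ies) assigned to more than one sea area: ",
         paste(wb$water_body_id[duplicated(wb$water_body_id)], collapse = ", "))
  samples$date <- as.Date(samples$date)
  if (anyNA(samples$date)) stop("unparseable date(s) in sample metadata")
  md <- format(samples$date, "%m-%d")
  samples$in_window <- md >= window_start & md <= window_end
  samples
}

#' Apply the standard exclusion filters to observations
#'
#' Removes records whose taxon carries an exclusion category in the trait
#' table: heterotrophs, akinetes, heterocytes, cysts, mainly
#' benthic/littoral taxa, single-celled picoplankton and
#' \emph{Synechococcus} (the latter two because light microscopy of
#' Lugol's-preserved samples cannot enumerate them reliably).
#' \emph{Anabaena} counting results are retained: the name was historically
#' used for pelagic \emph{Dolichospermum} taxa, so those records carry no
#' exclusion category. Filtering is a pure selection: retained records are
#' returned unchanged.
#'
#' @param observations validated observation data frame.
#' @param table a \code{trait_table} covering all observed taxa.
#' @return list with \code{observations} (retained rows) and \code{report}
#'   (named integer vector of rows removed per exclusion category), of class
#'   \code{exclusion_report}.
#' @export
apply_exclusion_filters <- function(observations, table) {
  validate_coverage(table, observations)
  cat_by_taxon <- setNames(table$excluded_category, table$taxon_id)
  categ <- cat_by_taxon[observations$taxon_id]
  drop <- !is.na(categ)
  report <- integer(length(EXCLUDED_CATEGORIES))
  names(report) <- EXCLUDED_CATEGORIES
  if (any(drop)) {
    tab <- table(factor(categ[drop], levels = EXCLUDED_CATEGORIES))
    report[names(tab)] <- as.integer(tab)
  }
  kept <- observations[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0)
    warning("all observations removed by exclusion filters")
  structure(list(observations = kept, report = report),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion filter report:", sum(x$report), "row(s) removed,",
      nrow(x$observations), "retained\n")
  for (nm in names(x$report))
    if (x$report[[nm]] > 0) cat("  ", nm, ": ", x$report[[nm]], "\n", sep = "")
  invisible(x)
}

#' Write an exclusion report to JSON
#'
#' @param report an \code{exclusion_report}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(list(removed = as.list(report$report),
                            retained_rows = nrow(report$observations)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Convert biovolume concentration to wet-weight biomass
#'
#' Uses the standard wet-weight convention of a unit density of
#' 1 g cm\eqn{^{-3}}, i.e. \eqn{10^{-6}} \eqn{\mu g} per \eqn{\mu m^3}:
#' biomass (\eqn{\mu g\,L^{-1}}) = biovolume (\eqn{\mu m^3 L^{-1}}) \eqn{\times}
#' \code{density}. The conversion is linear and monotone.
#'
#' @param biovolume_per_litre biovolume concentration, \eqn{\mu m^3 L^{-1}},
#'   non-negative.
#' @param density conversion factor in \eqn{\mu g\,\mu m^{-3}}; default
#'   \code{1e-6} (1 g cm\eqn{^{-3}}).
#' @return biomass in \eqn{\mu g\,L^{-1}}.
#' @examples
#' convert_biomass(1e6)   # 1 ug/L
#' convert_biomass(5e8)   # 500 ug/L
#' @export
convert_biomass <- function(biovolume_per_litre, density = 1e-6) {
  if (any(biovolume_per_litre < 0)) stop("negative biovolume")
  biovolume_per_litre * density
}
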