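#' Small/large size classification of a counting unit
#'
#' A counting unit (cell, colony, coenobium, chain or 100 um filament piece)
#' is classified by its maximum morphometric dimension: \code{small} if
#' \eqn{\le} 10 um (boundary inclusive), \code{large} otherwise. Note the
#' classification applies to the whole counting unit, so a colony of small
#' cells can be large.
#'
#' @param max_dimension maximum morphometric measure of the counting unit,
#'   um, positive.
#' @param threshold class boundary in um (default 10).
#' @return factor with levels \code{small, large}.
#' @examples
#' classify_size(c(10, 10.1, 40))
#' @export
classify_size <- function(max_dimension, threshold = 10) {
  if (any(max_dimension <= 0)) stop("max_dimension must be positive")
  factor(ifelse(max_dimension <= threshold, "small", "large"),
         levels = c("small", "large"))
}

#' Biovolume of a single cell within a counting unit
#'
#' @param biovolume_per_unit biovolume of the counting unit, \eqn{\mu m^3}.
#' @param cells_per_unit number of cells in the counting unit, \eqn{\ge 1}.
#' @return per-cell biovolume, \eqn{\mu m^3}.
#' @export
per_cell_biovolume <- function(biovolume_per_unit, cells_per_unit) {
  if (any(biovolume_per_unit < 0)) stop("negative biovolume")
  if (any(cells_per_unit < 1)) stop("cells_per_unit must be >= 1")
  biovolume_per_unit / cells_per_unit
}

#' Volume of a sphere of given diameter
#'
#' @param diameter sphere diameter, um.
#' @return volume, \eqn{\mu m^3}.
#' @export
sphere_volume <- function(diameter) {
  if (any(diameter < 0)) stop("negative diameter")
  pi / 6 * diameter^3
}

#' Equivalent spherical diameter of a cell
#'
#' Diameter of the sphere with the cell's biovolume:
#' \eqn{ESD = (6V/\pi)^{1/3}}. Zero biovolume maps to zero.
#'
#' @param per_cell_biovolume cell biovolume, \eqn{\mu m^3}, non-negative.
#' @return ESD in um.
#' @examples
#' equivalent_spherical_diameter(523.598775)  # sphere of diameter 10
#' @export
equivalent_spherical_diameter <- function(per_cell_biovolume) {
  if (any(per_cell_biovolume < 0)) stop("negative biovolume")
  (6 * per_cell_biovolume / pi)^(1 / 3)
}

#' Per-taxon size summaries within samples
#'
#' For every observation row, derives the cell density
#' (units \eqn{\times} cells per unit), the per-cell biovolume, the
#' equivalent spherical diameter and the total taxon ESD
#' (cell density \eqn{\times} ESD). When \code{cells_per_unit} is missing
#' from a row, a per-taxon default table is consulted; rows that cannot be
#' resolved raise an error (no silent defaults).
#'
#' @param observations validated observation data frame.
#' @param cells_per_unit_defaults optional data frame
#'   (\code{taxon_id, default_cells_per_unit}) used where
#'   \code{cells_per_unit} is \code{NA}.
#' @return data frame: \code{sample_id, taxon_id, cell_density,
#'   per_cell_biovolume, esd, total_taxon_esd}.
#' @export
taxon_size_summary <- function(observations, cells_per_unit_defaults = NULL) {
  cpu <- observations$cells_per_unit
  if (anyNA(cpu)) {
    if (is.null(cells_per_unit_defaults))
      stop("cells_per_unit missing for ", sum(is.na(cpu)),
           " row(s) and no defaults table supplied")
    idx <- match(observations$taxon_id[is.na(cpu)],
                 cells_per_unit_defaults$taxon_id)
    if (anyNA(idx))
      stop("cells_per_unit missing and no default for taxa: ",
           paste(unique(observations$taxon_id[is.na(cpu)][is.na(idx)]),
                 collapse = ", "))
    cpu[is.na(cpu)] <- cells_per_unit_defaults$default_cells_per_unit[idx]
  }
  pcv <- per_cell_biovolume(observations$biovolume_per_unit, cpu)
  data.frame(sample_id = observations$sample_id,
             taxon_id = observations$taxon_id,
             cell_density = observations$units_per_litre * cpu,
             per_cell_biovolume = pcv,
             esd = equivalent_spherical_diameter(pcv),
             stringsAsFactors = FALSE) -> out
  out$total_taxon_esd <- out$cell_density * out$esd
  out
}

#' Cell-count-weighted average equivalent spherical diameter of a sample
#'
#' The sum of total taxon ESDs divided by the total cell number:
#' \eqn{aveESD = \sum_i n_i d_i / \sum_i n_i} where \eqn{n_i} is the cell
#' density of taxon \eqn{i} and \eqn{d_i} its ESD. Cells with recorded zero
#' biovolume contribute zero to the numerator; whether they count in the
#' denominator is controlled by \code{include_zero_volume_cells} (such rows
#' trigger a data warning either way).
#'
#' @param summaries data frame from \code{\link{taxon_size_summary}} (one
#'   sample, or grouped externally).
#' @param include_zero_volume_cells logical; keep zero-biovolume cells in
#'   the denominator (default \code{TRUE}).
#' @return aveESD in um.
#' @examples
#' s <- data.frame(sample_id = "a", taxon_id = c("t1", "t2"),
#'                 cell_density = c(300, 100), per_cell_biovolume = c(1, 1),
#'                 esd = c(2, 10), total_taxon_esd = c(600, 1000))
#' sample_ave_esd(s)  # 4
#' @export
sample_ave_esd <- function(summaries, include_zero_volume_cells = TRUE) {
  zero_vol <- summaries$per_cell_biovolume == 0 & summaries$cell_density > 0
  if (any(zero_vol))
    warning(sum(zero_vol),
            " row(s) have cells but zero biovolume; they contribute no ESD")
  keep <- if (include_zero_volume_cells) rep(TRUE, nrow(summaries)) else !zero_vol
  total_cells <- sum(summaries$cell_density[keep])
  if (!is.finite(total_cells) || total_cells <= 0)
    stop("total cell count is zero; aveESD undefined")
  sum(summaries$total_taxon_esd[keep]) / total_cells
}

#' Per-sample morphometric statistics
#'
#' @inheritParams taxon_size_summary
#' @inheritParams sample_ave_esd
#' @return data frame: \code{sample_id, ave_esd, total_cells}.
#' @export
sample_morphometrics <- function(observations, cells_per_unit_defaults = NULL,
                                 include_zero_volume_cells = TRUE) {
  ss <- taxon_size_summary(observations, cells_per_unit_defaults)
  parts <- split(ss, ss$sample_id)
  out <- data.frame(
    sample_id = names(parts),
    ave_esd = vapply(parts, sample_ave_esd, numeric(1),
                     include_zero_volume_cells = include_zero_volume_cells),
    total_cells = vapply(parts, function(p) sum(p$cell_density), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
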