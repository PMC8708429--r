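#' @importFrom stats aggregate as.formula coef median pnorm pt ptukey qnorm
#'   rbinom rlnorm rnorm runif sd setNames var vcov predict
#' @importFrom utils read.csv write.csv
NULL

TRAIT_FLAGS <- c("n_fixation", "mixotrophy", "motility", "buoyancy", "harmful")

TRAIT_RANKS <- c("species", "genus", "order", "higher")
TRAIT_GROUPS <- c("cyanobacteria", "eukaryote")
EXCLUDED_CATEGORIES <- c("heterotroph", "akinete", "heterocyte", "cyst",
                         "benthic_littoral", "picoplankton_single",
                         "synechococcus")

TRAIT_TABLE_COLUMNS <- c("taxon_id", "taxon_name", "rank", "parent_genus",
                         "group", TRAIT_FLAGS, "excluded_category",
                         "override_note")

#' Read a taxon trait table
#'
#' Reads a CSV trait table holding one row per taxon with binary
#' morpho-functional trait flags (nitrogen fixation, mixotrophy, motility,
#' buoyancy, harmfulness), taxonomic rank, group (cyanobacteria vs eukaryote)
#' and an optional exclusion category used by the observation filters.
#' Records above species rank may carry overrides in \code{override_note}
#' (semicolon-separated \code{trait=0/1} assignments) which take precedence
#' over the genus-level OR rule applied by \code{\link{assign_traits}}.
#'
#' @param path path to a CSV file with columns \code{taxon_id, taxon_name,
#'   rank, parent_genus, group, n_fixation, mixotrophy, motility, buoyancy,
#'   harmful, excluded_category, override_note}; trait flags coded 0/1,
#'   optional fields empty.
#' @param version optional version string attached to the table.
#' @return an object of class \code{trait_table}: a data frame of validated
#'   records with a \code{version} attribute.
#' @examples
#' tt <- load_trait_table(system.file("extdata", "example_trait_table.csv",
#'                                    package = "planktraits"))
#' nrow(tt)
#' @export
load_trait_table <- function(path, version = NA_character_) {
  if (!file.exists(path)) stop("trait table file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", na.strings = c("NA", ""))
  missing_cols <- setdiff(TRAIT_TABLE_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[, TRAIT_TABLE_COLUMNS]
  for (fl in TRAIT_FLAGS) {
    v <- raw[[fl]]
    if (!all(v %in% c("0", "1")))
      stop("trait flag '", fl, "' must be coded 0/1")
    raw[[fl]] <- v == "1"
  }
  as_trait_table(raw, version = version)
}

#' Construct and validate a trait table from a data frame
#'
#' @param records data frame with the trait table schema (see
#'   \code{\link{load_trait_table}}); trait flags logical or 0/1.
#' @param version optional version string.
#' @return a \code{trait_table}.
#' @export
as_trait_table <- function(records, version = NA_character_) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRAIT_TABLE_COLUMNS, names(records))
  if (length(missing_cols) > 0)
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  records <- records[, TRAIT_TABLE_COLUMNS]
  for (fl in TRAIT_FLAGS) records[[fl]] <- as.logical(records[[fl]])
  if (nrow(records) == 0) {
    warning("trait table has a header but no records")
  } else {
    dup <- records$taxon_id[duplicated(records$taxon_id)]
    if (length(dup) > 0)
      stop("duplicated taxon_id in trait table: ",
           paste(unique(dup), collapse = ", "))
    bad_rank <- setdiff(unique(records$rank), TRAIT_RANKS)
    if (length(bad_rank) > 0)
      stop("unknown rank token(s): ", paste(bad_rank, collapse = ", "))
    bad_group <- setdiff(unique(records$group), TRAIT_GROUPS)
    if (length(bad_group) > 0)
      stop("unknown group token(s): ", paste(bad_group, collapse = ", "))
    bad_excl <- setdiff(unique(records$excluded_category),
                        c(NA, EXCLUDED_CATEGORIES))
    if (length(bad_excl) > 0)
      stop("unknown excluded_category token(s): ",
           paste(bad_excl, collapse = ", "))
    if (anyNA(records[TRAIT_FLAGS]))
      stop("trait flags must not be missing")
  }
  rownames(records) <- NULL
  structure(records, version = version,
            class = c("trait_table", "data.frame"))
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Taxon trait table:", nrow(x), "records",
      if (!is.na(attr(x, "version"))) paste0("(version ", attr(x, "version"), ")"),
      "\n")
  cat("  ranks:  ", paste(names(table(x$rank)), table(x$rank),
                          sep = ":", collapse = "  "), "\n")
  cat("  excluded records:", sum(!is.na(x$excluded_category)), "\n")
  invisible(x)
}

#' Write a trait table to CSV
#'
#' @param table a \code{trait_table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trait_table <- function(table, path) {
  out <- as.data.frame(table)
  for (fl in TRAIT_FLAGS) out[[fl]] <- as.integer(out[[fl]])
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# Parse "trait=0;trait=1" override assignments out of override_note.
# Free text after a '#' is ignored.
parse_overrides <- function(note) {
  if (is.na(note) || !nzchar(note)) return(list())
  note <- sub("#.*$", "", note)
  parts <- strsplit(note, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2 || !(trimws(kv[1]) %in% TRAIT_FLAGS) ||
        !(trimws(kv[2]) %in% c("0", "1")))
      stop("malformed override assignment: '", p, "'")
    out[[trimws(kv[1])]] <- trimws(kv[2]) == "1"
  }
  out
}

#' Resolve trait flags for one observed taxon
#'
#' Species-rank records report their own flags. Records above species rank
#' (genus, order, higher) are treated as potential carriers of a trait if any
#' member species in the table carries it (logical OR over records whose
#' \code{parent_genus} matches the record's name), unless an explicit
#' override in the table's \code{override_note} fixes the flag. Overrides
#' always win; this is how table-level exceptions such as non-buoyant
#' \emph{Snowella} spp. or harmful \emph{Aphanizomenon} spp. are encoded.
#' Order- and higher-rank records are resolved from their own row plus
#' overrides (no member enumeration).
#'
#' @param taxon_id taxon identifier, present in \code{table}.
#' @param table a \code{trait_table}.
#' @return named list: logical \code{n_fixation, mixotrophy, motility,
#'   buoyancy, harmful}, plus \code{group}, \code{rank} and
#'   \code{excluded_category}.
#' @export
assign_traits <- function(taxon_id, table) {
  stopifnot(inherits(table, "trait_table"))
  i <- match(taxon_id, table$taxon_id)
  if (is.na(i))
    stop("taxon not found in trait table: '", taxon_id, "'")
  rec <- table[i, ]
  flags <- as.list(rec[TRAIT_FLAGS])
  flags <- lapply(flags, as.logical)
  if (rec$rank == "genus") {
    members <- table[!is.na(table$parent_genus) &
                     table$parent_genus == rec$taxon_name &
                     table$rank == "species", , drop = FALSE]
    if (nrow(members) > 0)
      for (fl in TRAIT_FLAGS)
        flags[[fl]] <- flags[[fl]] || any(members[[fl]])
  }
  ov <- parse_overrides(rec$override_note)
  for (fl in names(ov)) flags[[fl]] <- ov[[fl]]
  c(flags,
    list(group = rec$group, rank = rec$rank,
         excluded_category = rec$excluded_category))
}

#' Resolve trait flags for every record of a table
#'
#' Vectorized companion of \code{\link{assign_traits}}: applies the
#' genus-level OR rule and overrides to all records at once.
#'
#' @param table a \code{trait_table}.
#' @return data frame with one row per record: \code{taxon_id}, resolved
#'   logical trait flags, \code{group}, \code{excluded_category}, and the
#'   three-way harmfulness class (\code{hab_class}).
#' @export
resolve_traits <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  out <- data.frame(taxon_id = table$taxon_id,
                    group = table$group,
                    excluded_category = table$excluded_category,
                    stringsAsFactors = FALSE)
  for (fl in TRAIT_FLAGS) out[[fl]] <- table[[fl]]
  is_genus <- table$rank == "genus"
  if (any(is_genus)) {
    sp <- table[table$rank == "species" & !is.na(table$parent_genus), ,
                drop = FALSE]
    if (nrow(sp) > 0) {
      for (fl in TRAIT_FLAGS) {
        carrier_genera <- unique(sp$parent_genus[sp[[fl]]])
        hit <- is_genus & table$taxon_name %in% carrier_genera
        out[[fl]] <- out[[fl]] | hit
      }
    }
  }
  for (i in which(!is.na(table$override_note) & nzchar(table$override_note))) {
    ov <- parse_overrides(table$override_note[i])
    for (fl in names(ov)) out[[fl]][i] <- ov[[fl]]
  }
  out <- out[, c("taxon_id", TRAIT_FLAGS, "group", "excluded_category")]
  out$hab_class <- harmful_partition(out$harmful, out$group)
  out
}

#' Three-way harmfulness partition
#'
#' Splits the harmfulness trait by major group: harmful cyanobacteria
#' (\code{HABcyano}), harmful eukaryotic phytoplankton (\code{HABalg}) and
#' everything else (\code{nonHAB}). The partition is exhaustive and
#' exclusive.
#'
#' @param harmful logical vector of resolved harmfulness flags.
#' @param group character vector, \code{"cyanobacteria"} or
#'   \code{"eukaryote"}.
#' @return factor with levels \code{HABcyano, HABalg, nonHAB}.
#' @export
harmful_partition <- function(harmful, group) {
  if (length(harmful) != length(group))
    stop("harmful and group must have equal length")
  bad <- setdiff(unique(group), TRAIT_GROUPS)
  if (length(bad) > 0)
    stop("unknown group token(s): ", paste(bad, collapse = ", "))
  out <- ifelse(!harmful, "nonHAB",
                ifelse(group == "cyanobacteria", "HABcyano", "HABalg"))
  factor(out, levels = c("HABcyano", "HABalg", "nonHAB"))
}

#' Check that a trait table covers an observation table
#'
#' @param table a \code{trait_table}.
#' @param observations observation data frame with a \code{taxon_id} column.
#' @return \code{TRUE} invisibly; errors listing unresolvable taxa otherwise.
#' @export
validate_coverage <- function(table, observations) {
  missing <- setdiff(unique(observations$taxon_id), table$taxon_id)
  if (length(missing) > 0)
    stop("taxa present in observations but absent from the trait table: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
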