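# trait label -> resolved flag column, in canonical table order
TRAIT_RESPONSE_MAP <- list(
  Nfix = "n_fixation", Buo = "buoyancy", Mot = "motility", MX = "mixotrophy")

#' Canonical names of the 27 response variables
#'
#' Biomass (ug/L wet weight) and share of total biomass for each binary
#' trait and its complement (N-fixing/non-N-fixing, buoyant/non-buoyant,
#' motile/non-motile, mixotrophic/autotrophic), for the two size classes,
#' for the three-way harmfulness partition, plus the average equivalent
#' spherical diameter.
#'
#' @return character vector of length 27.
#' @export
response_names <- function() {
  pairs <- function(stem) paste(stem, c("biom", "share"))
  c(pairs("Nfix"), pairs("nonNfix"), pairs("Buo"), pairs("nonBuo"),
    pairs("Mot"), pairs("nonMot"), pairs("MX"), pairs("AU"),
    pairs("Small"), pairs("Large"), "aveESD",
    pairs("HABalg"), pairs("HABcyano"), pairs("nonHAB"))
}

#' Build the trait response matrix
#'
#' For each sample, each trait-specific biomass is the sum of the biomasses
#' of the taxa carrying the trait, and its share is that biomass divided by
#' the total sample biomass; the complementary (non-carrier) variables are
#' built analogously. Size classes are assigned per counting unit (maximum
#' dimension \eqn{\le} 10 um vs larger), harmfulness is split three ways
#' (harmful cyanobacteria, harmful eukaryotes, non-harmful), and aveESD is
#' the cell-count-weighted mean equivalent spherical diameter. Samples whose
#' total biomass is zero are dropped with a warning (shares undefined).
#'
#' @param observations filtered (post-exclusion) observation data frame.
#' @param traits resolved trait flags per taxon, from
#'   \code{\link{resolve_traits}}.
#' @param cells_per_unit_defaults optional defaults for
#'   \code{\link{taxon_size_summary}}.
#' @return data frame of class \code{response_matrix}: \code{sample_id} plus
#'   the 27 columns of \code{\link{response_names}} (shares as fractions).
#' @export
build_responses <- function(observations, traits,
                            cells_per_unit_defaults = NULL) {
  idx <- match(observations$taxon_id, traits$taxon_id)
  if (anyNA(idx))
    stop("taxa missing from resolved traits: ",
         paste(unique(observations$taxon_id[is.na(idx)]), collapse = ", "))
  obs <- observations
  for (fl in names(TRAIT_RESPONSE_MAP))
    obs[[fl]] <- traits[[TRAIT_RESPONSE_MAP[[fl]]]][idx]
  obs$hab_class <- traits$hab_class[idx]
  obs$size_class <- classify_size(obs$max_dimension)

  total <- tapply(obs$biomass, obs$sample_id, sum)
  zero <- total <= 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero total biomass dropped: ",
            paste(names(total)[zero], collapse = ", "))
    obs <- obs[!(obs$sample_id %in% names(total)[zero]), , drop = FALSE]
    total <- total[!zero]
  }
  if (length(total) == 0) stop("no samples with positive biomass")
  sids <- names(total)

  sum_by <- function(mask) {
    s <- tapply(obs$biomass[mask], factor(obs$sample_id[mask], levels = sids),
                sum)
    s[is.na(s)] <- 0
    as.numeric(s)
  }
  out <- data.frame(sample_id = sids, stringsAsFactors = FALSE)
  tot <- as.numeric(total)
  add_pair <- function(out, stem, mask) {
    b <- sum_by(mask)
    out[[paste(stem, "biom")]] <- b
    out[[paste(stem, "share")]] <- b / tot
    out
  }
  for (stem in names(TRAIT_RESPONSE_MAP)) {
    out <- add_pair(out, stem, obs[[stem]])
    non_stem <- if (stem == "MX") "AU" else paste0("non", stem)
    out <- add_pair(out, non_stem, !obs[[stem]])
  }
  out <- add_pair(out, "Small", obs$size_class == "small")
  out <- add_pair(out, "Large", obs$size_class == "large")
  morpho <- sample_morphometrics(obs[, OBS_COLUMNS],
                                 cells_per_unit_defaults)
  out$aveESD <- morpho$ave_esd[match(out$sample_id, morpho$sample_id)]
  out <- add_pair(out, "HABalg", obs$hab_class == "HABalg")
  out <- add_pair(out, "HABcyano", obs$hab_class == "HABcyano")
  out <- add_pair(out, "nonHAB", obs$hab_class == "nonHAB")

  out <- out[, c("sample_id", response_names())]
  rownames(out) <- NULL
  class(out) <- c("response_matrix", "data.frame")
  out
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Trait response matrix:", nrow(x), "samples x",
      ncol(x) - 1, "responses\n")
  invisible(x)
}

#' Profile-likelihood Box-Cox exponent
#'
#' Maximizes the Box-Cox profile log-likelihood
#' \eqn{-\frac{n}{2}\log\hat\sigma^2(\lambda) + (\lambda-1)\sum\log y} over
#' a grid of \eqn{\lambda \in [-2, 2]} with step 0.01.
#'
#' @param values positive observations (after any shift).
#' @param grid candidate exponents.
#' @return the maximizing \eqn{\lambda}.
#' @export
boxcox_lambda <- function(values, grid = seq(-2, 2, by = 0.01)) {
  if (any(values <= 0)) stop("Box-Cox requires positive values")
  if (length(unique(values)) < 2) stop("constant input; Box-Cox undefined")
  n <- length(values)
  slog <- sum(log(values))
  ll <- vapply(grid, function(lam) {
    z <- if (abs(lam) < 1e-12) log(values) else (values^lam - 1) / lam
    s2 <- sum((z - mean(z))^2) / n
    -n / 2 * log(s2) + (lam - 1) * slog
  }, numeric(1))
  grid[which.max(ll)]
}

#' Box-Cox power transformation
#'
#' \eqn{(y + shift)^\lambda - 1)/\lambda}, the natural logarithm at
#' \eqn{\lambda = 0}.
#'
#' @param values observations.
#' @param lambda exponent.
#' @param shift non-negative shift making all values positive.
#' @return transformed values.
#' @export
boxcox_transform <- function(values, lambda, shift = 0) {
  y <- values + shift
  if (any(y <= 0)) stop("values + shift must be positive")
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Inverse Box-Cox transformation
#'
#' @param transformed transformed values.
#' @inheritParams boxcox_transform
#' @return values on the original scale.
#' @export
boxcox_inverse <- function(transformed, lambda, shift = 0) {
  y <- if (abs(lambda) < 1e-12) exp(transformed) else
    (transformed * lambda + 1)^(1 / lambda)
  y - shift
}

#' Fit a Box-Cox transformation to one response
#'
#' Responses containing zeros receive a shift of half the smallest positive
#' value before the exponent is profiled; strictly positive responses are
#' not shifted.
#'
#' @param values non-negative observations.
#' @return list of class \code{boxcox_fit}: \code{lambda}, \code{shift},
#'   \code{transformed}.
#' @export
boxcox_fit <- function(values) {
  if (any(values < 0)) stop("negative values; Box-Cox undefined")
  shift <- 0
  if (any(values == 0)) {
    pos <- values[values > 0]
    if (length(pos) == 0) stop("all-zero response; Box-Cox undefined")
    shift <- min(pos) / 2
  }
  lambda <- boxcox_lambda(values + shift)
  structure(list(lambda = lambda, shift = shift,
                 transformed = boxcox_transform(values, lambda, shift)),
            class = "boxcox_fit")
}

#' Box-Cox transform every response column
#'
#' @param responses a \code{response_matrix}.
#' @param skip character vector of response names to leave untransformed.
#' @return list: \code{transformed} (data frame, same shape) and \code{meta}
#'   (data frame of per-response \code{lambda} and \code{shift}; \code{NA}
#'   for skipped columns).
#' @export
transform_responses <- function(responses, skip = character(0)) {
  stopifnot(inherits(responses, "response_matrix"))
  out <- as.data.frame(responses)
  meta <- data.frame(response = response_names(), lambda = NA_real_,
                     shift = NA_real_, stringsAsFactors = FALSE)
  for (nm in setdiff(response_names(), skip)) {
    bc <- boxcox_fit(out[[nm]])
    out[[nm]] <- bc$transformed
    meta[meta$response == nm, c("lambda", "shift")] <- c(bc$lambda, bc$shift)
  }
  list(transformed = out, meta = meta)
}

#' Write Box-Cox metadata to JSON
#'
#' @param meta the \code{meta} element of \code{\link{transform_responses}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_transform_meta <- function(meta, path) {
  jsonlite::write_json(meta, path, dataframe = "rows", na = "null")
  invisible(path)
}
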