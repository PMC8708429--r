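LOADING_SOURCES <- c("river", "point", "sediment", "offshore")

# dominant N source / dominant P source -> loading type 1-5
LOADING_TYPE_MAP <- data.frame(
  n_dominant = c("offshore", "river", "river", "river", "river"),
  p_dominant = c("offshore", "point", "offshore", "river", "sediment"),
  loading_type = 1:5,
  stringsAsFactors = FALSE)

#' Surface-layer mean of a profiled variable
#'
#' Unweighted arithmetic mean of measurements taken at 0-10 m depth. For
#' stations shallower than 10 m the entire water column is used.
#'
#' @param depth measurement depths, m.
#' @param value measured values (same length as \code{depth}).
#' @param max_depth surface-layer bound, m (default 10).
#' @param bottom_depth optional station bottom depth, m; when smaller than
#'   \code{max_depth} all measurements are used.
#' @return the surface-layer mean.
#' @examples
#' surface_layer_mean(c(0, 5, 10), c(18, 16, 14))  # 16
#' @export
surface_layer_mean <- function(depth, value, max_depth = 10,
                               bottom_depth = NULL) {
  if (length(depth) != length(value))
    stop("depth and value must have equal length")
  ok <- !is.na(value)
  use <- if (!is.null(bottom_depth) && bottom_depth < max_depth)
    ok else ok & depth <= max_depth
  if (!any(use)) stop("no usable measurements in the surface layer")
  mean(value[use])
}

#' Seawater density at atmospheric pressure (EOS-80)
#'
#' One-atmosphere density from the UNESCO EOS-80 polynomial: the pure-water
#' term of Bigg plus the Millero & Poisson salinity correction. The pressure
#' term is omitted (surface and shallow coastal use). Published check
#' values: 999.96675 kg m\eqn{^{-3}} at (5 degC, 0 psu) and 1027.67547
#' kg m\eqn{^{-3}} at (5 degC, 35 psu).
#'
#' @param temperature degC, in [-2, 40].
#' @param salinity practical salinity, psu, in [0, 42].
#' @return density \eqn{\sigma} in kg m\eqn{^{-3}}.
#' @examples
#' water_density(5, 0)
#' water_density(5, 35)
#' @export
water_density <- function(temperature, salinity) {
  if (any(temperature < -2 | temperature > 40))
    stop("temperature outside [-2, 40] degC")
  if (any(salinity < 0 | salinity > 42))
    stop("salinity outside [0, 42] psu")
  t <- temperature
  s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  rho_w + a * s + b * s^1.5 + 4.8314e-4 * s^2
}

#' Stratification index of the water column
#'
#' \eqn{E = (\sigma_{bottom} - \sigma_{surface}) \times 1000 / depth},
#' where the densities (kg m\eqn{^{-3}}) come from the surface-layer and the
#' deepest temperature/salinity measurement, and \code{depth_deepest} is the
#' depth of that deepest measurement. Larger values mean stronger
#' stratification; negative values indicate an unstable column. The
#' \eqn{\times 1000} scaling is kept as conventionally printed; the unit is
#' carried opaquely.
#'
#' @param sigma_surface surface density, kg m\eqn{^{-3}}.
#' @param sigma_bottom near-bottom density, kg m\eqn{^{-3}}.
#' @param depth_deepest depth of the deepest T/S measurement, m, positive.
#' @return the stratification index E.
#' @examples
#' stratification_index(1002, 1004.5, 25)  # 100
#' @export
stratification_index <- function(sigma_surface, sigma_bottom, depth_deepest) {
  if (any(depth_deepest <= 0)) stop("depth_deepest must be positive")
  (sigma_bottom - sigma_surface) * 1000 / depth_deepest
}

#' Classify a water body by its dominant nutrient loading sources
#'
#' The dominant (argmax) N source and dominant P source are mapped to one of
#' five loading source types: (1) N and P mainly from offshore; (2) N from
#' rivers, P from a point source; (3) N from rivers, P from offshore;
#' (4) N and P from rivers; (5) N from rivers, P from the sediment.
#' Combinations outside this enumeration, and ties in the argmax, are
#' errors: the typology presupposes clear dominance.
#'
#' @param n_shares named numeric vector of N loading shares over
#'   \code{river, point, sediment, offshore}; must sum to 1 (tolerance 1e-6).
#' @param p_shares same for P.
#' @return integer loading type in 1..5.
#' @examples
#' classify_loading_source(
#'   c(river = 0.8, point = 0.1, sediment = 0.05, offshore = 0.05),
#'   c(river = 0.2, point = 0.1, sediment = 0.6, offshore = 0.1))  # 5
#' @export
classify_loading_source <- function(n_shares, p_shares) {
  dom <- function(shares, nutrient) {
    if (!setequal(names(shares), LOADING_SOURCES))
      stop(nutrient, " shares must be named over: ",
           paste(LOADING_SOURCES, collapse = ", "))
    shares <- shares[LOADING_SOURCES]
    if (any(shares < 0 | shares > 1))
      stop(nutrient, " shares must lie in [0, 1]")
    if (abs(sum(shares) - 1) > 1e-6)
      stop(nutrient, " shares must sum to 1 (got ", sum(shares), ")")
    mx <- max(shares)
    hit <- names(shares)[shares == mx]
    if (length(hit) > 1)
      stop("tie in dominant ", nutrient, " source: ",
           paste(hit, collapse = ", "))
    hit
  }
  nd <- dom(n_shares, "N")
  pd <- dom(p_shares, "P")
  i <- which(LOADING_TYPE_MAP$n_dominant == nd & LOADING_TYPE_MAP$p_dominant == pd)
  if (length(i) == 0)
    stop("dominant-source combination (N: ", nd, ", P: ", pd,
         ") is outside the five loading source types")
  LOADING_TYPE_MAP$loading_type[i]
}

#' Read depth-profile measurements
#'
#' @param path CSV with columns \code{sample_id, depth, temperature,
#'   salinity, tp} (TP optional per depth, may be \code{NA}).
#' @return validated data frame.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profiles file not found: ", path)
  pr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "depth", "temperature", "salinity", "tp")
  missing_cols <- setdiff(need, names(pr))
  if (length(missing_cols) > 0)
    stop("profiles are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(pr$depth < 0)) stop("negative depth")
  dup <- duplicated(pr[, c("sample_id", "depth")])
  if (any(dup)) stop("duplicated depth within a sample profile")
  pr
}

#' Read Secchi depths
#'
#' @param path CSV with columns \code{sample_id, secchi} (m).
#' @return data frame.
#' @export
read_secchi <- function(path) {
  if (!file.exists(path)) stop("Secchi file not found: ", path)
  sc <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "secchi") %in% names(sc)))
    stop("Secchi file needs columns sample_id, secchi")
  if (any(sc$secchi <= 0)) stop("Secchi depth must be positive")
  sc
}

#' Read water-body nutrient loading shares
#'
#' @param path CSV with columns \code{water_body_id, nutrient, river, point,
#'   sediment, offshore}; one row per water body and nutrient
#'   (\code{"N"} or \code{"P"}), shares summing to 1.
#' @return data frame.
#' @export
read_loading_shares <- function(path) {
  if (!file.exists(path)) stop("loading shares file not found: ", path)
  ls <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("water_body_id", "nutrient", LOADING_SOURCES)
  missing_cols <- setdiff(need, names(ls))
  if (length(missing_cols) > 0)
    stop("loading shares are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(ls$nutrient %in% c("N", "P")))
    stop("nutrient must be 'N' or 'P'")
  sums <- rowSums(ls[, LOADING_SOURCES])
  if (any(abs(sums - 1) > 1e-6))
    stop("loading shares must sum to 1 per water body and nutrient")
  ls
}

#' Loading type per water body
#'
#' @param loading_shares data frame as returned by
#'   \code{\link{read_loading_shares}}.
#' @return data frame \code{water_body_id, loading_type}.
#' @export
classify_loading_types <- function(loading_shares) {
  wbs <- unique(loading_shares$water_body_id)
  lt <- vapply(wbs, function(wb) {
    rows <- loading_shares[loading_shares$water_body_id == wb, ]
    n <- rows[rows$nutrient == "N", LOADING_SOURCES]
    p <- rows[rows$nutrient == "P", LOADING_SOURCES]
    if (nrow(n) != 1 || nrow(p) != 1)
      stop("water body ", wb, " needs exactly one N and one P share row")
    classify_loading_source(unlist(n), unlist(p))
  }, integer(1))
  data.frame(water_body_id = wbs, loading_type = lt, stringsAsFactors = FALSE)
}

#' Per-sample hydrographic summary
#'
#' For every sample: surface-layer (0-10 m) means of temperature, salinity
#' and TP; surface and near-bottom EOS-80 densities; the stratification
#' index E from the deepest joint temperature/salinity measurement; Secchi
#' depth; and, when loading shares and sample metadata are given, the water
#' body's loading source type.
#'
#' @param profiles depth-profile data frame (see \code{\link{read_profiles}}).
#' @param secchi data frame \code{sample_id, secchi}.
#' @param samples optional sample metadata (for water body lookup).
#' @param loading_shares optional loading-share data frame.
#' @param bottom_depths optional data frame \code{sample_id, bottom_depth}
#'   used for the shallow-station rule; defaults to the deepest measurement.
#' @return data frame with one row per sample: \code{sample_id, temp_mean,
#'   sal_mean, tp_mean, secchi, sigma_surface, sigma_bottom,
#'   bottom_depth_used, e_index} and (if resolvable) \code{loading_type}.
#' @export
summarize_hydrography <- function(profiles, secchi, samples = NULL,
                                  loading_shares = NULL,
                                  bottom_depths = NULL) {
  parts <- split(profiles, profiles$sample_id)
  rows <- lapply(names(parts), function(sid) {
    p <- parts[[sid]]
    bd <- if (!is.null(bottom_depths)) {
      i <- match(sid, bottom_depths$sample_id)
      if (is.na(i)) max(p$depth) else bottom_depths$bottom_depth[i]
    } else max(p$depth)
    temp_mean <- surface_layer_mean(p$depth, p$temperature, bottom_depth = bd)
    sal_mean <- surface_layer_mean(p$depth, p$salinity, bottom_depth = bd)
    tp_mean <- if (all(is.na(p$tp))) NA_real_ else
      surface_layer_mean(p$depth, p$tp, bottom_depth = bd)
    # deepest joint T/S measurement defines the bottom layer and the depth
    joint <- !is.na(p$temperature) & !is.na(p$salinity)
    if (!any(joint)) stop("sample ", sid, ": no joint T/S measurement")
    deepest <- which(joint)[which.max(p$depth[joint])]
    sigma_s <- water_density(temp_mean, sal_mean)
    sigma_b <- water_density(p$temperature[deepest], p$salinity[deepest])
    depth_deepest <- p$depth[deepest]
    e <- if (depth_deepest > 0)
      stratification_index(sigma_s, sigma_b, depth_deepest) else NA_real_
    data.frame(sample_id = sid, temp_mean = temp_mean, sal_mean = sal_mean,
               tp_mean = tp_mean, sigma_surface = sigma_s,
               sigma_bottom = sigma_b, bottom_depth_used = depth_deepest,
               e_index = e, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$secchi <- secchi$secchi[match(out$sample_id, secchi$sample_id)]
  if (!is.null(samples) && !is.null(loading_shares)) {
    lt <- classify_loading_types(loading_shares)
    wb <- samples$water_body_id[match(out$sample_id, samples$sample_id)]
    out$loading_type <- lt$loading_type[match(wb, lt$water_body_id)]
  }
  rownames(out) <- NULL
  out
}
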