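#' Run the trait analysis pipeline on a survey bundle
#'
#' End-to-end data preparation: validates trait-table coverage, applies the
#' exclusion filters, resolves trait flags (genus OR-rule plus overrides),
#' builds the 27-column response matrix and per-sample morphometrics,
#' summarizes the hydrographic profiles (surface-layer means,
#' stratification index, loading source type), and assembles the model
#' frame used by the per-response GAMMs.
#'
#' @param bundle a \code{survey_bundle} (from \code{\link{simulate_survey}}
#'   or \code{\link{read_survey}}).
#' @param cells_per_unit_defaults optional per-taxon
#'   \code{default_cells_per_unit} table for the morphometrics.
#' @return list of class \code{trait_pipeline}: \code{responses} (the
#'   \code{response_matrix}), \code{traits} (resolved flags),
#'   \code{exclusion_report}, \code{hydro} (per-sample summary), and
#'   \code{model_data} (one row per sample: \code{Temp, Sal, Secchi, E, TP,
#'   L, Area, water_body, station, time} plus the 27 responses).
#' @export
run_trait_pipeline <- function(bundle, cells_per_unit_defaults = NULL) {
  stopifnot(inherits(bundle, "survey_bundle"))
  validate_coverage(bundle$trait_table, bundle$observations)
  filt <- apply_exclusion_filters(bundle$observations, bundle$trait_table)
  traits <- resolve_traits(bundle$trait_table)
  responses <- build_responses(filt$observations, traits,
                               cells_per_unit_defaults)
  hydro <- summarize_hydrography(bundle$profiles, bundle$secchi,
                                 samples = bundle$samples,
                                 loading_shares = bundle$loading_shares,
                                 bottom_depths = bundle$bottom_depths)
  smp <- bundle$samples
  i <- match(responses$sample_id, smp$sample_id)
  h <- match(responses$sample_id, hydro$sample_id)
  if (anyNA(i) || anyNA(h))
    stop("samples present in observations but missing from metadata or",
         " hydrography")
  model_data <- data.frame(
    sample_id = responses$sample_id,
    Temp = hydro$temp_mean[h], Sal = hydro$sal_mean[h],
    Secchi = hydro$secchi[h], E = hydro$e_index[h], TP = hydro$tp_mean[h],
    L = factor(hydro$loading_type[h]),
    Area = factor(smp$sea_area[i], levels = SEA_AREAS),
    water_body = smp$water_body_id[i], station = smp$station_id[i],
    date = smp$date[i],
    time = as.numeric(smp$date[i] - as.Date("2000-01-01")) / 7,
    stringsAsFactors = FALSE, check.names = FALSE)
  model_data <- cbind(model_data,
                      as.data.frame(responses)[, response_names(),
                                               drop = FALSE])
  structure(list(responses = responses, traits = traits,
                 exclusion_report = filt, hydro = hydro,
                 model_data = model_data),
            class = "trait_pipeline")
}

#' @export
print.trait_pipeline <- function(x, ...) {
  cat("Trait pipeline result:\n")
  cat("  samples:", nrow(x$responses), " responses:",
      ncol(x$responses) - 1, "\n")
  cat("  rows removed by exclusion filters:",
      sum(x$exclusion_report$report), "\n")
  invisible(x)
}

#' Fit the per-response additive mixed models
#'
#' Box-Cox transforms each requested response (exponent profiled on the
#' pooled data, shift only where zeros occur) and fits the specification of
#' \code{\link{trait_gamm_spec}} to it.
#'
#' @param pipeline a \code{trait_pipeline}.
#' @param responses character vector of response names to model (default:
#'   all 27).
#' @param spec a \code{trait_gamm_spec}.
#' @param transform logical: apply the Box-Cox transformation (default
#'   \code{TRUE}).
#' @return list of class \code{trait_gamm_set}: \code{fits} (named list of
#'   \code{trait_gamm}), \code{transforms} (per-response lambda and shift),
#'   \code{spec}.
#' @export
fit_trait_models <- function(pipeline, responses = response_names(),
                             spec = trait_gamm_spec(), transform = TRUE) {
  stopifnot(inherits(pipeline, "trait_pipeline"))
  bad <- setdiff(responses, response_names())
  if (length(bad) > 0)
    stop("unknown response(s): ", paste(bad, collapse = ", "))
  md <- pipeline$model_data
  fits <- list()
  transforms <- data.frame(response = responses, lambda = NA_real_,
                           shift = NA_real_, stringsAsFactors = FALSE)
  for (nm in responses) {
    y <- md[[nm]]
    if (transform) {
      bc <- boxcox_fit(y)
      md[[nm]] <- bc$transformed
      transforms[transforms$response == nm, c("lambda", "shift")] <-
        c(bc$lambda, bc$shift)
    }
    fits[[nm]] <- fit_trait_gamm(md, nm, spec)
  }
  structure(list(fits = fits, transforms = transforms, spec = spec),
            class = "trait_gamm_set")
}

#' Per-term p-values and effect directions across responses
#'
#' Summary table in the layout of a GAMM results table: one row per
#' response, one column pair per explanatory variable (p-value, and for
#' smooth terms a direction code from
#' \code{\link{classify_effect_direction}}).
#'
#' @param fit_set a \code{trait_gamm_set}.
#' @return data frame: \code{response}, then \code{<term>_p} and
#'   \code{<term>_dir} columns.
#' @export
trait_gamm_pvalues <- function(fit_set) {
  stopifnot(inherits(fit_set, "trait_gamm_set"))
  spec <- fit_set$spec
  terms <- c(spec$smooths, spec$factors)
  rows <- lapply(names(fit_set$fits), function(nm) {
    fit <- fit_set$fits[[nm]]
    row <- list(response = nm, converged = fit$converged)
    for (tm in terms) {
      row[[paste0(tm, "_p")]] <- if (fit$converged)
        term_pvalue(fit, tm) else NA_real_
      if (tm %in% spec$smooths)
        row[[paste0(tm, "_dir")]] <- if (fit$converged)
          classify_effect_direction(fit, tm) else NA_character_
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tukey-adjusted area contrasts across responses
#'
#' One row per response and sea-area pair: the difference of estimated
#' marginal means with its Tukey-adjusted p-value.
#'
#' @param fit_set a \code{trait_gamm_set}.
#' @param factor_name the factor to contrast (default \code{"Area"}).
#' @return data frame: \code{response, contrast, estimate, se, t_ratio,
#'   p_value}.
#' @export
trait_gamm_contrasts <- function(fit_set, factor_name = "Area") {
  stopifnot(inherits(fit_set, "trait_gamm_set"))
  rows <- lapply(names(fit_set$fits), function(nm) {
    fit <- fit_set$fits[[nm]]
    if (!fit$converged) return(NULL)
    ct <- tukey_pairwise(estimated_marginal_means(fit, factor_name))
    cbind(response = nm, as.data.frame(ct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
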