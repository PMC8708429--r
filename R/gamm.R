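GAMM_COVARIATES <- c("Temp", "Sal", "Secchi", "E", "TP")

#' Specification of the per-response additive mixed model
#'
#' One model per response: penalized cubic regression splines for the
#' continuous covariates (surface temperature, salinity, Secchi depth,
#' stratification index E, total phosphorus), loading source type and sea
#' area as parametric factors, nested random intercepts for water body and
#' station, a continuous-time AR(1) residual correlation within station,
#' and one residual variance multiplier per sea area.
#'
#' @param smooths continuous covariates modeled as penalized smooths.
#' @param k basis dimension per smooth (cubic regression spline), \eqn{\ge 4}.
#' @param factors parametric factor terms.
#' @param random grouping variables for nested random intercepts, outermost
#'   first; \code{character(0)} for none.
#' @param car1 logical: continuous-time AR(1) residual correlation within
#'   station (decay \eqn{\phi^{\Delta t}} on the \code{time} column).
#' @param variance_by_area logical: estimate one residual variance
#'   multiplier per sea area.
#' @param alpha significance threshold for term tests (default 0.001; with
#'   27 models and 7 terms each, only smaller p-values are treated as
#'   significant).
#' @return list of class \code{trait_gamm_spec}.
#' @export
trait_gamm_spec <- function(smooths = GAMM_COVARIATES, k = 6,
                            factors = c("L", "Area"),
                            random = c("water_body", "station"),
                            car1 = TRUE, variance_by_area = TRUE,
                            alpha = 0.001) {
  if (k < 4) stop("basis dimension k must be >= 4")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(smooths = smooths, k = k, factors = factors,
                 random = random, car1 = car1,
                 variance_by_area = variance_by_area, alpha = alpha),
            class = "trait_gamm_spec")
}

#' Read a model specification from a JSON config file
#'
#' @param path JSON file whose fields mirror the arguments of
#'   \code{\link{trait_gamm_spec}} (missing fields take the defaults).
#' @return a \code{trait_gamm_spec}.
#' @export
read_gamm_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(trait_gamm_spec))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(trait_gamm_spec, cfg)
}

gamm_formula <- function(spec, response = ".response") {
  smooth_terms <- sprintf("s(%s, k = %d, bs = \"cr\")", spec$smooths, spec$k)
  rhs <- c(smooth_terms, spec$factors)
  if (length(rhs) == 0) rhs <- "1"
  as.formula(paste0("`", response, "` ~ ", paste(rhs, collapse = " + ")))
}

#' Fit the additive mixed model for one response
#'
#' Thin wrapper around \code{mgcv::gamm} (nlme backend) implementing the
#' specification of \code{\link{trait_gamm_spec}}: smoothing parameters and
#' variance components are estimated by REML, the AR(1) coefficient and the
#' per-area variance weights are iterated jointly with the working model.
#' When the specification requests no random effects, no correlation and no
#' variance weights, the model reduces to \code{mgcv::gam(method = "REML")}.
#' Non-convergence is flagged, not raised.
#'
#' @param data model frame; must contain the response, the spec's covariates
#'   and factors, the random grouping columns, and a numeric \code{time}
#'   column (unique within station) when \code{car1} is on.
#' @param response name of the response column (already transformed).
#' @param spec a \code{trait_gamm_spec}.
#' @param sp optional fixed smoothing parameters (one per smooth) passed to
#'   the mgcv fit instead of estimating them by REML; large values collapse
#'   each smooth to a straight line.
#' @return object of class \code{trait_gamm}: list with elements \code{gam}
#'   (the mgcv fit), \code{lme} (the nlme fit or \code{NULL}), \code{spec},
#'   \code{response}, \code{data}, \code{converged}, \code{message}.
#' @export
fit_trait_gamm <- function(data, response, spec = trait_gamm_spec(),
                           sp = NULL) {
  stopifnot(inherits(spec, "trait_gamm_spec"))
  need <- c(response, spec$smooths, spec$factors, spec$random,
            if (spec$car1) "time")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0)
    stop("model data is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(data)
  df$.response <- df[[response]]
  for (fc in spec$factors) {
    df[[fc]] <- factor(df[[fc]])
    if (nlevels(df[[fc]]) < 2)
      stop("factor '", fc, "' has fewer than 2 observed levels")
  }
  for (rg in spec$random) df[[rg]] <- factor(df[[rg]])
  if (spec$car1) {
    grp <- if (length(spec$random) > 0) utils::tail(spec$random, 1) else NULL
    if (!is.null(grp)) {
      dup <- tapply(df$time, df[[grp]], anyDuplicated)
      if (any(unlist(dup) > 0))
        stop("time values must be unique within '", grp,
             "' for the continuous AR(1) structure")
    }
  }
  form <- gamm_formula(spec)
  plain <- length(spec$random) == 0 && !spec$car1 && !spec$variance_by_area
  fit <- NULL
  msg <- NA_character_
  if (plain) {
    fit <- tryCatch(mgcv::gam(form, data = df, method = "REML", sp = sp),
                    error = function(e) {msg <<- conditionMessage(e); NULL})
    obj <- list(gam = fit, lme = NULL)
  } else {
    args <- list(form, data = df, method = "REML",
                 control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                            niterEM = 25, opt = "optim",
                                            returnObject = FALSE))
    if (length(spec$random) > 0)
      args$random <- setNames(rep(list(~1), length(spec$random)), spec$random)
    if (spec$car1) args$correlation <- nlme::corCAR1(form = ~time)
    if (spec$variance_by_area) args$weights <- nlme::varIdent(form = ~1 | Area)
    if (!is.null(sp)) args$sp <- sp
    fit <- tryCatch(
      do.call(mgcv::gamm, args),
      error = function(e) {msg <<- conditionMessage(e); NULL})
    obj <- if (is.null(fit)) list(gam = NULL, lme = NULL) else
      list(gam = fit$gam, lme = fit$lme)
  }
  structure(c(obj, list(spec = spec, response = response, data = df,
                        converged = !is.null(fit), message = msg)),
            class = "trait_gamm")
}

#' @export
print.trait_gamm <- function(x, ...) {
  cat("Trait GAMM for response '", x$response, "'", sep = "")
  if (!x$converged) {
    cat("  [NOT CONVERGED: ", x$message, "]\n", sep = "")
    return(invisible(x))
  }
  cat("\n")
  s <- summary(x$gam)
  if (!is.null(s$s.table) && nrow(s$s.table) > 0) {
    cat("Smooth terms (edf, p):\n")
    print(round(s$s.table[, c("edf", "p-value"), drop = FALSE], 4))
  }
  if (!is.null(s$pTerms.table) && nrow(s$pTerms.table) > 0) {
    cat("Parametric terms (p):\n")
    print(round(s$pTerms.table[, "p-value", drop = FALSE], 4))
  }
  if (!is.null(x$lme)) {
    phi <- car1_phi(x)
    if (!is.na(phi)) cat("CAR(1) phi:", round(phi, 3), "\n")
  }
  invisible(x)
}

#' Extract the continuous AR(1) coefficient from a fit
#'
#' @param fit a converged \code{trait_gamm} with a \code{corCAR1} structure.
#' @return \eqn{\phi} (correlation at unit time separation), or \code{NA}.
#' @export
car1_phi <- function(fit) {
  if (is.null(fit$lme)) return(NA_real_)
  cs <- fit$lme$modelStruct$corStruct
  if (is.null(cs)) return(NA_real_)
  unname(coef(cs, unconstrained = FALSE)[1])
}

#' Random-intercept standard deviations of a fit
#'
#' @param fit a converged \code{trait_gamm} fitted with random effects.
#' @return named numeric vector of intercept SDs per grouping level.
#' @export
random_intercept_sd <- function(fit) {
  if (is.null(fit$lme)) return(setNames(numeric(0), character(0)))
  vc <- nlme::VarCorr(fit$lme)
  rows <- grep("\\(Intercept\\)", rownames(vc))
  lvl <- rownames(vc)[rows - 1]           # group header precedes intercept row
  lvl <- sub(" =.*$", "", lvl)
  sds <- suppressWarnings(as.numeric(vc[rows, "StdDev"]))
  grouping <- fit$spec$random
  # keep only the user's grouping variables (gamm adds spline penalties as
  # pseudo-groups named g/g.0/...)
  keep <- vapply(grouping, function(g) {
    i <- grep(paste0("^", g), lvl)
    if (length(i) == 0) NA_integer_ else i[1]
  }, integer(1))
  setNames(sds[keep], grouping)
}

#' Per-area residual variance multipliers
#'
#' @param fit a converged \code{trait_gamm} fitted with variance weights.
#' @return named vector of relative residual SD multipliers (reference
#'   area = 1).
#' @export
area_variance_multipliers <- function(fit) {
  if (is.null(fit$lme)) return(setNames(numeric(0), character(0)))
  vs <- fit$lme$modelStruct$varStruct
  if (is.null(vs)) return(setNames(numeric(0), character(0)))
  co <- coef(vs, unconstrained = FALSE, allCoef = TRUE)
  setNames(as.numeric(co), names(co))
}

#' P-value of one model term
#'
#' Smooth terms are tested with mgcv's Wald-type test on the penalized
#' coefficients at the estimated effective degrees of freedom; factor terms
#' with a joint Wald test.
#'
#' @param fit a converged \code{trait_gamm}.
#' @param term covariate or factor name (e.g. \code{"Temp"}, \code{"Area"}).
#' @return p-value in [0, 1].
#' @export
term_pvalue <- function(fit, term) {
  if (!fit$converged) stop("fit did not converge; no term tests available")
  s <- summary(fit$gam)
  if (term %in% fit$spec$smooths) {
    row <- match(paste0("s(", term, ")"), rownames(s$s.table))
    if (is.na(row)) stop("smooth term not found: ", term)
    return(unname(s$s.table[row, "p-value"]))
  }
  if (term %in% fit$spec$factors) {
    row <- match(term, rownames(s$pTerms.table))
    if (is.na(row)) stop("parametric term not found: ", term)
    return(unname(s$pTerms.table[row, "p-value"]))
  }
  stop("term '", term, "' is not part of the model specification")
}

#' Effective degrees of freedom of a smooth term
#'
#' @inheritParams term_pvalue
#' @return the edf.
#' @export
term_edf <- function(fit, term) {
  if (!fit$converged) stop("fit did not converge")
  s <- summary(fit$gam)
  row <- match(paste0("s(", term, ")"), rownames(s$s.table))
  if (is.na(row)) stop("smooth term not found: ", term)
  unname(s$s.table[row, "edf"])
}

reference_row <- function(fit) {
  df <- fit$data
  out <- df[1, , drop = FALSE]
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) out[[nm]] <- mean(df[[nm]])
    else if (is.factor(df[[nm]])) out[[nm]] <- factor(levels(df[[nm]])[1],
                                                      levels = levels(df[[nm]]))
  }
  out
}

#' Classify the direction of a significant smooth effect
#'
#' Reproduces the effect coloring of GAMM result tables: \code{ns} if the
#' term's p-value is at or above the significance threshold; otherwise
#' \code{positive} or \code{negative} if the fitted smooth is monotone over
#' the observed covariate range with the corresponding sign; otherwise
#' \code{nonlinear} (unimodal or more complex). Directionality is thus read
#' off the shape of the fitted curve, not its effective degrees of freedom:
#' a significant monotone smooth carries an unambiguous direction even when
#' mildly curved, whereas the \code{nonlinear} class is reserved for
#' non-monotone (typically unimodal) responses. Small non-monotone
#' excursions below \code{wiggle_tol} times the smooth's range are
#' tolerated. Non-converged fits return \code{NA}.
#'
#' @inheritParams term_pvalue
#' @param alpha significance threshold; defaults to the spec's.
#' @param n_grid evaluation grid size over the covariate range.
#' @param wiggle_tol tolerated counter-directional movement as a fraction
#'   of the smooth's fitted range (default 0.005).
#' @return one of \code{"positive"}, \code{"negative"}, \code{"nonlinear"},
#'   \code{"ns"}, or \code{NA}.
#' @export
classify_effect_direction <- function(fit, term, alpha = fit$spec$alpha,
                                      n_grid = 200, wiggle_tol = 0.005) {
  if (!(term %in% fit$spec$smooths)) stop("'", term, "' is not a smooth term")
  if (!fit$converged) return(NA_character_)
  p <- term_pvalue(fit, term)
  if (is.na(p) || p >= alpha) return("ns")
  grid <- reference_row(fit)[rep(1, n_grid), , drop = FALSE]
  grid[[term]] <- seq(min(fit$data[[term]]), max(fit$data[[term]]),
                      length.out = n_grid)
  sm <- predict(fit$gam, newdata = grid, type = "terms",
                terms = paste0("s(", term, ")"))
  f <- as.numeric(sm[, 1])
  d <- diff(f)
  tol <- wiggle_tol * max(diff(range(f)), .Machine$double.eps)
  increasing <- all(d >= -tol)
  decreasing <- all(d <= tol)
  if (increasing && f[n_grid] > f[1]) return("positive")
  if (decreasing && f[n_grid] < f[1]) return("negative")
  "nonlinear"
}

#' Estimated marginal means for a factor
#'
#' Model-predicted means per factor level at reference values of the other
#' covariates: numeric covariates at their data means, other factors
#' averaged with equal (balanced) weights over their levels. The covariance
#' of the marginal means is propagated from the coefficient covariance of
#' the fit, so the random-effect, correlation and variance structures enter
#' through the coefficient precision. With unbalanced groups these are
#' model-adjusted predictions, not raw group means.
#'
#' @param fit a converged \code{trait_gamm}.
#' @param factor_name factor to summarize (default \code{"Area"}).
#' @return object of class \code{emm_grid}: \code{levels}, \code{emmean},
#'   \code{se}, \code{vcov}, \code{df}.
#' @export
estimated_marginal_means <- function(fit, factor_name = "Area") {
  if (!fit$converged) stop("fit did not converge")
  if (!(factor_name %in% fit$spec$factors))
    stop("factor '", factor_name, "' is not in the model")
  df <- fit$data
  lv <- levels(df[[factor_name]])
  other_factors <- setdiff(fit$spec$factors, factor_name)
  grids <- list(factor(lv, levels = lv))
  names(grids) <- factor_name
  for (of in other_factors)
    grids[[of]] <- factor(levels(df[[of]]), levels = levels(df[[of]]))
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  for (sm in fit$spec$smooths) grid[[sm]] <- mean(df[[sm]])
  X <- predict(fit$gam, newdata = grid, type = "lpmatrix")
  M <- matrix(0, nrow = length(lv), ncol = nrow(grid),
              dimnames = list(lv, NULL))
  for (i in seq_along(lv)) {
    rows <- grid[[factor_name]] == lv[i]
    M[i, rows] <- 1 / sum(rows)
  }
  A <- M %*% X
  beta <- coef(fit$gam)
  V <- A %*% vcov(fit$gam) %*% t(A)
  emmean <- as.numeric(A %*% beta)
  df_resid <- fit$gam$df.residual
  structure(list(factor = factor_name, levels = lv, emmean = emmean,
                 se = sqrt(diag(V)), vcov = V, df = df_resid),
            class = "emm_grid")
}

#' @export
print.emm_grid <- function(x, ...) {
  cat("Estimated marginal means of", x$factor,
      sprintf("(df = %.1f)\n", x$df))
  print(data.frame(level = x$levels, emmean = round(x$emmean, 4),
                   se = round(x$se, 4)), row.names = FALSE)
  invisible(x)
}

#' Tukey-adjusted pairwise contrasts of marginal means
#'
#' All pairwise differences of the estimated marginal means, with
#' familywise adjustment through the studentized range distribution on the
#' contrast t-statistics (\eqn{p = P(q_{k,\nu} > \sqrt{2}\,|t|)}). With
#' equal group sizes this matches the classical Tukey HSD test; with two
#' levels it reduces to the unadjusted two-sample t-test.
#'
#' @param emm an \code{emm_grid}.
#' @return data frame of class \code{tukey_contrasts}: \code{contrast},
#'   \code{estimate}, \code{se}, \code{df}, \code{t_ratio}, \code{p_value}
#'   (adjusted).
#' @export
tukey_pairwise <- function(emm) {
  stopifnot(inherits(emm, "emm_grid"))
  k <- length(emm$levels)
  if (k < 2) stop("need at least 2 levels for pairwise contrasts")
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    contrast = apply(pairs, 2, function(ij)
      paste(emm$levels[ij[1]], "-", emm$levels[ij[2]])),
    estimate = NA_real_, se = NA_real_, df = emm$df,
    t_ratio = NA_real_, p_value = NA_real_,
    stringsAsFactors = FALSE)
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    est <- emm$emmean[i] - emm$emmean[j]
    v <- emm$vcov[i, i] + emm$vcov[j, j] - 2 * emm$vcov[i, j]
    if (v <= 0) stop("singular covariance of marginal means")
    se <- sqrt(v)
    tval <- est / se
    out$estimate[c_i] <- est
    out$se[c_i] <- se
    out$t_ratio[c_i] <- tval
    out$p_value[c_i] <- ptukey(sqrt(2) * abs(tval), nmeans = k, df = emm$df,
                               lower.tail = FALSE)
  }
  class(out) <- c("tukey_contrasts", "data.frame")
  out
}
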