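#' Configuration of the synthetic survey generator
#'
#' Defaults restate the design of the monitoring data set the package
#' emulates: four coastal sea areas of the northern Baltic Sea (BS, AS,
#' wGF, eGF) with 80 stations nested in 44 water bodies, 912 samples
#' collected 1 July - 15 September over 2009-2020, and per-area
#' environmental distributions spanning the reported summer ranges
#' (temperature 8-26 degC, salinity about 1-6.6 psu, Secchi 0.2-8.8 m,
#' TP 1.5-135 ug/L). Trait effects on log-biomass are standardized
#' (per SD of the covariate) and default to the qualitative pattern of the
#' fitted models: temperature favors N-fixers, buoyant taxa and harmful
#' cyanobacteria and disfavors motile and mixotrophic taxa; transparency
#' relates negatively to biomass overall; TP relates positively to biomass
#' and negatively to mixotrophs.
#'
#' @param seed integer master seed; every stream of randomness in the
#'   generator derives from it (table: seed+1, environment: seed+2,
#'   communities: seed+3).
#' @param areas sea area codes.
#' @param stations_per_area,samples_per_area,water_bodies_per_area named
#'   integer vectors over \code{areas}.
#' @param years sampling years.
#' @param window month-day bounds of the sampling window.
#' @param taxon_pool number of simulated pool taxa (excluding the fixed
#'   named block and the excluded-category taxa).
#' @param prevalence named marginal trait prevalences over the pool.
#' @param effects numeric matrix (rows: \code{baseline} plus the five trait
#'   flags; columns: \code{Temp, Sal, Secchi, E, TP}) of standardized
#'   effects on log-biomass, in units of the sample-level residual SD
#'   \code{sigma} per SD of the covariate (an effect of 0.8 moves
#'   log-biomass by 0.8 residual SDs per covariate SD); the baseline row
#'   applies to every taxon, and a
#'   carrier additionally receives, per covariate, the contribution of its
#'   largest-magnitude carried trait (contributions are not stacked across
#'   traits, keeping each trait's aggregate carrier biomass log-linear in
#'   the covariate with the configured coefficient).
#' @param env list of per-area distribution parameters (see defaults).
#' @param sd_water_body,sd_station random intercept SDs on log-biomass.
#' @param phi continuous-time AR(1) coefficient of the sample-level
#'   residual at a one-week separation, in (-1, 1).
#' @param sigma sample-level residual SD on log-biomass.
#' @param area_sigma_mult named per-area residual SD multipliers.
#' @param taxon_noise_sd SD of independent per-taxon, per-sample noise.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(
    seed = 1L,
    areas = c("BS", "AS", "wGF", "eGF"),
    stations_per_area = c(BS = 17, AS = 24, wGF = 31, eGF = 8),
    samples_per_area = c(BS = 110, AS = 201, wGF = 460, eGF = 141),
    water_bodies_per_area = c(BS = 9, AS = 13, wGF = 17, eGF = 5),
    years = 2009:2020,
    window = c("07-01", "09-15"),
    taxon_pool = 200,
    prevalence = c(n_fixation = 0.10, mixotrophy = 0.25, motility = 0.35,
                   buoyancy = 0.12, harmful = 0.15),
    effects = default_effects(),
    env = default_env(),
    sd_water_body = 0.3,
    sd_station = 0.3,
    phi = 0.4,
    sigma = 0.5,
    area_sigma_mult = c(BS = 1.0, AS = 1.0, wGF = 1.4, eGF = 0.9),
    taxon_noise_sd = 0.3) {
  stopifnot(length(areas) >= 2,
            all(names(stations_per_area) == areas),
            all(names(samples_per_area) == areas),
            all(names(water_bodies_per_area) == areas))
  if (taxon_pool < 1) stop("taxon_pool must be positive")
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  if (abs(phi) >= 1) stop("phi must lie in (-1, 1)")
  if (sigma < 0 || sd_water_body < 0 || sd_station < 0 || taxon_noise_sd < 0)
    stop("SDs must be non-negative")
  stopifnot(identical(rownames(effects), c("baseline", TRAIT_FLAGS)),
            identical(colnames(effects), GAMM_COVARIATES))
  structure(list(seed = as.integer(seed), areas = areas,
                 stations_per_area = stations_per_area,
                 samples_per_area = samples_per_area,
                 water_bodies_per_area = water_bodies_per_area,
                 years = years, window = window, taxon_pool = taxon_pool,
                 prevalence = prevalence, effects = effects, env = env,
                 sd_water_body = sd_water_body, sd_station = sd_station,
                 phi = phi, sigma = sigma,
                 area_sigma_mult = area_sigma_mult,
                 taxon_noise_sd = taxon_noise_sd),
            class = "sim_config")
}

#' Default standardized trait effects on log-biomass
#'
#' @return effect matrix used by \code{\link{sim_config}}.
#' @export
default_effects <- function() {
  m <- matrix(0, nrow = 1 + length(TRAIT_FLAGS), ncol = length(GAMM_COVARIATES),
              dimnames = list(c("baseline", TRAIT_FLAGS), GAMM_COVARIATES))
  m["baseline", "Secchi"] <- -0.6
  m["baseline", "TP"] <- 0.4
  m["n_fixation", "Temp"] <- 0.8
  m["buoyancy", "Temp"] <- 0.8
  m["motility", "Temp"] <- -0.6
  m["mixotrophy", "Temp"] <- -0.6
  m["mixotrophy", "TP"] <- -0.5
  m["harmful", "Temp"] <- 0.6
  m
}

#' Default per-area environmental distribution parameters
#'
#' @return list used by \code{\link{sim_config}}; all vectors ordered
#'   BS, AS, wGF, eGF.
#' @export
default_env <- function() {
  list(temp_mean = c(15.5, 17.5, 16.5, 16.0),
       temp_sd = c(2.2, 2.2, 3.0, 2.2),
       sal_mean = c(5.2, 6.0, 4.5, 2.5),
       sal_sd = c(0.5, 0.4, 1.0, 0.5),
       secchi_mean = c(3.5, 3.0, 3.0, 4.0),
       secchi_sd = c(1.0, 0.9, 1.5, 1.0),
       tp_meanlog = log(c(15, 20, 35, 18)),
       tp_sdlog = c(0.4, 0.4, 0.6, 0.4),
       dT_max = c(4, 4, 5, 6),     # bottom-surface temperature contrast
       dS_max = c(1.0, 1.0, 1.5, 1.5),
       depth_range = c(6, 40))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# The fixed named block: genus/order records with the table-level override
# exceptions, their member species, and geometry for community simulation.
named_taxon_block <- function() {
  rec <- function(id, name, rank, parent, group, nf, mx, mo, bu, ha,
                  note = NA_character_)
    data.frame(taxon_id = id, taxon_name = name, rank = rank,
               parent_genus = parent, group = group, n_fixation = nf,
               mixotrophy = mx, motility = mo, buoyancy = bu, harmful = ha,
               excluded_category = NA_character_, override_note = note,
               stringsAsFactors = FALSE)
  rbind(
    rec("gen_snowella", "Snowella", "genus", NA, "cyanobacteria",
        FALSE, FALSE, FALSE, FALSE, FALSE,
        "buoyancy=0 # majority of local species lack gas vesicles"),
    rec("sp_snowella1", "Snowella lacustris", "species", "Snowella",
        "cyanobacteria", FALSE, FALSE, FALSE, TRUE, FALSE),
    rec("sp_snowella2", "Snowella litoralis", "species", "Snowella",
        "cyanobacteria", FALSE, FALSE, FALSE, FALSE, FALSE),
    rec("gen_amphidinium", "Amphidinium", "genus", NA, "eukaryote",
        FALSE, TRUE, TRUE, FALSE, FALSE,
        "harmful=0 # majority of local species non-toxic"),
    rec("sp_amphidinium1", "Amphidinium crassum", "species", "Amphidinium",
        "eukaryote", FALSE, TRUE, TRUE, FALSE, TRUE),
    rec("gen_anabaena", "Anabaena", "genus", NA, "cyanobacteria",
        TRUE, FALSE, FALSE, TRUE, FALSE,
        "harmful=1 # pelagic Dolichospermum records under the old name"),
    rec("gen_aphanizomenon", "Aphanizomenon", "genus", NA, "cyanobacteria",
        TRUE, FALSE, FALSE, TRUE, FALSE,
        "harmful=1 # A. flosaquae listed as harmful"),
    rec("ord_prymnesiales", "Prymnesiales", "order", NA, "eukaryote",
        FALSE, TRUE, TRUE, FALSE, FALSE,
        "harmful=1 # several toxic species in the order"),
    rec("gen_chrysochromulina", "Chrysochromulina", "genus", NA, "eukaryote",
        FALSE, TRUE, TRUE, FALSE, TRUE))
}

excluded_taxon_block <- function() {
  data.frame(
    taxon_id = paste0("excl_", EXCLUDED_CATEGORIES),
    taxon_name = paste("Excluded", EXCLUDED_CATEGORIES),
    rank = "species", parent_genus = NA_character_,
    group = c("eukaryote", "cyanobacteria", "cyanobacteria", "eukaryote",
              "eukaryote", "eukaryote", "cyanobacteria"),
    n_fixation = FALSE, mixotrophy = FALSE, motility = FALSE,
    buoyancy = FALSE, harmful = FALSE,
    excluded_category = EXCLUDED_CATEGORIES,
    override_note = NA_character_, stringsAsFactors = FALSE)
}

#' Simulate a taxon trait table
#'
#' Draws a pool of species-rank taxa with marginally Bernoulli trait flags
#' made internally consistent (N-fixers are heterocystous cyanobacteria and
#' non-mixotrophic; motility and mixotrophy imply a flagellated eukaryote;
#' buoyancy is confined to cyanobacteria), appends a fixed named block of
#' genus/order records carrying the standard override exceptions
#' (\emph{Snowella}, \emph{Amphidinium}, \emph{Anabaena},
#' \emph{Aphanizomenon}, Prymnesiales) with member species, and one taxon
#' per exclusion category so the observation filters are exercised.
#'
#' @param config a \code{sim_config}.
#' @return list: \code{table} (a \code{trait_table}) and \code{geometry}
#'   (per-taxon counting-unit geometry used by
#'   \code{\link{simulate_communities}}).
#' @export
simulate_trait_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$taxon_pool
  pv <- config$prevalence
  flags <- sapply(TRAIT_FLAGS, function(fl)
    runif(n) < pv[[fl]])
  flags <- matrix(as.logical(flags), nrow = n,
                  dimnames = list(NULL, TRAIT_FLAGS))
  group <- ifelse(runif(n) < 0.2, "cyanobacteria", "eukaryote")
  # consistency: precedence n_fixation > motility/mixotrophy > buoyancy
  fix <- flags[, "n_fixation"]
  group[fix] <- "cyanobacteria"
  flags[fix, "mixotrophy"] <- FALSE
  flags[fix, "motility"] <- FALSE
  flag_euk <- !fix & (flags[, "mixotrophy"] | flags[, "motility"])
  group[flag_euk] <- "eukaryote"
  flags[flag_euk, "buoyancy"] <- FALSE
  buo <- !fix & !flag_euk & flags[, "buoyancy"]
  group[buo] <- "cyanobacteria"
  flags[group == "eukaryote", "buoyancy"] <- FALSE

  pool <- data.frame(
    taxon_id = sprintf("t%04d", seq_len(n)),
    taxon_name = sprintf("Taxon %04d", seq_len(n)),
    rank = "species", parent_genus = NA_character_, group = group,
    stringsAsFactors = FALSE)
  for (fl in TRAIT_FLAGS) pool[[fl]] <- flags[, fl]
  pool$excluded_category <- NA_character_
  pool$override_note <- NA_character_

  records <- rbind(pool, named_taxon_block(), excluded_taxon_block())
  table <- as_trait_table(records, version = paste0("sim-", config$seed))

  m <- nrow(records)
  d <- clamp(rlnorm(m, log(8), 0.7), 1, 60)
  unit_type <- sample(UNIT_TYPES, m, replace = TRUE,
                      prob = c(0.55, 0.2, 0.05, 0.1, 0.1))
  cpu <- ifelse(unit_type == "cell", 1,
         ifelse(unit_type == "filament_100um",
                pmax(2, round(100 / d)),
                pmax(2, round(exp(runif(m, log(2), log(64)))))))
  max_dim <- ifelse(unit_type == "cell", d,
             ifelse(unit_type == "filament_100um", 100,
             ifelse(unit_type == "chain", d * cpu,
                    d * ceiling(cpu^(1 / 3)) * 1.5)))
  geometry <- data.frame(taxon_id = records$taxon_id,
                         cell_diameter = d, unit_type = unit_type,
                         cells_per_unit = cpu,
                         biovolume_per_unit = sphere_volume(d) * cpu,
                         max_dimension = max_dim,
                         stringsAsFactors = FALSE)
  list(table = table, geometry = geometry)
}

# station/water-body/sample layout with distinct dates per station
survey_layout <- function(config) {
  window_days <- function(year) {
    seq(as.Date(paste0(year, "-", config$window[1])),
        as.Date(paste0(year, "-", config$window[2])), by = "day")
  }
  all_days <- do.call(c, lapply(config$years, window_days))
  rows <- list()
  for (a in config$areas) {
    n_st <- config$stations_per_area[[a]]
    n_wb <- config$water_bodies_per_area[[a]]
    n_sm <- config$samples_per_area[[a]]
    stations <- sprintf("%s_st%02d", a, seq_len(n_st))
    wbs <- sprintf("%s_wb%02d", a, seq_len(n_wb))
    st_wb <- rep_len(wbs, n_st)
    st_of_sample <- rep_len(seq_len(n_st), n_sm)
    for (s in seq_len(n_st)) {
      k <- sum(st_of_sample == s)
      if (k == 0) next
      dates <- sort(sample(all_days, k))
      rows[[length(rows) + 1]] <- data.frame(
        station_id = stations[s], water_body_id = st_wb[s], sea_area = a,
        date = dates, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$sample_id <- sprintf("smp%04d", seq_len(nrow(out)))
  out[, c("sample_id", "station_id", "water_body_id", "sea_area", "date")]
}

#' Simulate environmental data for a survey
#'
#' Generates the sample layout (stations in water bodies in sea areas,
#' dates inside the summer window), depth profiles of temperature and
#' salinity (surface layer plus a near-bottom measurement with a
#' non-negative density contrast, so the stratification index is mostly
#' positive), surface TP, Secchi depths, and per-water-body nutrient
#' loading shares constructed to cover all five loading source types
#' (types are spread over water bodies round-robin; the designated dominant
#' source receives the largest share by construction).
#'
#' @param config a \code{sim_config}.
#' @return list: \code{samples}, \code{profiles}, \code{secchi},
#'   \code{loading_shares}, \code{bottom_depths} (per sample) and
#'   \code{covariates} (per-sample Temp/Sal/Secchi/E/TP obtained by running
#'   the hydrography module on the generated profiles).
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  env <- config$env
  samples <- survey_layout(config)
  n <- nrow(samples)
  ai <- match(samples$sea_area, config$areas)

  t0 <- clamp(rnorm(n, env$temp_mean[ai], env$temp_sd[ai]), 8, 26)
  s0 <- clamp(rnorm(n, env$sal_mean[ai], env$sal_sd[ai]), 0.5, 7)
  secchi <- clamp(rnorm(n, env$secchi_mean[ai], env$secchi_sd[ai]), 0.2, 8.8)
  tp <- clamp(rlnorm(n, env$tp_meanlog[ai], env$tp_sdlog[ai]), 1.5, 135)
  dT <- runif(n, 0, env$dT_max[ai])
  dS <- runif(n, 0, env$dS_max[ai])

  stations <- unique(samples$station_id)
  st_depth <- setNames(runif(length(stations), env$depth_range[1],
                             env$depth_range[2]), stations)
  bottom <- st_depth[samples$station_id]

  profiles <- do.call(rbind, lapply(seq_len(n), function(i) {
    bd <- bottom[i]
    zb <- max(bd - 1, 1.5)
    z <- unique(c(c(0, 5, 10)[c(0, 5, 10) <= zb - 0.5], zb))
    frac <- z / zb
    data.frame(sample_id = samples$sample_id[i], depth = z,
               temperature = t0[i] - dT[i] * frac^2,
               salinity = s0[i] + dS[i] * frac^2,
               tp = ifelse(z <= 10, tp[i], NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(profiles) <- NULL
  secchi_df <- data.frame(sample_id = samples$sample_id, secchi = secchi,
                          stringsAsFactors = FALSE)
  bottom_df <- data.frame(sample_id = samples$sample_id,
                          bottom_depth = unname(bottom),
                          stringsAsFactors = FALSE)

  wbs <- unique(samples$water_body_id)
  types <- sample(rep_len(1:5, length(wbs)))
  shares <- do.call(rbind, lapply(seq_along(wbs), function(i) {
    map <- LOADING_TYPE_MAP[LOADING_TYPE_MAP$loading_type == types[i], ]
    one <- function(dominant) {
      s <- setNames(numeric(4), LOADING_SOURCES)
      s[dominant] <- runif(1, 0.55, 0.75)
      rest <- setdiff(LOADING_SOURCES, dominant)
      w <- stats::rgamma(3, 1)
      s[rest] <- (1 - s[dominant]) * w / sum(w)
      s
    }
    rbind(data.frame(water_body_id = wbs[i], nutrient = "N",
                     t(one(map$n_dominant)), stringsAsFactors = FALSE),
          data.frame(water_body_id = wbs[i], nutrient = "P",
                     t(one(map$p_dominant)), stringsAsFactors = FALSE))
  }))
  rownames(shares) <- NULL

  hydro <- summarize_hydrography(profiles, secchi_df,
                                 bottom_depths = bottom_df)
  i <- match(samples$sample_id, hydro$sample_id)
  covariates <- data.frame(sample_id = samples$sample_id,
                           Temp = hydro$temp_mean[i], Sal = hydro$sal_mean[i],
                           Secchi = secchi, E = hydro$e_index[i],
                           TP = hydro$tp_mean[i], stringsAsFactors = FALSE)
  list(samples = samples, profiles = profiles, secchi = secchi_df,
       loading_shares = shares, bottom_depths = bottom_df,
       covariates = covariates)
}

# standard CAR(1) innovations along one station's ordered sample times
car1_series <- function(time_weeks, phi) {
  k <- length(time_weeks)
  e <- numeric(k)
  e[1] <- rnorm(1)
  if (k > 1) for (j in 2:k) {
    r <- if (phi == 0) 0 else phi^(time_weeks[j] - time_weeks[j - 1])
    e[j] <- r * e[j - 1] + sqrt(1 - r^2) * rnorm(1)
  }
  e
}

#' Simulate trait-structured communities
#'
#' Per-sample taxon biomasses follow a log-normal model: log-biomass =
#' taxon baseline + standardized-covariate effects (baseline row plus the
#' rows of every trait the taxon carries) + water-body intercept + station
#' intercept + a shared sample-level residual with continuous-time AR(1)
#' correlation within station and per-area SD multipliers + independent
#' per-taxon noise. Counting units and biovolumes follow each taxon's
#' geometry, and biomass is consistent with biovolume under the wet-weight
#' density convention. Excluded-category taxa appear sporadically with
#' small biomasses to exercise the filters.
#'
#' @param config a \code{sim_config}.
#' @param table_geometry output of \code{\link{simulate_trait_table}}.
#' @param environment output of \code{\link{simulate_environment}}.
#' @return list: \code{observations} (counting-unit table) and
#'   \code{ground_truth} (drawn effects and random components).
#' @export
simulate_communities <- function(config, table_geometry, environment) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  table <- table_geometry$table
  geometry <- table_geometry$geometry
  samples <- environment$samples
  cov <- environment$covariates
  stopifnot(identical(cov$sample_id, samples$sample_id))

  resolved <- resolve_traits(table)
  modelled <- resolved[is.na(resolved$excluded_category), , drop = FALSE]
  excluded <- resolved[!is.na(resolved$excluded_category), , drop = FALSE]
  n_tax <- nrow(modelled)
  n_smp <- nrow(samples)

  Z <- scale(as.matrix(cov[, GAMM_COVARIATES]))
  # per-taxon slopes: baseline plus, per covariate, the contribution of the
  # carried trait with the largest |effect| (no stacking across traits, so
  # each trait's carrier biomass responds log-linearly with the configured
  # coefficient; ties broken by trait order). Effects are standardized:
  # log-units per covariate SD, in units of the sample-level residual SD.
  effect_unit <- if (config$sigma > 0) config$sigma else 1
  flag_mat <- as.matrix(modelled[, TRAIT_FLAGS]) * 1
  trait_eff <- config$effects[TRAIT_FLAGS, , drop = FALSE]
  beta <- matrix(rep(config$effects["baseline", ], each = n_tax),
                 nrow = n_tax, dimnames = list(NULL, GAMM_COVARIATES))
  for (cv in GAMM_COVARIATES) {
    contrib <- flag_mat * rep(trait_eff[, cv], each = n_tax)
    pick <- max.col(abs(contrib), ties.method = "first")
    beta[, cv] <- beta[, cv] + contrib[cbind(seq_len(n_tax), pick)]
  }
  beta <- beta * effect_unit

  a_taxon <- rnorm(n_tax, log(2), 0.8)
  wbs <- unique(samples$water_body_id)
  sts <- unique(samples$station_id)
  u_wb <- setNames(rnorm(length(wbs), 0, config$sd_water_body), wbs)
  u_st <- setNames(rnorm(length(sts), 0, config$sd_station), sts)

  time_weeks <- as.numeric(samples$date - as.Date("2000-01-01")) / 7
  ar <- numeric(n_smp)
  for (st in sts) {
    i <- which(samples$station_id == st)
    i <- i[order(time_weeks[i])]
    ar[i] <- car1_series(time_weeks[i], config$phi)
  }
  mult <- config$area_sigma_mult[samples$sea_area]
  resid <- config$sigma * mult * ar

  sample_part <- u_wb[samples$water_body_id] + u_st[samples$station_id] + resid
  # n_smp x n_tax matrix of log-biomass
  log_b <- Z %*% t(beta) +
    matrix(a_taxon, n_smp, n_tax, byrow = TRUE) +
    matrix(sample_part, n_smp, n_tax) +
    matrix(rnorm(n_smp * n_tax, 0, config$taxon_noise_sd), n_smp, n_tax)
  biomass <- exp(log_b)

  gi <- match(modelled$taxon_id, geometry$taxon_id)
  obs <- data.frame(
    sample_id = rep(samples$sample_id, times = n_tax),
    taxon_id = rep(modelled$taxon_id, each = n_smp),
    unit_type = rep(geometry$unit_type[gi], each = n_smp),
    units_per_litre = as.numeric(biomass) * 1e6 /
      rep(geometry$biovolume_per_unit[gi], each = n_smp),
    cells_per_unit = rep(geometry$cells_per_unit[gi], each = n_smp),
    biovolume_per_unit = rep(geometry$biovolume_per_unit[gi], each = n_smp),
    biomass = as.numeric(biomass),
    max_dimension = rep(geometry$max_dimension[gi], each = n_smp),
    stringsAsFactors = FALSE)

  if (nrow(excluded) > 0) {
    ei <- match(excluded$taxon_id, geometry$taxon_id)
    hits <- which(matrix(runif(n_smp * nrow(excluded)) < 0.1,
                         n_smp, nrow(excluded)), arr.ind = TRUE)
    if (nrow(hits) > 0) {
      eb <- rlnorm(nrow(hits), log(0.5), 0.5)
      obs_ex <- data.frame(
        sample_id = samples$sample_id[hits[, 1]],
        taxon_id = excluded$taxon_id[hits[, 2]],
        unit_type = geometry$unit_type[ei][hits[, 2]],
        units_per_litre = eb * 1e6 /
          geometry$biovolume_per_unit[ei][hits[, 2]],
        cells_per_unit = geometry$cells_per_unit[ei][hits[, 2]],
        biovolume_per_unit = geometry$biovolume_per_unit[ei][hits[, 2]],
        biomass = eb,
        max_dimension = geometry$max_dimension[ei][hits[, 2]],
        stringsAsFactors = FALSE)
      obs <- rbind(obs, obs_ex)
    }
  }
  obs <- obs[order(obs$sample_id, obs$taxon_id), ]
  rownames(obs) <- NULL

  ground_truth <- list(
    seed = config$seed,
    effects = config$effects,
    taxon_traits = modelled,
    taxon_baseline = setNames(a_taxon, modelled$taxon_id),
    u_water_body = u_wb, u_station = u_st,
    phi = config$phi, sigma = config$sigma,
    area_sigma_mult = config$area_sigma_mult,
    sd_water_body = config$sd_water_body, sd_station = config$sd_station,
    covariates = cov)
  list(observations = validate_observations(obs), ground_truth = ground_truth)
}

#' Simulate a complete survey bundle
#'
#' Runs the three generator stages off a single master seed and returns (or
#' writes) every input the analysis pipeline consumes, together with the
#' ground truth.
#'
#' @param config a \code{sim_config}.
#' @param dir optional directory; when given, all inputs are written as CSV
#'   (plus ground truth as JSON) and can be re-read with
#'   \code{\link{read_survey}}.
#' @return list of class \code{survey_bundle}: \code{trait_table},
#'   \code{geometry}, \code{observations}, \code{samples}, \code{profiles},
#'   \code{secchi}, \code{loading_shares}, \code{bottom_depths},
#'   \code{ground_truth}.
#' @export
simulate_survey <- function(config = sim_config(), dir = NULL) {
  tg <- simulate_trait_table(config)
  env <- simulate_environment(config)
  com <- simulate_communities(config, tg, env)
  bundle <- structure(
    list(trait_table = tg$table, geometry = tg$geometry,
         observations = com$observations, samples = env$samples,
         profiles = env$profiles, secchi = env$secchi,
         loading_shares = env$loading_shares,
         bottom_depths = env$bottom_depths,
         ground_truth = com$ground_truth),
    class = "survey_bundle")
  if (!is.null(dir)) write_survey(bundle, dir)
  bundle
}

#' @export
print.survey_bundle <- function(x, ...) {
  cat("Synthetic survey bundle:\n")
  cat("  taxa:   ", nrow(x$trait_table), "\n")
  cat("  samples:", nrow(x$samples), "in",
      length(unique(x$samples$station_id)), "stations /",
      length(unique(x$samples$water_body_id)), "water bodies /",
      length(unique(x$samples$sea_area)), "sea areas\n")
  cat("  observation rows:", nrow(x$observations), "\n")
  invisible(x)
}

#' Write a survey bundle to a directory
#'
#' @param bundle a \code{survey_bundle}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_survey <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_trait_table(bundle$trait_table, p("trait_table.csv"))
  write.csv(bundle$geometry, p("geometry.csv"), row.names = FALSE, na = "")
  write.csv(bundle$observations, p("observations.csv"), row.names = FALSE)
  smp <- bundle$samples
  smp$date <- format(smp$date, "%Y-%m-%d")
  write.csv(smp, p("samples.csv"), row.names = FALSE)
  write.csv(bundle$profiles, p("profiles.csv"), row.names = FALSE, na = "")
  write.csv(bundle$secchi, p("secchi.csv"), row.names = FALSE)
  write.csv(bundle$loading_shares, p("loading_shares.csv"), row.names = FALSE)
  write.csv(bundle$bottom_depths, p("bottom_depths.csv"), row.names = FALSE)
  gt <- bundle$ground_truth
  gt$effects <- as.data.frame(gt$effects)
  jsonlite::write_json(gt, p("ground_truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a survey bundle from a directory
#'
#' Re-reads the files written by \code{\link{write_survey}} through the
#' package's validating readers.
#'
#' @param dir directory holding the bundle CSVs.
#' @return a \code{survey_bundle} (without ground truth unless present).
#' @export
read_survey <- function(dir) {
  p <- function(f) file.path(dir, f)
  gt <- NULL
  if (file.exists(p("ground_truth.json")))
    gt <- jsonlite::read_json(p("ground_truth.json"), simplifyVector = TRUE)
  structure(
    list(trait_table = load_trait_table(p("trait_table.csv")),
         geometry = read.csv(p("geometry.csv"), stringsAsFactors = FALSE),
         observations = read_observations(p("observations.csv")),
         samples = read_samples(p("samples.csv")),
         profiles = read_profiles(p("profiles.csv")),
         secchi = read_secchi(p("secchi.csv")),
         loading_shares = read_loading_shares(p("loading_shares.csv")),
         bottom_depths = read.csv(p("bottom_depths.csv"),
                                  stringsAsFactors = FALSE),
         ground_truth = gt),
    class = "survey_bundle")
}

#' Expected directions of the injected strong effects
#'
#' Derives, from a configuration's effect matrix, the set of
#' (carrier-biomass response, covariate) pairs whose net standardized
#' effect (baseline + trait row) meets a magnitude threshold, with the
#' expected sign. Used by the sign-recovery experiments.
#'
#' @param config a \code{sim_config}.
#' @param threshold minimum |net standardized effect| (default 0.5).
#' @return data frame: \code{response}, \code{term}, \code{sign}.
#' @export
injected_effect_signs <- function(config, threshold = 0.5) {
  stems <- c(n_fixation = "Nfix", buoyancy = "Buo", motility = "Mot",
             mixotrophy = "MX", harmful = "HABcyano")
  rows <- list()
  for (fl in names(stems)) {
    net <- config$effects["baseline", ] + config$effects[fl, ]
    for (cv in GAMM_COVARIATES) {
      if (abs(net[[cv]]) >= threshold)
        rows[[length(rows) + 1]] <- data.frame(
          response = paste(stems[[fl]], "biom"), term = cv,
          sign = ifelse(net[[cv]] > 0, "positive", "negative"),
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
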