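test_that("the generator is deterministic in the master seed", {
  cfg <- small_cfg(seed = 3)
  b1 <- simulate_survey(cfg)
  b2 <- simulate_survey(cfg)
  expect_identical(as.data.frame(b1$trait_table),
                   as.data.frame(b2$trait_table))
  expect_identical(b1$observations, b2$observations)
  expect_identical(b1$profiles, b2$profiles)
  b3 <- simulate_survey(small_cfg(seed = 4))
  expect_false(identical(b1$observations$biomass, b3$observations$biomass))
})

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(taxon_pool = 0), "taxon_pool")
  expect_error(sim_config(phi = 1), "phi")
  expect_error(sim_config(sd_station = -1), "non-negative")
  expect_error(sim_config(prevalence = c(n_fixation = 1.2, mixotrophy = 0.2,
                                         motility = 0.3, buoyancy = 0.1,
                                         harmful = 0.1)),
               "prevalences")
})

test_that("trait prevalence follows the configured binomial rate", {
  cfg <- sim_config(seed = 5, taxon_pool = 200)
  tg <- simulate_trait_table(cfg)
  pool <- as.data.frame(tg$table)
  pool <- pool[grepl("^t\\d+$", pool$taxon_id), ]   # pool taxa only
  expect_equal(nrow(pool), 200)
  n_fix <- sum(pool$n_fixation)
  expect_gte(n_fix, 14)        # binomial(200, 0.1) central 95% range
  expect_lte(n_fix, 26)
  # internal consistency of the drawn flags
  expect_true(all(pool$group[pool$n_fixation] == "cyanobacteria"))
  expect_true(all(!pool$mixotrophy[pool$n_fixation]))
  expect_true(all(pool$group[pool$buoyancy] == "cyanobacteria"))
  expect_true(all(pool$group[pool$mixotrophy | pool$motility] == "eukaryote"))
  # one taxon per exclusion category ships with the table
  tab <- as.data.frame(tg$table)
  expect_setequal(unique(stats::na.omit(tab$excluded_category)),
                  c("heterotroph", "akinete", "heterocyte", "cyst",
                    "benthic_littoral", "picoplankton_single",
                    "synechococcus"))
})

test_that("environment generator produces the configured area contrasts", {
  env <- simulate_environment(small_cfg(seed = 21))
  cov <- merge(env$covariates, env$samples)
  # AS configured warmer than BS
  t_as <- cov$Temp[cov$sea_area == "AS"]
  t_bs <- cov$Temp[cov$sea_area == "BS"]
  expect_gt(mean(t_as), mean(t_bs))
  expect_lt(t.test(t_bs, t_as)$p.value, 0.01)
  # eGF configured fresher than AS
  expect_lt(mean(cov$Sal[cov$sea_area == "eGF"]),
            mean(cov$Sal[cov$sea_area == "AS"]))
  # stratification index spans positive values
  expect_gt(mean(cov$E > 0), 0.9)
})

test_that("all five loading types occur in the default 44-water-body draw", {
  b <- default_bundle()
  expect_equal(length(unique(b$samples$water_body_id)), 44)
  expect_equal(length(unique(b$samples$station_id)), 80)
  expect_equal(nrow(b$samples), 912)
  lt <- classify_loading_types(b$loading_shares)
  expect_setequal(sort(unique(lt$loading_type)), 1:5)
})

test_that("a homogeneous profile yields E = 0 through the hydrography module", {
  pr <- data.frame(sample_id = "s", depth = c(0, 5, 10, 22),
                   temperature = 14, salinity = 5, tp = c(12, 12, 12, NA))
  h <- summarize_hydrography(pr, data.frame(sample_id = "s", secchi = 3))
  expect_equal(h$e_index, 0)
})

test_that("degenerate generator gives constant biomass per taxon", {
  cfg <- small_cfg(seed = 9,
                   effects = matrix(0, 6, 5,
                                    dimnames = list(c("baseline",
                                                      "n_fixation",
                                                      "mixotrophy", "motility",
                                                      "buoyancy", "harmful"),
                                                    c("Temp", "Sal", "Secchi",
                                                      "E", "TP"))),
                   sd_water_body = 0, sd_station = 0, phi = 0, sigma = 0,
                   taxon_noise_sd = 0)
  b <- simulate_survey(cfg)
  pool_obs <- b$observations[grepl("^t\\d+$", b$observations$taxon_id), ]
  spread <- tapply(pool_obs$biomass, pool_obs$taxon_id,
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("injected positive temperature effect shows up in N-fixer share", {
  md <- default_pipeline()$model_data
  expect_gt(cor(md$Temp, md[["Nfix share"]]), 0)
  expect_gt(cor(md$Temp, log(md[["Nfix biom"]])), 0.3)
  # negative transparency effect on total biomass
  total <- md[["Nfix biom"]] + md[["nonNfix biom"]]
  expect_lt(cor(md$Secchi, log(total)), 0)
})

test_that("survey bundles round-trip through CSV and the validating readers", {
  dir <- tempfile("survey")
  b <- small_bundle()
  write_survey(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("trait_table.csv", "observations.csv", "samples.csv", "profiles.csv",
      "secchi.csv", "loading_shares.csv", "bottom_depths.csv",
      "ground_truth.json")))))
  back <- read_survey(dir)
  expect_equal(as.data.frame(back$trait_table), as.data.frame(b$trait_table),
               ignore_attr = TRUE)
  expect_equal(back$observations$biomass, b$observations$biomass)
  expect_equal(back$samples$date, b$samples$date)
  # and the re-read bundle passes the full pipeline
  pl <- run_trait_pipeline(back)
  expect_equal(nrow(pl$responses), nrow(b$samples))
})

test_that("simulated observations are internally consistent", {
  b <- small_bundle()
  obs <- b$observations
  # biomass consistent with biovolume concentration at 1 g/cm^3
  bv_per_l <- obs$units_per_litre * obs$biovolume_per_unit
  expect_equal(convert_biomass(bv_per_l), obs$biomass, tolerance = 1e-10)
  expect_true(all(obs$cells_per_unit[obs$unit_type == "cell"] == 1))
  # expected directions table derives from the config
  exp <- injected_effect_signs(small_cfg())
  expect_true(all(exp$term %in% c("Temp", "Sal", "Secchi", "E", "TP")))
  expect_true(all(exp$sign %in% c("positive", "negative")))
  expect_gte(nrow(exp), 8)
})

test_that("the full pipeline runs end-to-end on a written bundle", {
  dir <- tempfile("survey")
  simulate_survey(small_cfg(seed = 15), dir = dir)
  pl <- run_trait_pipeline(read_survey(dir))
  expect_s3_class(pl, "trait_pipeline")
  expect_identical(colnames(pl$responses)[-1], response_names())
  md <- pl$model_data
  expect_true(all(c("Temp", "Sal", "Secchi", "E", "TP", "L", "Area",
                    "water_body", "station", "time") %in% names(md)))
  expect_false(anyNA(md$TP))
  expect_equal(anyDuplicated(md[, c("station", "time")]), 0)
})

test_that("end-to-end recovery: random SDs within 50%, null covariates quiet", {
  # random intercept SDs propagate through aggregation to biomass responses
  fs <- suppressWarnings(fit_trait_models(default_pipeline(),
                                          responses = "nonHAB biom"))
  fit <- fs$fits[["nonHAB biom"]]
  expect_true(fit$converged)
  sds <- random_intercept_sd(fit)
  expect_lt(abs(sds[["station"]] - 0.3) / 0.3, 0.5)
  expect_lt(abs(sds[["water_body"]] - 0.3) / 0.3, 0.5)
  # the wGF area was generated with the largest residual SD multiplier
  mult <- area_variance_multipliers(fit)
  expect_equal(names(which.max(mult)), "wGF")
  # covariates with zero injected effect (salinity, stratification) stay
  # below the study's alpha = 0.001 across replicate null-style checks
  # (10 reduced surveys x 2 biomass responses x 2 terms: >= 95% quiet)
  p_null <- c()
  for (sd in 31:40) {
    pl <- run_trait_pipeline(simulate_survey(small_cfg(seed = sd)))
    fs <- suppressWarnings(fit_trait_models(
      pl, responses = c("nonNfix biom", "nonHAB biom")))
    for (nm in names(fs$fits)) {
      if (!fs$fits[[nm]]$converged) next
      p_null <- c(p_null, term_pvalue(fs$fits[[nm]], "Sal"),
                  term_pvalue(fs$fits[[nm]], "E"))
    }
  }
  expect_gte(length(p_null), 30)
  expect_gte(mean(p_null >= 0.001), 0.95)
})
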