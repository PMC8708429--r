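test_that("response matrix has exactly the 27 canonical columns", {
  rn <- response_names()
  expect_length(rn, 27)
  resp <- small_pipeline()$responses
  expect_identical(colnames(resp)[-1], rn)
  expect_equal(nrow(resp), nrow(small_bundle()$samples))
})

test_that("degenerate single-carrier community gives share one", {
  traits <- data.frame(
    taxon_id = "fixer", n_fixation = TRUE, mixotrophy = FALSE,
    motility = FALSE, buoyancy = TRUE, harmful = FALSE,
    group = "cyanobacteria", excluded_category = NA_character_,
    stringsAsFactors = FALSE)
  traits$hab_class <- harmful_partition(traits$harmful, traits$group)
  obs <- data.frame(
    sample_id = "s1", taxon_id = "fixer", unit_type = "cell",
    units_per_litre = 1000, cells_per_unit = 1, biovolume_per_unit = 500,
    biomass = 0.5, max_dimension = 9.8, stringsAsFactors = FALSE)
  r <- build_responses(obs, traits)
  expect_equal(r[["Nfix share"]], 1)
  expect_equal(r[["nonNfix share"]], 0)
  expect_equal(r[["Nfix biom"]], 0.5)
  expect_equal(r[["Small share"]], 1)
  expect_equal(r[["aveESD"]], equivalent_spherical_diameter(500))
})

test_that("two-taxon community partitions the harmfulness classes", {
  traits <- data.frame(
    taxon_id = c("hab", "dia"),
    n_fixation = FALSE, mixotrophy = FALSE, motility = FALSE,
    buoyancy = FALSE, harmful = c(TRUE, FALSE),
    group = c("cyanobacteria", "eukaryote"),
    excluded_category = NA_character_, stringsAsFactors = FALSE)
  traits$hab_class <- harmful_partition(traits$harmful, traits$group)
  obs <- data.frame(
    sample_id = "s1", taxon_id = c("hab", "dia"), unit_type = "cell",
    units_per_litre = c(100, 100), cells_per_unit = 1,
    biovolume_per_unit = c(3e5, 7e5), biomass = c(30, 70),
    max_dimension = c(12, 15), stringsAsFactors = FALSE)
  r <- build_responses(obs, traits)
  expect_equal(r[["HABcyano share"]], 0.3)
  expect_equal(r[["nonHAB share"]], 0.7)
  expect_equal(r[["HABalg share"]], 0)
  expect_equal(r[["HABcyano biom"]] + r[["HABalg biom"]] + r[["nonHAB biom"]],
               100)
})

test_that("zero-biomass samples are dropped with a warning", {
  traits <- data.frame(
    taxon_id = "t1", n_fixation = FALSE, mixotrophy = FALSE,
    motility = FALSE, buoyancy = FALSE, harmful = FALSE,
    group = "eukaryote", excluded_category = NA_character_,
    stringsAsFactors = FALSE)
  traits$hab_class <- harmful_partition(traits$harmful, traits$group)
  obs <- data.frame(
    sample_id = c("keep", "zero"), taxon_id = "t1", unit_type = "cell",
    units_per_litre = c(10, 0), cells_per_unit = 1,
    biovolume_per_unit = 1e5, biomass = c(1, 0), max_dimension = 8,
    stringsAsFactors = FALSE)
  expect_warning(r <- build_responses(obs, traits), "zero total biomass")
  expect_equal(r$sample_id, "keep")
})

test_that("partition invariants hold on a simulated survey", {
  pl <- small_pipeline()
  r <- pl$responses
  total <- r[["Nfix biom"]] + r[["nonNfix biom"]]
  for (stem in list(c("Buo", "nonBuo"), c("Mot", "nonMot"), c("MX", "AU"),
                    c("Small", "Large"))) {
    expect_equal(r[[paste(stem[1], "biom")]] + r[[paste(stem[2], "biom")]],
                 total, tolerance = 1e-12)
    expect_equal(r[[paste(stem[1], "share")]] + r[[paste(stem[2], "share")]],
                 rep(1, nrow(r)), tolerance = 1e-12)
  }
  expect_equal(r[["HABcyano biom"]] + r[["HABalg biom"]] + r[["nonHAB biom"]],
               total, tolerance = 1e-12)
  expect_true(all(r[["Nfix share"]] >= 0 & r[["Nfix share"]] <= 1))
})

test_that("response construction is invariant to observation row order", {
  b <- small_bundle()
  filt <- apply_exclusion_filters(b$observations, b$trait_table)
  traits <- resolve_traits(b$trait_table)
  r1 <- build_responses(filt$observations, traits)
  set.seed(2)
  shuffled <- filt$observations[sample(nrow(filt$observations)), ]
  r2 <- build_responses(shuffled, traits)
  expect_equal(r1, r2)
})

test_that("Box-Cox exponent is recovered by profile likelihood", {
  set.seed(77)
  # lognormal data: true lambda 0
  y0 <- exp(rnorm(500))
  expect_gte(boxcox_lambda(y0), -0.15)
  expect_lte(boxcox_lambda(y0), 0.15)
  # already-normal positive data: true lambda 1
  y1 <- rnorm(500, mean = 20, sd = 2)
  expect_gte(boxcox_lambda(y1), 0.7)
  expect_lte(boxcox_lambda(y1), 1.3)
  expect_error(boxcox_lambda(rep(3, 10)), "constant")
  expect_error(boxcox_lambda(c(-1, 2)), "positive")
})

test_that("grid-search exponent matches the MASS profile oracle", {
  set.seed(13)
  for (y in list(exp(rnorm(300)), rnorm(300, 50, 5)^1.5)) {
    prof <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, by = 0.01),
                         plotit = FALSE)
    expect_equal(boxcox_lambda(y), prof$x[which.max(prof$y)],
                 tolerance = 0.011)
  }
})

test_that("Box-Cox transform and inverse are consistent", {
  expect_equal(boxcox_transform(exp(1), lambda = 0), 1)
  expect_equal(boxcox_transform(5, lambda = 1), 4)
  set.seed(21)
  y <- runif(100, 0.01, 50)
  for (lam in c(-1, -0.3, 0, 0.5, 1, 2)) {
    z <- boxcox_transform(y, lam, shift = 0.2)
    expect_equal(boxcox_inverse(z, lam, shift = 0.2), y, tolerance = 1e-10)
  }
  expect_error(boxcox_transform(-2, 0.5), "positive")
})

test_that("zero-containing responses get the half-minimum shift", {
  y <- c(0, 0.4, 1.2, 8, 0, 2.1)
  bc <- boxcox_fit(y)
  expect_equal(bc$shift, 0.2)
  pos <- boxcox_fit(y + 1)
  expect_equal(pos$shift, 0)
  expect_error(boxcox_fit(rep(0, 5)), "all-zero")
})

test_that("transform_responses records per-response metadata", {
  pl <- small_pipeline()
  tr <- transform_responses(pl$responses, skip = "aveESD")
  expect_true(all(is.finite(tr$meta$lambda[tr$meta$response != "aveESD"])))
  expect_true(is.na(tr$meta$lambda[tr$meta$response == "aveESD"]))
  expect_equal(tr$transformed$aveESD, pl$responses$aveESD)
  # shares in [0,1] get shifted only when zeros occur
  shares0 <- pl$responses[["HABalg share"]]
  i <- tr$meta$response == "HABalg share"
  if (any(shares0 == 0)) expect_gt(tr$meta$shift[i], 0) else
    expect_equal(tr$meta$shift[i], 0)
  f <- tempfile(fileext = ".json")
  write_transform_meta(tr$meta, f)
  expect_true(file.exists(f))
})
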