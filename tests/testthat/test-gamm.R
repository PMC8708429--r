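# spec for a plain fixed-effects model (no random terms, no correlation,
# no variance weights) used by the oracle comparisons
plain_spec <- function(smooths = character(0), factors = "Area", k = 6,
                       alpha = 0.001) {
  trait_gamm_spec(smooths = smooths, k = k, factors = factors,
                  random = character(0), car1 = FALSE,
                  variance_by_area = FALSE, alpha = alpha)
}

balanced_anova_data <- function(k = 4, n = 10, seed = 31, delta = c(0, 0.8,
                                                                    1.6, 0.4)) {
  set.seed(seed)
  data.frame(Area = factor(rep(LETTERS[1:k], each = n)),
             y = rnorm(k * n) + rep(delta[1:k], each = n))
}

test_that("Tukey pairwise contrasts match classical Tukey HSD when balanced", {
  d <- balanced_anova_data()
  fit <- fit_trait_gamm(d, "y", plain_spec())
  expect_true(fit$converged)
  ct <- tukey_pairwise(estimated_marginal_means(fit, "Area"))
  expect_equal(nrow(ct), 6)

  # oracle 1: direct studentized-range computation
  n <- 10
  gm <- tapply(d$y, d$Area, mean)
  s2 <- sum((d$y - ave(d$y, d$Area))^2) / (nrow(d) - 4)
  for (i in seq_len(nrow(ct))) {
    lv <- strsplit(ct$contrast[i], " - ")[[1]]
    q <- abs(gm[lv[1]] - gm[lv[2]]) / sqrt(s2 / n)
    p_oracle <- ptukey(q, nmeans = 4, df = nrow(d) - 4, lower.tail = FALSE)
    expect_equal(ct$p_value[i], unname(p_oracle), tolerance = 1e-6)
  }
  # oracle 2: stats::TukeyHSD on the aov fit
  th <- TukeyHSD(aov(y ~ Area, data = d))$Area
  key <- vapply(strsplit(ct$contrast, " - "), function(x)
    paste(rev(x), collapse = "-"), character(1))
  expect_equal(ct$p_value, unname(th[key, "p adj"]), tolerance = 1e-6)
})

test_that("identical group means give adjusted p near one", {
  d <- balanced_anova_data(delta = c(0, 0, 0, 0), seed = 101)
  d$y <- rep(rnorm(10), times = 4)      # identical responses per group
  fit <- fit_trait_gamm(d, "y", plain_spec())
  ct <- tukey_pairwise(estimated_marginal_means(fit, "Area"))
  expect_true(all(ct$p_value > 0.999))
})

test_that("two levels reduce to the unadjusted two-sample t-test", {
  set.seed(55)
  d <- data.frame(Area = factor(rep(c("A", "B"), each = 12)),
                  y = rnorm(24) + rep(c(0, 0.5), each = 12))
  fit <- fit_trait_gamm(d, "y", plain_spec())
  ct <- tukey_pairwise(estimated_marginal_means(fit, "Area"))
  p_t <- summary(stats::lm(y ~ Area, data = d))$coefficients[2, 4]
  expect_equal(ct$p_value, unname(p_t), tolerance = 1e-9)
})

test_that("marginal means reduce to cell means in a balanced layout", {
  d <- balanced_anova_data()
  fit <- fit_trait_gamm(d, "y", plain_spec())
  emm <- estimated_marginal_means(fit, "Area")
  expect_equal(emm$emmean, as.numeric(tapply(d$y, d$Area, mean)),
               tolerance = 1e-10)
  expect_equal(emm$df, 36)
})

test_that("a covariate equally distributed across groups leaves contrasts
           unchanged", {
  d <- balanced_anova_data()
  # identical covariate values within every group: orthogonal to contrasts
  d$x <- rep(seq(-1, 1, length.out = 10), times = 4)
  d$y <- d$y + 0.7 * d$x
  f0 <- fit_trait_gamm(d, "y", plain_spec())
  f1 <- fit_trait_gamm(d, "y", plain_spec(smooths = "x", k = 4))
  e0 <- estimated_marginal_means(f0, "Area")
  e1 <- estimated_marginal_means(f1, "Area")
  # the smooth's value at the reference point shifts all levels equally, so
  # differences of marginal means are what orthogonality preserves
  d0 <- outer(e0$emmean, e0$emmean, "-")
  d1 <- outer(e1$emmean, e1$emmean, "-")
  expect_equal(d1, d0, tolerance = 1e-8)
})

test_that("unbalanced groups give adjusted predictions, not raw means", {
  set.seed(73)
  n1 <- 30; n2 <- 10
  g <- factor(rep(c("A", "B"), c(n1, n2)))
  x <- c(rnorm(n1, -0.5), rnorm(n2, 1.5))     # covariate confounded with group
  y <- 1 + 2 * x + ifelse(g == "B", 1, 0) + rnorm(n1 + n2, sd = 0.3)
  d <- data.frame(Area = g, x = x, y = y)
  fit <- fit_trait_gamm(d, "y", plain_spec(smooths = "x", k = 4))
  emm <- estimated_marginal_means(fit, "Area")
  raw <- tapply(d$y, d$Area, mean)
  expect_gt(min(abs(emm$emmean - raw)), 0.5)
  # closed form on the same 2-group linear model: EMM_a = b0 + b_a + b_x * xbar
  lmfit <- stats::lm(y ~ Area + x, data = d)
  closed <- c(coef(lmfit)[1] + coef(lmfit)["x"] * mean(x),
              coef(lmfit)[1] + coef(lmfit)["AreaB"] +
                coef(lmfit)["x"] * mean(x))
  # smooth shrinks to essentially linear here; agreement is approximate
  expect_equal(emm$emmean, unname(closed), tolerance = 0.02)
})

test_that("adjusted p-values are monotone in the unadjusted t-statistics", {
  d <- balanced_anova_data(seed = 7)
  fit <- fit_trait_gamm(d, "y", plain_spec())
  ct <- tukey_pairwise(estimated_marginal_means(fit, "Area"))
  o <- order(abs(ct$t_ratio))
  expect_true(all(diff(ct$p_value[o]) <= 1e-12))
  # and never smaller than the unadjusted two-sided p
  p_unadj <- 2 * pt(abs(ct$t_ratio), df = ct$df, lower.tail = FALSE)
  expect_true(all(ct$p_value >= p_unadj - 1e-12))
})

test_that("effect directions are recovered from known generators", {
  set.seed(99)
  n <- 300
  x <- runif(n, -2, 2)
  g <- factor(rep(c("A", "B"), length.out = n))
  sp <- plain_spec(smooths = "x")
  # increasing linear effect
  d <- data.frame(x = x, Area = g, y = 1.2 * x + rnorm(n))
  f <- fit_trait_gamm(d, "y", sp)
  expect_equal(classify_effect_direction(f, "x"), "positive")
  # decreasing
  d$y <- -1.2 * x + rnorm(n)
  f <- fit_trait_gamm(d, "y", sp)
  expect_equal(classify_effect_direction(f, "x"), "negative")
  # unimodal (quadratic) effect
  d$y <- -1.5 * x^2 + rnorm(n)
  f <- fit_trait_gamm(d, "y", sp)
  expect_equal(classify_effect_direction(f, "x"), "nonlinear")
  # no effect at the study's strict threshold
  d$y <- rnorm(n)
  f <- fit_trait_gamm(d, "y", sp)
  expect_equal(classify_effect_direction(f, "x"), "ns")
  expect_error(classify_effect_direction(f, "Area"), "not a smooth term")
})

test_that("plain fit equals a hand-solved penalized regression", {
  set.seed(12)
  n <- 150
  d <- data.frame(x = runif(n, 0, 1), Area = factor(rep(c("A", "B", "C"),
                                                        each = 50)))
  d$y <- sin(2 * pi * d$x) + 0.5 * (d$Area == "B") + rnorm(n, sd = 0.3)
  fit <- fit_trait_gamm(d, "y", plain_spec(smooths = "x", k = 6))
  g <- fit$gam
  X <- predict(g, type = "lpmatrix")
  # embed the single smooth's penalty at its coefficient block
  sm <- g$smooth[[1]]
  S <- matrix(0, ncol(X), ncol(X))
  idx <- sm$first.para:sm$last.para
  S[idx, idx] <- sm$S[[1]] * g$sp[1]
  beta_hand <- solve(crossprod(X) + S, crossprod(X, d$y))
  expect_equal(unname(coef(g)), as.numeric(beta_hand), tolerance = 1e-6)
})

test_that("infinite smoothing collapses the smooth to a straight line", {
  set.seed(14)
  n <- 120
  d <- data.frame(x = runif(n, -1, 1),
                  Area = factor(rep(c("A", "B"), each = 60)))
  d$y <- 0.8 * d$x + 0.4 * (d$Area == "B") + rnorm(n, sd = 0.5)
  fit <- fit_trait_gamm(d, "y", plain_spec(smooths = "x", k = 6), sp = 1e9)
  expect_lt(abs(term_edf(fit, "x") - 1), 1e-3)
  lmfit <- stats::lm(y ~ x + Area, data = d)
  expect_equal(unname(fitted(fit$gam)), unname(fitted(lmfit)),
               tolerance = 1e-4)
})

test_that("model frame validation fails loudly", {
  d <- balanced_anova_data()
  expect_error(fit_trait_gamm(d, "nope", plain_spec()), "missing column")
  d1 <- d
  d1$Area <- factor("A", levels = "A")
  expect_error(fit_trait_gamm(d1, "y", plain_spec()),
               "fewer than 2 observed levels")
  fit <- fit_trait_gamm(d, "y", plain_spec())
  expect_error(term_pvalue(fit, "Secchi"), "not part of the model")
  expect_error(trait_gamm_spec(k = 3), "k must be >= 4")
  # duplicated time within a station is rejected for the CAR(1) structure
  d2 <- d
  d2$station <- rep(c("s1", "s2"), each = 20)
  d2$water_body <- "wb"
  d2$time <- rep(1:10, 4)
  spec <- trait_gamm_spec(smooths = character(0), factors = "Area",
                          random = c("water_body", "station"), car1 = TRUE,
                          variance_by_area = FALSE)
  expect_error(fit_trait_gamm(d2, "y", spec), "unique within")
})

test_that("mixed fit recovers structure on one small survey", {
  pl <- small_pipeline()
  fs <- suppressWarnings(fit_trait_models(pl, responses = "MX share"))
  fit <- fs$fits[["MX share"]]
  expect_true(fit$converged)
  expect_true(is.finite(car1_phi(fit)))
  expect_gt(car1_phi(fit), -1)
  expect_lt(car1_phi(fit), 1)
  sds <- random_intercept_sd(fit)
  expect_named(sds, c("water_body", "station"))
  expect_true(all(sds >= 0))
  mult <- area_variance_multipliers(fit)
  expect_true(length(mult) >= 3)   # reference + three estimated
  for (tm in c("Temp", "Sal", "Secchi", "E", "TP", "L", "Area")) {
    p <- term_pvalue(fit, tm)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("model config round-trips through JSON", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(k = 8, alpha = 0.001, car1 = FALSE), f,
                       auto_unbox = TRUE)
  spec <- read_gamm_config(f)
  expect_equal(spec$k, 8)
  expect_false(spec$car1)
  expect_equal(spec$smooths, c("Temp", "Sal", "Secchi", "E", "TP"))
  jsonlite::write_json(list(bogus = 1), f, auto_unbox = TRUE)
  expect_error(read_gamm_config(f), "unknown config field")
})
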