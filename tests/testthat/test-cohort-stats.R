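test_that("gaussian group coefficient equals the difference of means", {
  d <- data.frame(generation = rep(c("F1", "F2"), each = 10),
                  rearing_temperature_C = 5,
                  lifespan_days = rep(c(10, 20), each = 10))
  eff <- fit_trait_glm(d, "lifespan_days", "generation", family = "gaussian")
  expect_equal(eff$estimate[eff$term == "generationF2"], 10)
  expect_true(all(eff$ci_low <= eff$estimate & eff$estimate <= eff$ci_high))
})

test_that("poisson group coefficient equals the log ratio of group means", {
  d <- data.frame(generation = rep(c("F1", "F2"), each = 6),
                  rearing_temperature_C = 5,
                  fecundity = c(3, 4, 5, 4, 4, 4, 8, 7, 9, 8, 8, 8))
  eff <- fit_trait_glm(d, "fecundity", "generation", family = "poisson")
  expect_equal(eff$estimate[eff$term == "generationF2"],
               log(mean(d$fecundity[7:12]) / mean(d$fecundity[1:6])),
               tolerance = 1e-6)
})

test_that("overdispersed counts trigger the negative-binomial upgrade", {
  set.seed(31)
  d <- data.frame(generation = rep(c("F1", "F2"), each = 40),
                  rearing_temperature_C = 5,
                  fecundity = rnbinom(80, mu = rep(c(8, 16), each = 40),
                                      size = 1.2))
  eff <- fit_trait_glm(d, "fecundity", "generation", family = "auto")
  expect_equal(attr(eff, "family"), "negbin")
  # and the estimate still targets the log mean ratio
  expect_equal(eff$estimate[2], log(mean(d$fecundity[41:80]) /
                                      mean(d$fecundity[1:40])),
               tolerance = 0.05)
})

test_that("standardized gaussian slope is b * SDx / SDy and scale-free", {
  set.seed(7)
  d <- data.frame(generation = "F1", rearing_temperature_C = 5,
                  oviposition_order = 1:30,
                  oviposition_day = 5 + 3 * (1:30) + rnorm(30))
  raw <- fit_trait_glm(d, "oviposition_day", "oviposition_order",
                       family = "gaussian")
  std <- standardized_coefficients(d, "oviposition_day", "oviposition_order",
                                   family = "gaussian")
  b <- raw$estimate[2]
  expect_equal(std$estimate[2],
               b * sd(d$oviposition_order) / sd(d$oviposition_day),
               tolerance = 1e-8)

  d10 <- d
  d10$oviposition_day <- d10$oviposition_day * 10
  std10 <- standardized_coefficients(d10, "oviposition_day",
                                     "oviposition_order",
                                     family = "gaussian")
  expect_equal(std10$estimate, std$estimate, tolerance = 1e-8)
  # already-standardized data: standardized fit equals plain fit
  ds <- d
  ds$oviposition_day <- as.numeric(scale(ds$oviposition_day))
  ds$oviposition_order <- as.numeric(scale(ds$oviposition_order))
  expect_equal(standardized_coefficients(ds, "oviposition_day",
                                         "oviposition_order",
                                         family = "gaussian")$estimate,
               fit_trait_glm(ds, "oviposition_day", "oviposition_order",
                             family = "gaussian")$estimate,
               tolerance = 1e-8)
  expect_error(
    standardized_coefficients(
      data.frame(generation = "F1", rearing_temperature_C = 5,
                 oviposition_order = rep(2, 5), oviposition_day = 1:5),
      "oviposition_day", "oviposition_order", family = "gaussian"),
    "zero-variance")
})

test_that("model deviance never increases when adding a predictor", {
  sim <- generate_lifehistory_cohort(lifehistory_config(), seed = 17)
  tr <- derive_traits(sim$cohort)
  f1 <- attr(fit_trait_glm(tr, "lifespan_days", "generation"), "fit")
  f2 <- attr(fit_trait_glm(tr, "lifespan_days",
                           c("generation", "temperature")), "fit")
  expect_lte(deviance(f2), deviance(f1) + 1e-8)
})

test_that("Kruskal-Wallis H matches the direct rank-sum oracle", {
  g3 <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(unlist(g3), rep(1:3, each = 3))
  expect_equal(kw$H, kw_oracle(g3))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)

  g2 <- list(c(1, 2), c(3, 4))
  kw2 <- kruskal_wallis(unlist(g2), rep(1:2, each = 2))
  expect_equal(kw2$H, kw_oracle(g2))
  expect_equal(kw2$H, 2.4)

  # with ties, against the oracle's midrank tie correction
  gt <- list(c(1, 2, 2, 3), c(2, 4, 4), c(5, 5, 6))
  kwt <- kruskal_wallis(unlist(gt), rep(1:3, lengths(gt)))
  expect_equal(kwt$H, kw_oracle(gt))
})

test_that("identical samples give H = 0, p = 1", {
  kw <- kruskal_wallis(rep(2, 9), rep(1:3, each = 3))
  expect_equal(kw$H, 0)
  expect_equal(kw$p_value, 1)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(11)
  x <- rlnorm(30)
  g <- rep(1:3, each = 10)
  h0 <- kruskal_wallis(x, g)$H
  expect_equal(kruskal_wallis(log(x), g)$H, h0)
  expect_equal(kruskal_wallis(x^3, g)$H, h0)
  expect_equal(kruskal_wallis(rank(x), g)$H, h0)
})

test_that("post-hoc table is symmetric with adjusted p-values", {
  set.seed(12)
  x <- c(rnorm(10), rnorm(10, 3), rnorm(10, 6))
  g <- rep(c("a", "b", "c"), each = 10)
  kw <- kruskal_wallis(x, g)
  expect_true(isSymmetric(kw$posthoc))
  expect_true(all(kw$posthoc >= 0 & kw$posthoc <= 1))
  expect_lt(kw$posthoc["a", "c"], 0.05)
})

test_that("interaction CI covers zero on additive data", {
  # Wald z intervals are asymptotic; 20 females per cell keeps the
  # t-vs-z difference negligible.
  covered <- 0
  for (r in 1:100) {
    set.seed(600 + r)
    d <- data.frame(
      generation = rep(c("F1", "F2"), each = 40),
      rearing_temperature_C = rep(rep(c(5, 15), each = 20), 2)
    )
    d$lifespan_days <- 50 + 10 * (d$generation == "F2") -
      20 * (d$rearing_temperature_C == 15) + rnorm(80, sd = 8)
    eff <- fit_trait_glm(d, "lifespan_days",
                         c("generation", "temperature",
                           "generation:temperature"))
    row <- grepl(":", eff$term)
    if (eff$ci_low[row] <= 0 && eff$ci_high[row] >= 0) covered <- covered + 1
  }
  expect_gte(covered, 93)
})

test_that("planted lifespan difference between temperatures recovers sign", {
  groups <- data.frame(
    generation = "F1", temperature_C = c(5, 15), n = 15,
    lifespan_mean = c(90, 60), lifespan_sd = 20,
    age_first_mean = c(34, 20), age_first_sd = 5,
    interval_mean = c(14, 9), interval_sd = 3,
    clutch_mean = 2.5, clutch_slope = 0.1, hatch_prob = 0.6,
    hatch_time_mean = c(22, 12), hatch_time_sd = 3,
    stringsAsFactors = FALSE
  )
  cfg <- lifehistory_config(groups = groups)
  hits <- 0
  for (r in 1:100) {
    sim <- generate_lifehistory_cohort(cfg, seed = 7000 + r)
    tr <- derive_traits(sim$cohort)
    eff <- fit_trait_glm(tr, "lifespan_days", "temperature")
    if (eff$estimate[2] < 0) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
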