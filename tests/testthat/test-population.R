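# Stage 1: population simulation, calibration and the CI-based
# categorisation rules.

test_that("calibrate centres the population mean OR at exactly 1", {
  expect_equal(calibrate(rep(0, 5)), 0)
  expect_equal(calibrate(c(0, log(2))), log(1.5), tolerance = 1e-12)
  set.seed(4)
  x <- rnorm(1000, sd = 0.7)
  s <- calibrate(x)
  expect_equal(mean(exp(x - s)), 1, tolerance = 1e-12)
  # geometric variant centres the mean log OR instead
  expect_equal(mean(x - calibrate(x, mean_type = "geometric")), 0,
               tolerance = 1e-12)
})

test_that("profile sampling respects HWE dosage moments and HLA carriage", {
  set.seed(21)
  f0 <- toy_snp_factors(2, 0)        # control_freq 0: never carried
  d0 <- riskcat:::sample_profiles(2000, f0)$dosage
  expect_true(all(d0 == 0))

  f5 <- toy_snp_factors(2, 0.5)
  d5 <- riskcat:::sample_profiles(1e5, f5)$dosage
  expect_equal(mean(d5), 1, tolerance = 3 * sqrt(0.5 / 1e5))

  z <- qnorm(0.975)
  hla <- risk_factors(data.frame(
    id = c("*04", "*03"), kind = "hla_allele", resolution = "two_digit",
    or = c(2, 1.5), ci_low = c(2, 1.5) * exp(-z * 0.1),
    ci_high = c(2, 1.5) * exp(z * 0.1), control_freq = c(0.2, 0.1)))
  prof <- riskcat:::sample_profiles(1e5, hla)
  carried <- mean(prof$dosage[, "*04"] >= 1)
  expect_equal(carried, 1 - 0.8^2,
               tolerance = 3 * sqrt(0.36 * 0.64 / 1e5) + 1e-3)
})

test_that("the 3-SNP toy population has all 27 genotype combinations", {
  f <- toy3()
  fit_mc <- riskcat(f, toy3_config(), m = 1e5, seed = 5,
                    method = "monte-carlo")
  expect_equal(nrow(fit_mc$population), 27)
  fit_en <- riskcat(f, toy3_config(), method = "enumerate")
  expect_equal(nrow(fit_en$population), 27)
  expect_equal(sum(fit_en$population$weight), 1, tolerance = 1e-12)
})

test_that("identical seeds reproduce the fit bit-for-bit; different seeds agree within MC error", {
  f <- toy3()
  a <- riskcat(f, toy3_config(), m = 2e4, seed = 17, method = "monte-carlo")
  b <- riskcat(f, toy3_config(), m = 2e4, seed = 17, method = "monte-carlo")
  expect_identical(a$population, b$population)
  expect_identical(a$categoriser, b$categoriser)

  c2 <- riskcat(f, toy3_config(), m = 2e4, seed = 99, method = "monte-carlo")
  expect_equal(a$categoriser$baseline, c2$categoriser$baseline,
               tolerance = 0.05)
  expect_equal(a$categoriser$first_elevated, c2$categoriser$first_elevated,
               tolerance = 0.05)
})

test_that("Monte-Carlo category proportions match exhaustive HWE enumeration", {
  f <- toy3()
  en <- riskcat(f, toy3_config(), method = "enumerate")
  m <- 1e5
  mc <- riskcat(f, toy3_config(), m = m, seed = 31, method = "monte-carlo")
  p_en <- tapply(en$population$weight, en$population$category, sum,
                 default = 0)
  p_mc <- tapply(mc$population$weight, mc$population$category, sum,
                 default = 0)
  for (k in names(p_en)) {
    se <- sqrt(p_en[[k]] * (1 - p_en[[k]]) / m)
    expect_lt(abs(p_mc[[k]] - p_en[[k]]), 3 * se + 1e-9)
  }
})

test_that("the hand-worked five-profile population categorises as reduced/average/average/elevated/high", {
  pop <- five_profiles()
  cat5 <- build_categoriser(pop)
  expect_equal(unname(cat5$baseline), c(0.8, 1.25))
  expect_equal(unname(cat5$first_elevated), c(1.5, 2.7))
  expect_equal(as.character(categorise(pop, cat5)),
               c("reduced", "average", "average", "elevated", "high"))
})

test_that("degenerate populations classify everything average", {
  pop <- data.frame(or = rep(1.2, 4), ci_low = rep(0.9, 4),
                    ci_high = rep(1.6, 4))
  cz <- build_categoriser(pop)
  expect_null(cz$first_elevated)
  expect_true(all(categorise(pop, cz) == "average"))
  # shared endpoint counts as overlap -> average
  touching <- data.frame(or = 1.3, ci_low = 1.25, ci_high = 1.4)
  cat5 <- build_categoriser(five_profiles())
  expect_equal(as.character(categorise(touching, cat5)), "average")
  below <- data.frame(or = 0.25, ci_low = 0.2, ci_high = 0.3)
  expect_equal(as.character(categorise(below, cat5)), "reduced")
})

test_that("populations with no separating profile have no elevated or high class", {
  f <- toy_snp_factors(1.1, 0.3, sigma = 0.5)  # huge uncertainty
  fit <- riskcat(f, model_config("weak", "s1"), method = "enumerate")
  expect_null(fit$categoriser$first_elevated)
  expect_true(all(fit$population$category %in% c("reduced", "average")))
})

test_that("categories partition the population and respect the boundaries", {
  f <- ra_risk_factors()
  fit <- riskcat(f, ra_model_config("HLA", f), m = 2e4, seed = 3)
  pop <- fit$population
  expect_false(anyNA(pop$category))
  expect_equal(sum(pop$weight), 1, tolerance = 1e-9)
  b <- fit$categoriser$baseline
  fe <- fit$categoriser$first_elevated
  expect_true(all(pop$ci_high[pop$category == "reduced"] < b[["low"]]))
  expect_true(all(pop$ci_low[pop$category == "high"] > fe[["high"]]))
  ave <- pop$category == "average"
  expect_true(all(pop$ci_low[ave] <= b[["high"]] &
                    pop$ci_high[ave] >= b[["low"]]))
})

test_that("greater precision never shrinks the non-average mass", {
  f_wide <- toy3(sigma = rep(0.25, 3))
  f_tight <- toy3(sigma = rep(0.1, 3))
  cfg <- toy3_config()
  mass <- function(f) {
    fit <- riskcat(f, cfg, method = "enumerate")
    sum(fit$population$weight[fit$population$category != "average"])
  }
  expect_gte(mass(f_tight), mass(f_wide))
})

test_that("a sex-specific exposure requires the matching sex restriction", {
  f <- toy_env_factors(applies_to = "males")
  cfg_bad <- model_config("env", "smoke", sex_restriction = "none")
  expect_error(riskcat(f, cfg_bad, m = 1000), "sex restriction")
  cfg_ok <- model_config("env", "smoke", sex_restriction = "males_only")
  fit <- riskcat(f, cfg_ok, method = "enumerate")
  expect_equal(nrow(fit$population), 2)
})

test_that("HLA allele frequencies summing above one are rejected", {
  z <- qnorm(0.975)
  bad <- risk_factors(data.frame(
    id = c("*04", "*03"), kind = "hla_allele", resolution = "two_digit",
    or = c(2, 2), ci_low = 2 * exp(-z * 0.1), ci_high = 2 * exp(z * 0.1),
    control_freq = c(0.7, 0.6)))
  expect_error(riskcat(bad, model_config("bad", c("*04", "*03")), m = 1000),
               "sum")
})
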