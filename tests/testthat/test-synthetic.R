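# Synthetic cohort generator: prevalence calibration, parameter recovery,
# resolution masking, onset model and missingness.

test_that("solve_intercept hits the target prevalence", {
  expect_equal(solve_intercept(rep(0, 100), 0.01), qlogis(0.01),
               tolerance = 1e-8)
  # self-consistency on an independent draw from the same profile law
  set.seed(41)
  f <- toy_snp_factors(2.5, 0.3)
  pool1 <- drop(riskcat:::sample_profiles(1e5, f)$dosage) * log(2.5)
  pool1 <- pool1 - calibrate(pool1)
  a <- solve_intercept(pool1, 0.05)
  pool2 <- drop(riskcat:::sample_profiles(1e5, f)$dosage) * log(2.5)
  pool2 <- pool2 - calibrate(pool2)
  realised <- mean(plogis(a + pool2))
  expect_equal(realised, 0.05, tolerance = 3 * sqrt(0.05 * 0.95 / 1e5) + 2e-3)
  # symmetric profile law at prevalence 0.5: alpha ~ -mean log OR
  lor <- rnorm(1e5, 0, 0.3)
  lor <- lor - mean(lor)
  expect_equal(solve_intercept(lor, 0.5), 0, tolerance = 0.02)
})

test_that("seeded generation is fully deterministic", {
  f <- toy3()
  cfg <- toy3_config()
  synth <- synth_config(n_cases = 150, n_controls = 150)
  a <- simulate_cohort(f, cfg, synth, seed = 5, pool_m = 2e4)
  b <- simulate_cohort(f, cfg, synth, seed = 5, pool_m = 2e4)
  expect_identical(a, b)
  expect_equal(sum(a$status == "case"), 150)
  expect_equal(sum(a$status == "control"), 150)
})

test_that("null models produce equal case and control allele frequencies", {
  set.seed(13)
  f <- toy_snp_factors(c(1, 1), c(0.3, 0.5), sigma = c(0.05, 0.05))
  cfg <- model_config("null", f$id, prevalence = 0.1)
  coh <- simulate_cohort(f, cfg, synth_config(n_cases = 2000,
                                              n_controls = 2000,
                                              missing_rates = c(snp = 0)),
                         seed = 19, pool_m = 2e4)
  for (id in f$id) {
    f_ca <- mean(coh[[id]][coh$status == "case"]) / 2
    f_co <- mean(coh[[id]][coh$status == "control"]) / 2
    se <- sqrt(f_co * (1 - f_co) / (2 * 2000)) * sqrt(2)
    expect_lt(abs(f_ca - f_co), 4 * se)
  }
})

test_that("case allele frequencies shift in the direction of the generating OR", {
  set.seed(29)
  f <- toy_snp_factors(c(2.0, 0.5), c(0.3, 0.3), sigma = c(0.05, 0.05))
  cfg <- model_config("dir", f$id, prevalence = 0.05)
  coh <- simulate_cohort(f, cfg, synth_config(n_cases = 2000,
                                              n_controls = 2000,
                                              missing_rates = c(snp = 0)),
                         seed = 7, pool_m = 2e4)
  freq <- function(id, st) mean(coh[[id]][coh$status == st]) / 2
  expect_gt(freq("s1", "case"), freq("s1", "control"))
  expect_lt(freq("s2", "case"), freq("s2", "control"))
})

test_that("the male ever-smoking odds ratio is recovered from generated cohorts", {
  f <- toy_env_factors(or = 3.0, prev = 0.5, applies_to = "males")
  cfg <- model_config("smoke", "smoke", sex_restriction = "males_only",
                      prevalence = 0.05)
  coh <- simulate_cohort(f, cfg,
                         synth_config(n_cases = 5000, n_controls = 5000,
                                      missing_rates = c(smoking = 0)),
                         seed = 37, pool_m = 2e4)
  male <- coh$sex == "male"
  tab <- table(status = coh$status[male], smoke = coh$ever_smoker[male])
  est <- contingency_or(tab["case", "1"], tab["case", "0"],
                        tab["control", "1"], tab["control", "0"])
  expect_equal(est$or, 3.0, tolerance = 0.15)
  # females carry no smoking effect in the generative model
  tabf <- table(status = coh$status[!male], smoke = coh$ever_smoker[!male])
  estf <- contingency_or(tabf["case", "1"], tabf["case", "0"],
                         tabf["control", "1"], tabf["control", "0"])
  expect_equal(estf$or, 1.0, tolerance = 0.15)
})

test_that("resolution masking follows the configured mix", {
  f <- ra_risk_factors()
  cfg <- ra_model_config("HLA", f)
  coh <- simulate_cohort(f, cfg,
                         synth_config(n_cases = 300, n_controls = 300,
                                      resolution_mix = c(four_digit = 1,
                                                         two_digit = 0,
                                                         mixed = 0)),
                         seed = 3, pool_m = 2e4)
  expect_identical(coh$hla_allele_1, coh$hla_true_1)
  expect_true(all(grepl(":", coh$hla_allele_1)))

  set.seed(101)
  two <- mask_resolution(coh, c(four_digit = 0, two_digit = 1, mixed = 0))
  expect_false(any(grepl(":", two$hla_allele_1)))
  expect_false(any(grepl(":", two$hla_allele_2)))

  mixed <- mask_resolution(coh, c(four_digit = 0, two_digit = 0, mixed = 1))
  n_four <- grepl(":", mixed$hla_allele_1) + grepl(":", mixed$hla_allele_2)
  expect_true(all(n_four == 1))
  # ground truth untouched
  expect_identical(mixed$hla_true_1, coh$hla_true_1)
})

test_that("onset ages follow the baseline Weibull when hazard ratios are 1", {
  set.seed(53)
  synth <- synth_config(hr_per_or_unit = 1, hr_smoking = 1,
                        onset_shape = 4, onset_scale = 52)
  ages <- generate_onset_ages(runif(4000, 0.1, 10), rbinom(4000, 1, 0.5),
                              synth)
  ks <- ks.test(ages, pweibull, shape = 4, scale = 52)
  expect_gt(ks$p.value, 0.01)
})

test_that("smokers have later onset when the smoking hazard ratio is below 1", {
  set.seed(59)
  synth <- synth_config(hr_per_or_unit = 1, hr_smoking = 0.848)
  smoke <- rep(0:1, each = 5000)
  ages <- generate_onset_ages(rep(1, 10^4), smoke, synth)
  expect_gte(km_curve(ages[smoke == 1])$median,
             km_curve(ages[smoke == 0])$median)
})

test_that("missingness injection realises the configured MCAR rates", {
  f <- toy3()
  cfg <- toy3_config()
  coh <- simulate_cohort(f, cfg,
                         synth_config(n_cases = 5000, n_controls = 5000,
                                      missing_rates = c(snp = 0,
                                                        smoking = 0,
                                                        onset = 0)),
                         seed = 61, pool_m = 2e4)
  expect_false(anyNA(coh$s1))
  expect_false(anyNA(coh$ever_smoker))

  set.seed(67)
  all_gone <- inject_missingness(coh, c(snp = 1, smoking = 1),
                                 snp_ids = c("s1", "s2", "s3"))
  expect_true(all(is.na(all_gone$s1)))
  expect_true(all(is.na(all_gone$ever_smoker)))

  some <- inject_missingness(coh, c(snp = 0.2), snp_ids = "s1")
  rate <- mean(is.na(some$s1))
  expect_equal(rate, 0.2, tolerance = 3 * sqrt(0.2 * 0.8 / 10^4) / 0.2)
})

test_that("multivariable logistic recovery targets the generating log ORs", {
  f <- toy_snp_factors(c(1.8, 0.6, 1.3), c(0.25, 0.4, 0.15),
                       sigma = c(0.05, 0.05, 0.05))
  cfg <- model_config("rec", f$id, prevalence = 0.05)
  coh <- simulate_cohort(f, cfg, synth_config(n_cases = 4000,
                                              n_controls = 4000),
                         seed = 73, pool_m = 2e4)
  rec <- recover_parameters(coh, f, cfg)
  expect_true(all(rec$estimable))
  expect_equal(rec$estimate, rec$truth, tolerance = 0.15)
  # each 95% CI covers marginally; demand no gross miss
  expect_gte(mean(rec$covered), 2 / 3)
})

test_that("scoring a cohort generated under the model discriminates cases from controls", {
  f <- toy_snp_factors(c(3, 2), c(0.3, 0.2), sigma = c(0.05, 0.05))
  cfg <- model_config("auc", f$id, prevalence = 0.05)
  coh <- simulate_cohort(f, cfg, synth_config(n_cases = 1000,
                                              n_controls = 1000,
                                              missing_rates = c(snp = 0)),
                         seed = 79, pool_m = 2e4)
  fit <- riskcat(f, cfg, method = "enumerate")
  sc <- predict(fit, coh)
  auc <- roc_auc(sc$or[coh$status == "case"],
                 sc$or[coh$status == "control"])
  expect_gt(auc$auc, 0.55)
})
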