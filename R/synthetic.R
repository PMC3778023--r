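# Synthetic case-control cohort generator with the statistical structure
# the prediction pipeline assumes: HWE SNP genotypes, a multi-allelic HLA
# locus at mixed typing resolution, sex-specific smoking exposure, disease
# status logistic in the calibrated profile log OR, onset ages from a
# Weibull proportional-hazards model, and MCAR missingness.

#' Synthetic cohort generation settings
#'
#' @param n_cases,n_controls cohort sizes to generate.
#' @param female_prop proportion of females in the source population.
#' @param smoking_prev named ever-smoking prevalence by sex.
#' @param resolution_mix fractions of individuals whose HLA typing is kept
#'   at four-digit resolution on both alleles, collapsed to two-digit on
#'   both, or mixed (one allele collapsed); must sum to 1.
#' @param missing_rates MCAR missingness: `snp` per genotype call,
#'   `smoking` per person, `onset` per case.
#' @param acpa_pos_prop fraction of cases labelled ACPA-positive.
#' @param onset_shape,onset_scale baseline Weibull shape/scale for onset
#'   age (years).
#' @param hr_per_or_unit onset hazard ratio per unit of the HLA-model
#'   summary OR score (default 1.026: higher genetic risk, earlier onset).
#' @param hr_smoking onset hazard ratio for ever-smokers (default 0.848:
#'   smokers develop disease later).
#' @return object of class `"synth_config"`.
#' @export
synth_config <- function(n_cases = 1516, n_controls = 1647,
                         female_prop = 0.5,
                         smoking_prev = c(male = 0.57, female = 0.50),
                         resolution_mix = c(four_digit = 0.78,
                                            two_digit = 0.06, mixed = 0.16),
                         missing_rates = c(snp = 0.005, smoking = 0.15,
                                           onset = 0.04),
                         acpa_pos_prop = 0.85,
                         onset_shape = 4, onset_scale = 52,
                         hr_per_or_unit = 1.026, hr_smoking = 0.848) {
  stopifnot(n_cases >= 1, n_controls >= 0,
            female_prop >= 0, female_prop <= 1,
            all(smoking_prev >= 0), all(smoking_prev <= 1),
            all(resolution_mix >= 0),
            abs(sum(resolution_mix) - 1) < 1e-8,
            all(missing_rates >= 0), all(missing_rates <= 1),
            acpa_pos_prop >= 0, acpa_pos_prop <= 1,
            onset_shape > 0, onset_scale > 0,
            hr_per_or_unit > 0, hr_smoking > 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Disease-model intercept matching a target prevalence
#'
#' Finds the baseline log odds `alpha` such that the mean disease
#' probability `mean(plogis(alpha + log_or))` over a population of
#' calibrated profile log ORs equals the target prevalence (to within
#' 1e-4 of prevalence units).
#'
#' @param log_or calibrated profile log ORs of a simulated population.
#' @param prevalence target disease prevalence in (0, 1).
#' @return scalar intercept on the log-odds scale.
#' @export
solve_intercept <- function(log_or, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1, length(log_or) >= 1)
  f <- function(a) mean(stats::plogis(a + log_or)) - prevalence
  lo <- stats::qlogis(prevalence) - max(log_or) - 1
  hi <- stats::qlogis(prevalence) - min(log_or) + 1
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-10)
  if (abs(f(r$root)) > 1e-4)
    stop("intercept search did not reach the target prevalence",
         call. = FALSE)
  r$root
}

# Genetic + exposure machinery shared by the generator: calibration shifts
# for the full model and the HLA-only submodel, estimated on a pilot pool.
synth_engine <- function(cf, config, synth, pool_m = 1e5) {
  gen <- cf[cf$kind != "environmental", , drop = FALSE]
  env <- cf[cf$kind == "environmental", , drop = FALSE]
  if (nrow(env) > 1)
    stop("the generator supports one environmental factor", call. = FALSE)
  hla_dist <- hla_allele_distribution(gen)
  beta_gen <- log(gen$or)
  beta_env <- if (nrow(env)) log(env$or) else 0
  hla_cols <- which(gen$kind == "hla_allele")

  draw <- function(n) {
    prof <- sample_profiles(n, gen, hla_dist)
    sex <- ifelse(stats::runif(n) < synth$female_prop, "female", "male")
    smoke <- stats::rbinom(n, 1L,
                           unname(synth$smoking_prev[sex]))
    lor_gen <- drop(prof$dosage %*% beta_gen)
    lor_env <- if (nrow(env)) {
      applies <- switch(env$applies_to[1],
                        all = rep(TRUE, n), males = sex == "male",
                        females = sex == "female")
      smoke * applies * beta_env
    } else 0
    lor_hla <- if (length(hla_cols))
      drop(prof$dosage[, hla_cols, drop = FALSE] %*% beta_gen[hla_cols])
    else rep(0, n)
    list(dosage = prof$dosage, hla_codes = prof$hla_codes, sex = sex,
         smoke = smoke, lor = lor_gen + lor_env, lor_hla = lor_hla)
  }
  pilot <- draw(pool_m)
  shift <- calibrate(pilot$lor)
  shift_hla <- calibrate(pilot$lor_hla)
  alpha <- solve_intercept(pilot$lor - shift, config$prevalence)
  list(draw = draw, shift = shift, shift_hla = shift_hla, alpha = alpha,
       gen = gen, env = env)
}

#' Generate a synthetic case-control cohort
#'
#' Draws risk profiles from the registered factor frequencies, assigns
#' disease status as `Bernoulli(plogis(alpha + calibrated log OR))` with
#' the intercept solved to match the configuration's prevalence, and
#' rejection-samples until the requested numbers of cases and controls are
#' collected. Cases receive serostatus labels and Weibull
#' proportional-hazards onset ages whose hazard increases with the
#' HLA-model OR score and decreases with ever-smoking. HLA typing
#' resolution is then degraded per `resolution_mix` and MCAR missingness
#' injected.
#'
#' Ground truth is retained for validation: columns `hla_true_1`,
#' `hla_true_2` keep the four-digit alleles, and
#' `attr(cohort, "truth")` holds the complete dosage matrix, calibrated
#' log ORs, HLA OR scores, the calibration shifts and the intercept.
#'
#' @param factors a `risk_factors` registry (the generative ground truth).
#' @param config a [model_config()]; its factors and prevalence define the
#'   disease model.
#' @param synth a [synth_config()].
#' @param seed optional integer seed (full determinism).
#' @param pool_m pilot-pool size for calibration and intercept solving.
#' @param batch,max_batches rejection-sampling batch size and attempt cap.
#' @return a cohort data.frame (layout in [eligibility()]) of
#'   `n_cases + n_controls` rows, class `"synth_cohort"`.
#' @export
simulate_cohort <- function(factors, config, synth = synth_config(),
                            seed = NULL, pool_m = 1e5, batch = 5e4,
                            max_batches = 1000) {
  if (!is.null(seed)) set.seed(seed)
  cf <- config_factors(factors, config)
  eng <- synth_engine(cf, config, synth, pool_m)

  need_ca <- synth$n_cases
  need_co <- synth$n_controls
  keep <- list()
  tries <- 0
  while ((need_ca > 0 || need_co > 0) && tries < max_batches) {
    tries <- tries + 1
    b <- eng$draw(batch)
    p <- stats::plogis(eng$alpha + b$lor - eng$shift)
    y <- stats::rbinom(batch, 1L, p)
    take_ca <- which(y == 1)[seq_len(min(need_ca, sum(y == 1)))]
    take_co <- which(y == 0)[seq_len(min(need_co, sum(y == 0)))]
    take <- c(take_ca, take_co)
    if (length(take))
      keep[[length(keep) + 1]] <- list(
        dosage = b$dosage[take, , drop = FALSE],
        hla_codes = if (is.null(b$hla_codes)) NULL else
          b$hla_codes[take, , drop = FALSE],
        sex = b$sex[take], smoke = b$smoke[take],
        lor = b$lor[take], lor_hla = b$lor_hla[take],
        status = ifelse(seq_along(take) <= length(take_ca),
                        "case", "control"))
    need_ca <- need_ca - length(take_ca)
    need_co <- need_co - length(take_co)
  }
  if (need_ca > 0 || need_co > 0)
    stop("could not reach requested cohort size in ", max_batches,
         " batches; raise max_batches or the prevalence", call. = FALSE)

  D <- do.call(rbind, lapply(keep, `[[`, "dosage"))
  codes <- if (is.null(keep[[1]]$hla_codes)) NULL else
    do.call(rbind, lapply(keep, `[[`, "hla_codes"))
  sex <- unlist(lapply(keep, `[[`, "sex"))
  smoke <- unlist(lapply(keep, `[[`, "smoke"))
  status <- unlist(lapply(keep, `[[`, "status"))
  lor <- unlist(lapply(keep, `[[`, "lor")) - eng$shift
  or_hla <- exp(unlist(lapply(keep, `[[`, "lor_hla")) - eng$shift_hla)
  n <- length(status)

  cohort <- data.frame(id = sprintf("S%05d", seq_len(n)), sex = sex,
                       status = status, stringsAsFactors = FALSE)
  cohort$serostatus <- ifelse(
    status == "case",
    ifelse(stats::runif(n) < synth$acpa_pos_prop, "acpa_pos", "seropos"),
    NA_character_)
  if (!is.null(codes)) {
    cohort$hla_allele_1 <- codes[, 1]
    cohort$hla_allele_2 <- codes[, 2]
    cohort$hla_true_1 <- codes[, 1]
    cohort$hla_true_2 <- codes[, 2]
  }
  for (id in eng$gen$id[eng$gen$kind == "snp"]) cohort[[id]] <- D[, id]
  cohort$ever_smoker <- smoke
  cohort$onset_age <- NA_real_
  is_ca <- status == "case"
  cohort$onset_age[is_ca] <- generate_onset_ages(or_hla[is_ca],
                                                 smoke[is_ca], synth)

  cohort <- mask_resolution(cohort, synth$resolution_mix)
  cohort <- inject_missingness(cohort, synth$missing_rates,
                               snp_ids = eng$gen$id[eng$gen$kind == "snp"])
  attr(cohort, "truth") <- list(dosage = D, ever_smoker = smoke,
                                log_or = lor, or_hla = or_hla,
                                shift = eng$shift,
                                shift_hla = eng$shift_hla,
                                alpha = eng$alpha)
  class(cohort) <- c("synth_cohort", "data.frame")
  cohort
}

#' Degrade HLA typing resolution
#'
#' Collapses four-digit allele codes to their two-digit groups per the
#' resolution mix: a person is typed four-digit on both alleles, two-digit
#' on both, or mixed (exactly one allele collapsed, chosen at random).
#'
#' @param cohort cohort with `hla_allele_1` / `hla_allele_2` columns.
#' @param resolution_mix named fractions summing to 1 (see
#'   [synth_config()]).
#' @return the cohort with collapsed allele codes.
#' @export
mask_resolution <- function(cohort, resolution_mix = c(four_digit = 0.78,
                                                       two_digit = 0.06,
                                                       mixed = 0.16)) {
  if (is.null(cohort$hla_allele_1)) return(cohort)
  n <- nrow(cohort)
  mode <- sample(names(resolution_mix), n, replace = TRUE,
                 prob = resolution_mix)
  two <- mode == "two_digit"
  cohort$hla_allele_1[two] <- allele_group(cohort$hla_allele_1[two])
  cohort$hla_allele_2[two] <- allele_group(cohort$hla_allele_2[two])
  mix <- which(mode == "mixed")
  slot <- sample(c(1L, 2L), length(mix), replace = TRUE)
  a1 <- mix[slot == 1L]
  a2 <- mix[slot == 2L]
  cohort$hla_allele_1[a1] <- allele_group(cohort$hla_allele_1[a1])
  cohort$hla_allele_2[a2] <- allele_group(cohort$hla_allele_2[a2])
  cohort
}

#' Draw onset ages under a Weibull proportional-hazards model
#'
#' Each case's hazard is the baseline Weibull hazard multiplied by
#' `hr_per_or_unit^or_score * hr_smoking^ever_smoker`, so onset age is
#' `scale * (-log(U) / h)^(1/shape)`. With both hazard ratios at 1 the
#' ages are i.i.d. baseline Weibull.
#'
#' @param or_score HLA-model summary OR score per case.
#' @param ever_smoker 0/1 per case.
#' @param synth a [synth_config()] (shape, scale and hazard ratios).
#' @return onset ages in years.
#' @export
generate_onset_ages <- function(or_score, ever_smoker,
                                synth = synth_config()) {
  stopifnot(length(or_score) == length(ever_smoker))
  h <- synth$hr_per_or_unit^or_score * synth$hr_smoking^ever_smoker
  u <- stats::runif(length(or_score))
  synth$onset_scale * (-log(u) / h)^(1 / synth$onset_shape)
}

#' Inject missing-completely-at-random data
#'
#' Masks SNP genotype calls, smoking status and onset ages at the
#' configured per-field rates, emulating the missingness patterns of real
#' cohort tables (ground-truth columns are untouched).
#'
#' @param cohort cohort data.frame.
#' @param missing_rates named rates (`snp`, `smoking`, `onset`).
#' @param snp_ids SNP column names to mask; default: columns starting
#'   `"rs"`.
#' @return the cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort,
                               missing_rates = c(snp = 0.005,
                                                 smoking = 0.15,
                                                 onset = 0.04),
                               snp_ids = grep("^rs", names(cohort),
                                              value = TRUE)) {
  n <- nrow(cohort)
  r <- function(nm) if (nm %in% names(missing_rates))
    unname(missing_rates[nm]) else 0
  if (length(snp_ids) && r("snp") > 0)
    for (id in snp_ids)
      cohort[[id]][stats::runif(n) < r("snp")] <- NA
  if (!is.null(cohort$ever_smoker) && r("smoking") > 0)
    cohort$ever_smoker[stats::runif(n) < r("smoking")] <- NA
  if (!is.null(cohort$onset_age) && r("onset") > 0) {
    mask <- stats::runif(n) < r("onset") & !is.na(cohort$onset_age)
    cohort$onset_age[mask] <- NA
  }
  cohort
}

#' Simulate a cohort from a fitted model's ground truth
#'
#' Convenience wrapper: [simulate_cohort()] with the fitted model's factor
#' registry and configuration as the generative truth.
#'
#' @param object a fitted [riskcat()] model.
#' @param nsim number of cohorts.
#' @param seed optional seed.
#' @param synth a [synth_config()].
#' @param ... passed to [simulate_cohort()].
#' @return a cohort (`nsim = 1`) or list of cohorts.
#' @export
simulate.riskcat <- function(object, nsim = 1, seed = NULL,
                             synth = synth_config(), ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i)
    simulate_cohort(object$factors, object$config, synth, seed = NULL, ...))
  if (nsim == 1) out[[1]] else out
}

#' Per-factor parameter recovery by multivariable logistic regression
#'
#' Regresses case status on the complete ground-truth dosage matrix of a
#' synthetic cohort (one joint logistic model, which targets the generative
#' conditional log ORs) and reports each factor's estimate, Wald CI and
#' whether it covers the generating value. Factors whose dosage never
#' varies in the realised cohort are flagged inestimable.
#'
#' @param cohort a [simulate_cohort()] output (needs its `"truth"`
#'   attribute).
#' @param factors,config the registry/config the cohort was generated from.
#' @param level CI level.
#' @return data.frame with columns `id`, `truth`, `estimate`, `ci_low`,
#'   `ci_high`, `covered`, `estimable`.
#' @export
recover_parameters <- function(cohort, factors, config, level = 0.95) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) stop("cohort lacks a ground-truth attribute",
                           call. = FALSE)
  cf <- config_factors(factors, config)
  D <- truth$dosage
  env <- cf$id[cf$kind == "environmental"]
  if (length(env)) {
    # exposure indicator restricted to the applicable sex
    applies <- switch(cf$applies_to[match(env, cf$id)],
                      all = rep(TRUE, nrow(cohort)),
                      males = cohort$sex == "male",
                      females = cohort$sex == "female")
    D <- cbind(D, matrix(truth$ever_smoker * applies, ncol = 1,
                         dimnames = list(NULL, env)))
  }
  D <- D[, cf$id, drop = FALSE]
  y <- as.integer(cohort$status == "case")
  varying <- apply(D, 2, function(v) stats::var(v) > 0)
  fit <- stats::glm.fit(cbind(1, D[, varying, drop = FALSE]), y,
                        family = stats::binomial())
  est <- fit$coefficients[-1]
  # Wald SEs from the unscaled covariance of the IRLS fit
  w <- fit$weights
  X <- cbind(1, D[, varying, drop = FALSE])
  XtWX <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(XtWX)))[-1]
  z <- stats::qnorm((1 + level) / 2)

  out <- data.frame(id = cf$id, truth = log(cf$or), estimate = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    covered = NA, estimable = varying,
                    stringsAsFactors = FALSE)
  out$estimate[varying] <- est
  out$ci_low[varying] <- est - z * se
  out$ci_high[varying] <- est + z * se
  out$covered[varying] <- out$ci_low[varying] <= out$truth[varying] &
    out$truth[varying] <= out$ci_high[varying]
  rownames(out) <- NULL
  out
}
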