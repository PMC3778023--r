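# Stage 2: score individual-level records against a fitted model.
#
# A cohort table has one row per person and columns:
#   id, sex ("male"/"female"/NA), status ("case"/"control"), serostatus,
#   hla_allele_1, hla_allele_2 (any notation accepted by normalise_allele(),
#   NA when untyped), ever_smoker (0/1/NA), onset_age (cases, years),
#   plus one column per SNP named by its factor id holding risk-allele
#   dosages 0/1/2 (NA when missing).

#' Model eligibility of cohort records
#'
#' Only individuals with data on every risk factor a model contains are
#' scored. A record is ineligible when (in order): the model is restricted
#' to males and the record is female or of unknown sex; the model includes
#' ever-smoking and smoking status is missing; the model includes SNPs and
#' any modelled SNP dosage is missing; the model includes HLA and both
#' allele slots are untyped. The first failing rule is reported.
#'
#' @param cohort cohort data.frame (see file header for the layout).
#' @param config a [model_config()].
#' @param factors the `risk_factors` registry the config draws from.
#' @return data.frame with logical `eligible` and character `reason`
#'   (`NA` when eligible; otherwise `"sex_restriction"`,
#'   `"missing_smoking"`, `"missing_snp"` or `"missing_hla"`).
#' @export
eligibility <- function(cohort, config, factors) {
  cf <- config_factors(factors, config)
  n <- nrow(cohort)
  reason <- rep(NA_character_, n)

  if (config$sex_restriction == "males_only") {
    sex <- as.character(cohort$sex)
    bad <- is.na(sex) | sex != "male"
    reason[bad] <- "sex_restriction"
  }
  if (any(cf$kind == "environmental")) {
    smoke <- if (!is.null(cohort$ever_smoker)) cohort$ever_smoker
             else rep(NA, n)
    bad <- is.na(reason) & is.na(smoke)
    reason[bad] <- "missing_smoking"
  }
  snp_ids <- cf$id[cf$kind == "snp"]
  if (length(snp_ids)) {
    present <- intersect(snp_ids, names(cohort))
    if (length(present) < length(snp_ids)) {
      reason[is.na(reason)] <- "missing_snp"
    } else {
      G <- as.matrix(cohort[, present, drop = FALSE])
      bad <- is.na(reason) & rowSums(is.na(G)) > 0
      reason[bad] <- "missing_snp"
    }
  }
  if (any(cf$kind == "hla_allele")) {
    a1 <- if (!is.null(cohort$hla_allele_1)) cohort$hla_allele_1 else
      rep(NA, n)
    a2 <- if (!is.null(cohort$hla_allele_2)) cohort$hla_allele_2 else
      rep(NA, n)
    bad <- is.na(reason) & is.na(a1) & is.na(a2)
    reason[bad] <- "missing_hla"
  }
  data.frame(eligible = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

# Dosage matrix of a cohort over a model's factors: SNP columns copied,
# HLA alleles resolved at their highest known resolution, sex-applicable
# exposures as 0/1. NAs are zeroed (eligibility gates their use).
cohort_dosages <- function(cohort, cf) {
  n <- nrow(cohort)
  D <- matrix(0, n, nrow(cf), dimnames = list(NULL, cf$id))
  for (id in cf$id[cf$kind == "snp"])
    if (!is.null(cohort[[id]])) {
      v <- cohort[[id]]
      v[is.na(v)] <- 0
      D[, id] <- v
    }
  if (any(cf$kind == "hla_allele")) {
    a1 <- normalise_allele(if (is.null(cohort$hla_allele_1)) rep(NA, n)
                           else cohort$hla_allele_1)
    a2 <- normalise_allele(if (is.null(cohort$hla_allele_2)) rep(NA, n)
                           else cohort$hla_allele_2)
    for (a in list(a1, a2)) {
      fid <- match_allele_factor(a, cf)
      j <- match(fid, cf$id)
      ok <- which(!is.na(j))
      idx <- cbind(ok, j[ok])
      D[idx] <- D[idx] + 1
    }
  }
  for (i in which(cf$kind == "environmental")) {
    v <- if (!is.null(cohort$ever_smoker)) cohort$ever_smoker else rep(NA, n)
    v[is.na(v)] <- 0
    applies <- switch(cf$applies_to[i],
                      all = rep(TRUE, n),
                      males = !is.na(cohort$sex) & cohort$sex == "male",
                      females = !is.na(cohort$sex) & cohort$sex == "female")
    D[, cf$id[i]] <- v * applies
  }
  D
}

#' Score individuals with a fitted risk categorisation model
#'
#' Computes each eligible record's summary OR (the product of its carried
#' factor ORs, calibrated by the population shift so the population-average
#' profile scores OR 1), its CI, its risk category against the frozen
#' boundaries, and its lifetime risk.
#'
#' Records typed at a single HLA allele are scored on the known allele and
#' flagged in `note`. Ineligible records are returned with `NA` risk fields
#' and the failing eligibility rule, unless `strict = TRUE`.
#'
#' @param object a fitted [riskcat()] model.
#' @param newdata cohort data.frame (layout in [eligibility()]).
#' @param strict error on the first ineligible record instead of returning
#'   it unscored.
#' @param ... unused.
#' @return data.frame with columns `id`, `or`, `ci_low`, `ci_high`,
#'   `category`, `lifetime_risk_pct`, `eligible`, `reason`, `note`.
#' @export
predict.riskcat <- function(object, newdata, strict = FALSE, ...) {
  cf <- object$factors
  n <- nrow(newdata)
  el <- eligibility(newdata, object$config, cf)
  if (strict && any(!el$eligible)) {
    i <- which(!el$eligible)[1]
    stop("ineligible record ", newdata$id[i], ": ", el$reason[i],
         call. = FALSE)
  }
  D <- cohort_dosages(newdata, cf)
  lor <- drop(D %*% object$beta) - object$calibration_shift
  v <- drop(D^2 %*% object$sigma2)
  ci <- odds_ratio_ci(lor, v, object$config$level)
  category <- categorise(ci, object$categoriser)

  sex <- if (!is.null(newdata$sex)) as.character(newdata$sex)
         else rep(NA_character_, n)
  ltr <- lifetime_risk(ci$or, sex)

  note <- rep(NA_character_, n)
  if (any(cf$kind == "hla_allele") &&
      !is.null(newdata$hla_allele_1) && !is.null(newdata$hla_allele_2)) {
    single <- xor(is.na(newdata$hla_allele_1), is.na(newdata$hla_allele_2))
    note[el$eligible & single] <- "single_hla_allele"
  }
  out <- data.frame(
    id = if (!is.null(newdata$id)) newdata$id else seq_len(n),
    or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
    category = category, lifetime_risk_pct = ltr,
    eligible = el$eligible, reason = el$reason, note = note,
    stringsAsFactors = FALSE)
  nas <- !el$eligible
  out[nas, c("or", "ci_low", "ci_high", "lifetime_risk_pct")] <- NA_real_
  out$category[nas] <- NA
  rownames(out) <- NULL
  out
}

#' Lifetime disease risk from a summary odds ratio
#'
#' In the low-prevalence regime odds ratios approximate relative risks, so
#' the lifetime risk is the published sex-specific baseline lifetime risk
#' multiplied by the summary OR: 2.4% for women and 1.1% for men, capped at
#' 100%. Unknown sex gives `NA` (not zero).
#'
#' @param or summary odds ratio(s).
#' @param sex `"male"` / `"female"` (vectorised, recycled).
#' @param baseline_pct named baseline lifetime risks in percent.
#' @return lifetime risk in percent.
#' @examples
#' lifetime_risk(20, c("female", "male"))   # 48% and 22%
#' @export
lifetime_risk <- function(or, sex,
                          baseline_pct = c(female = 2.4, male = 1.1)) {
  if (any(or < 0, na.rm = TRUE)) stop("or must be positive", call. = FALSE)
  base <- unname(baseline_pct[as.character(sex)])
  pmin(or * base, 100)
}
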