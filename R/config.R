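#' Define a prediction-model configuration
#'
#' A configuration names the subset of registered risk factors entering one
#' prediction model, together with the disease prevalence used downstream
#' for absolute-risk calibration and the CI level used for categorisation.
#' Configurations containing an environmental factor restricted to one sex
#' must carry the matching sex restriction (ever-smoking models are
#' evaluated in males only).
#'
#' @param name model label, e.g. `"HLA_smoking"`.
#' @param factor_ids character vector of factor ids (must exist in the
#'   registry the model is fitted against).
#' @param sex_restriction `"none"` or `"males_only"`.
#' @param prevalence disease prevalence in (0, 1) used for lifetime-risk and
#'   synthetic-cohort calibration. Default 0.008 (UK seropositive RA scale).
#' @param level CI level for risk categorisation (default 0.95).
#' @return an object of class `"model_config"`.
#' @export
model_config <- function(name, factor_ids,
                         sex_restriction = c("none", "males_only"),
                         prevalence = 0.008, level = 0.95) {
  sex_restriction <- match.arg(sex_restriction)
  stopifnot(is.character(factor_ids), length(factor_ids) >= 1,
            prevalence > 0, prevalence < 1, level > 0, level < 1)
  structure(list(name = name, factor_ids = unique(factor_ids),
                 sex_restriction = sex_restriction,
                 prevalence = prevalence, level = level),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("Model configuration:", x$name, "\n")
  cat("  factors:         ", length(x$factor_ids), "\n")
  cat("  sex restriction: ", x$sex_restriction, "\n")
  cat("  prevalence:      ", x$prevalence, "\n")
  cat("  CI level:        ", x$level, "\n")
  invisible(x)
}

#' Standard rheumatoid-arthritis model configurations
#'
#' The five model configurations evaluated in the package examples, built
#' from the bundled risk-factor table: `SNP` (31 SNPs), `HLA` (10 two-digit
#' + 15 four-digit HLA-DRB1 alleles), `HLA_SNP`, `HLA_smoking` and
#' `HLA_SNP_smoking` (HLA + the 28 SNPs genotyped in both evaluation
#' cohorts + ever-smoking). Smoking-containing models are restricted to
#' males. SNP availability follows the named cohort's genotyping platform.
#'
#' @param name one of `"SNP"`, `"HLA"`, `"HLA_SNP"`, `"HLA_smoking"`,
#'   `"HLA_SNP_smoking"`.
#' @param factors a `risk_factors` registry; default the bundled table.
#' @param cohort `"WTCCC"` or `"UKRAGG"`: which cohort's SNP availability to
#'   mirror for the SNP-containing models.
#' @param prevalence,level passed to [model_config()].
#' @return a `model_config`.
#' @examples
#' ra_model_config("HLA")
#' @export
ra_model_config <- function(name = c("SNP", "HLA", "HLA_SNP", "HLA_smoking",
                                     "HLA_SNP_smoking"),
                            factors = ra_risk_factors(),
                            cohort = c("WTCCC", "UKRAGG"),
                            prevalence = 0.008, level = 0.95) {
  name <- match.arg(name)
  cohort <- match.arg(cohort)
  avail <- if (cohort == "WTCCC") factors$in_wtccc else factors$in_ukragg
  if (is.null(avail)) avail <- rep(TRUE, nrow(factors))
  hla <- factors$id[factors$kind == "hla_allele"]
  snps <- factors$id[factors$kind == "snp" & avail]
  snps_both <- factors$id[factors$kind == "snp" &
                            factors$in_wtccc & factors$in_ukragg]
  smoke <- factors$id[factors$kind == "environmental"]
  ids <- switch(name,
    SNP = snps,
    HLA = hla,
    HLA_SNP = c(hla, snps),
    HLA_smoking = c(hla, smoke),
    HLA_SNP_smoking = c(hla, snps_both, smoke))
  sexr <- if (name %in% c("HLA_smoking", "HLA_SNP_smoking")) "males_only"
          else "none"
  model_config(name, ids, sex_restriction = sexr,
               prevalence = prevalence, level = level)
}

# Subset a registry to a configuration, preserving order and validating ids.
config_factors <- function(factors, config) {
  miss <- setdiff(config$factor_ids, factors$id)
  if (length(miss))
    stop("config names unknown factors: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- factors[match(config$factor_ids, factors$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
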