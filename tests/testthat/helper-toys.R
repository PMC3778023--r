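# Toy model builders used across the suite. CIs are constructed from a
# chosen per-factor SE so that se_from_ci() recovers it exactly.

toy_snp_factors <- function(ors, freqs, sigma = rep(0.1, length(ors)),
                            ids = paste0("s", seq_along(ors))) {
  z <- qnorm(0.975)
  risk_factors(data.frame(
    id = ids, kind = "snp",
    or = ors,
    ci_low = ors * exp(-z * sigma),
    ci_high = ors * exp(z * sigma),
    control_freq = freqs,
    stringsAsFactors = FALSE))
}

# the 3-SNP toy model (ORs 1.5 / 1.3 / 1.2, control freqs 0.3 / 0.2 / 0.4)
toy3 <- function(sigma = rep(0.1, 3)) {
  toy_snp_factors(c(1.5, 1.3, 1.2), c(0.3, 0.2, 0.4), sigma)
}

toy3_config <- function(level = 0.95) {
  model_config("toy3", c("s1", "s2", "s3"), level = level)
}

# hand-specified five-profile population exercising every category rule
five_profiles <- function() {
  data.frame(or = c(0.5, 0.9, 1.0, 2.0, 5.0),
             ci_low = c(0.4, 0.7, 0.8, 1.5, 3.0),
             ci_high = c(0.6, 1.2, 1.25, 2.7, 8.3))
}

# minimal single-exposure registry (male ever-smoking style)
toy_env_factors <- function(or = 3.0, sigma = 0.12, prev = 0.5,
                            applies_to = "males") {
  z <- qnorm(0.975)
  risk_factors(data.frame(
    id = "smoke", kind = "environmental",
    or = or, ci_low = or * exp(-z * sigma), ci_high = or * exp(z * sigma),
    exposure_prev = prev, applies_to = applies_to,
    stringsAsFactors = FALSE))
}
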