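#' Combined log odds and variance of one or more risk profiles
#'
#' Under the multiplicative independence model a profile carrying dosage
#' `k_i` of factor `i` (0/1/2 allele copies, or a 0/1 exposure indicator)
#' has `log OR = sum_i k_i log(OR_i)` relative to a profile with no risk
#' factors present, with variance `sum_i k_i^2 sigma_i^2` where `sigma_i`
#' is the per-factor SE of the log OR (see [factor_se] sources in
#' [risk_factors()]).
#'
#' @param dosages named numeric vector (one profile) or matrix with one
#'   column per factor id (many profiles). Names must be registered factor
#'   ids; an empty profile returns `(0, 0)`.
#' @param factors a `risk_factors` registry.
#' @param level CI level used when deriving per-factor SEs from published
#'   CIs.
#' @return list with numeric components `log_or` and `var_log_or`.
#' @examples
#' f <- risk_factors(data.frame(id = "rsX", kind = "snp", or = 2,
#'                              ci_low = 2 * exp(-1.96 * 0.1),
#'                              ci_high = 2 * exp(1.96 * 0.1),
#'                              control_freq = 0.3))
#' profile_log_odds(c(rsX = 1), f)
#' @export
profile_log_odds <- function(dosages, factors, level = 0.95) {
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = 1,
                                               dimnames = list(NULL,
                                                               names(dosages)))
  if (ncol(dosages) == 0)
    return(list(log_or = rep(0, nrow(dosages)),
                var_log_or = rep(0, nrow(dosages))))
  ids <- colnames(dosages)
  if (is.null(ids)) stop("dosages must be named by factor id", call. = FALSE)
  idx <- match(ids, factors$id)
  if (anyNA(idx))
    stop("unknown factor id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  beta <- log(factors$or[idx])
  sig2 <- factor_se(factors[idx, , drop = FALSE], level)^2
  list(log_or = drop(dosages %*% beta),
       var_log_or = drop(dosages^2 %*% sig2))
}

#' Wald odds-ratio confidence interval on the log scale
#'
#' @param log_or log odds ratio(s).
#' @param var_log_or variance(s) of the log OR (>= 0); zero variance yields
#'   a degenerate interval equal to the point estimate.
#' @param level confidence level.
#' @return data.frame with columns `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio_ci <- function(log_or, var_log_or, level = 0.95) {
  if (any(var_log_or < 0)) stop("variance must be >= 0", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(var_log_or)
  data.frame(or = exp(log_or),
             ci_low = exp(log_or - half),
             ci_high = exp(log_or + half))
}
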