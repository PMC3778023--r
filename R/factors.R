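#' Standard-error of a log odds ratio from its published confidence interval
#'
#' Recovers the precision of a published odds ratio from its Wald confidence
#' interval: on the log scale the interval half-width is `z * se`, so
#' `se = (log(ci_high) - log(ci_low)) / (2 * z)`.
#'
#' @param ci_low,ci_high positive lower/upper CI bounds on the OR scale.
#' @param level confidence level of the published interval (default 0.95).
#' @return non-negative standard error of the log OR (vectorised).
#' @examples
#' se_from_ci(2.35, 3.88)         # male ever-smoking meta-analysis CI
#' @export
se_from_ci <- function(ci_low, ci_high, level = 0.95) {
  if (any(!is.finite(ci_low)) || any(!is.finite(ci_high)) ||
      any(ci_low <= 0) || any(ci_high <= 0))
    stop("CI bounds must be positive and finite", call. = FALSE)
  if (any(ci_high < ci_low))
    stop("ci_high must be >= ci_low", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  (log(ci_high) - log(ci_low)) / (2 * z)
}

#' Woolf standard error of a log allelic odds ratio from study sizes
#'
#' Fallback precision estimate when no CI is published: expected allele
#' counts in a case-control study of the given size are
#' `a = 2 n_ca f_ca`, `b = 2 n_ca (1 - f_ca)`, `c = 2 n_co f_co`,
#' `d = 2 n_co (1 - f_co)` and the Woolf SE is `sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' @param freq_ca,freq_co risk-allele frequency in cases/controls, strictly
#'   inside (0, 1) - a frequency of exactly 0 or 1 makes the precision
#'   incomputable and raises an error (callers fall back to [se_from_ci]).
#' @param n_ca,n_co discovery-study case/control counts (individuals).
#' @return non-negative standard error of the log OR.
#' @export
se_from_counts <- function(freq_ca, freq_co, n_ca, n_co) {
  if (any(n_ca < 1) || any(n_co < 1))
    stop("sample sizes must be >= 1", call. = FALSE)
  if (any(freq_ca <= 0) || any(freq_ca >= 1) ||
      any(freq_co <= 0) || any(freq_co >= 1))
    stop("allele frequencies of 0 or 1 give incomputable precision",
         call. = FALSE)
  a <- 2 * n_ca * freq_ca
  b <- 2 * n_ca * (1 - freq_ca)
  cc <- 2 * n_co * freq_co
  d <- 2 * n_co * (1 - freq_co)
  sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
}

#' Construct a validated risk-factor registry
#'
#' A risk-factor table has one row per genetic or environmental factor with
#' columns:
#' \describe{
#'   \item{id}{factor identifier; HLA alleles as `"*NN"` / `"*NN:NN"`, SNPs
#'     as rs ids, environmental exposures free-form.}
#'   \item{kind}{`"snp"`, `"hla_allele"` or `"environmental"`.}
#'   \item{resolution}{`"two_digit"`, `"four_digit"` or `"not_applicable"`.}
#'   \item{parent}{two-digit parent group of a four-digit allele (e.g. `"*04"`
#'     for `"*04:01"`); `NA` otherwise.}
#'   \item{or, ci_low, ci_high}{published per-allele (or per-exposure) OR and
#'     95% CI.}
#'   \item{control_freq}{risk-allele frequency in the unaffected population
#'     (genetic factors).}
#'   \item{n_cases, n_controls}{optional discovery-study sizes, used for the
#'     Woolf precision fallback when no CI is supplied.}
#'   \item{exposure_prev}{population exposure proportion (environmental
#'     factors).}
#'   \item{applies_to}{`"all"`, `"males"` or `"females"`.}
#' }
#'
#' @param df data.frame with the columns above (extra columns are kept).
#' @return the validated data.frame with class `"risk_factors"`.
#' @seealso [read_risk_factors()], [ra_risk_factors()]
#' @export
risk_factors <- function(df) {
  req <- c("id", "kind", "or", "ci_low", "ci_high")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("risk-factor table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("resolution", "parent"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  for (col in c("control_freq", "n_cases", "n_controls", "exposure_prev",
                "se_log_or"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  if (is.null(df$applies_to)) df$applies_to <- "all"
  df$resolution[is.na(df$resolution)] <- "not_applicable"

  if (anyDuplicated(df$id))
    stop("duplicated factor ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  if (!all(df$kind %in% c("snp", "hla_allele", "environmental")))
    stop("kind must be snp, hla_allele or environmental", call. = FALSE)
  if (!all(df$applies_to %in% c("all", "males", "females")))
    stop("applies_to must be all, males or females", call. = FALSE)
  bad <- !(df$ci_low <= df$or & df$or <= df$ci_high) |
    df$or <= 0 | df$ci_low <= 0
  if (any(bad, na.rm = TRUE))
    stop("OR outside its CI (or nonpositive) for: ",
         paste(df$id[which(bad)], collapse = ", "), call. = FALSE)

  gen <- df$kind != "environmental"
  f <- df$control_freq[gen]
  if (any(is.na(f) | f < 0 | f > 1))
    stop("genetic factors need control_freq in [0, 1]", call. = FALSE)
  four <- df$kind == "hla_allele" & df$resolution == "four_digit"
  if (any(four & is.na(df$parent)))
    stop("four-digit HLA factors must name a two-digit parent", call. = FALSE)
  orphan <- four & !(df$parent %in% df$id[df$resolution == "two_digit"])
  if (any(orphan))
    stop("four-digit alleles with unknown parent group: ",
         paste(df$id[orphan], collapse = ", "), call. = FALSE)
  env <- df$kind == "environmental"
  p <- df$exposure_prev[env]
  if (any(is.na(p) | p < 0 | p > 1))
    stop("environmental factors need exposure_prev in [0, 1]", call. = FALSE)
  both <- env & !is.na(df$se_log_or) & is.finite(df$ci_low)
  if (any(both))
    stop("supply either se_log_or or a CI for environmental factors, not both",
         call. = FALSE)

  class(df) <- c("risk_factors", "data.frame")
  df
}

#' Read a risk-factor table from a delimited file
#'
#' @param path TSV/CSV file with the columns documented in [risk_factors()].
#' @param sep field separator; default tab.
#' @return a `risk_factors` data.frame.
#' @export
read_risk_factors <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE, comment.char = "")
  risk_factors(df)
}

#' Bundled rheumatoid-arthritis risk-factor table
#'
#' The published summary statistics used throughout the package examples:
#' 10 two-digit and 15 four-digit HLA-DRB1 allele ORs with control
#' frequencies, 34 non-HLA susceptibility SNP ORs with control minor-allele
#' frequencies (meta-analysis values), and the male ever-smoking OR
#' (3.02, 95% CI 2.35-3.88). `in_wtccc` / `in_ukragg` flag genotyping
#' availability of each SNP in the two evaluation cohorts.
#'
#' @return a `risk_factors` data.frame with 60 rows.
#' @export
ra_risk_factors <- function() {
  path <- system.file("extdata", "ra_risk_factors.tsv", package = "riskcat",
                      mustWork = TRUE)
  read_risk_factors(path)
}

# Per-factor SE of the log OR: CI-derived when a CI is given (the directly
# published precision), otherwise Woolf from discovery sample sizes with the
# case frequency implied by the OR and control frequency.
factor_se <- function(factors, level = 0.95) {
  se <- factors$se_log_or
  use_ci <- is.na(se) & is.finite(factors$ci_low) & is.finite(factors$ci_high)
  se[use_ci] <- se_from_ci(factors$ci_low[use_ci], factors$ci_high[use_ci],
                           level)
  left <- which(is.na(se))
  for (i in left) {
    f_co <- factors$control_freq[i]
    n_ca <- factors$n_cases[i]
    n_co <- factors$n_controls[i]
    if (is.na(f_co) || is.na(n_ca) || is.na(n_co))
      stop("no precision source (CI, se_log_or or sizes) for factor ",
           factors$id[i], call. = FALSE)
    odds_ca <- factors$or[i] * f_co / (1 - f_co)
    f_ca <- odds_ca / (1 + odds_ca)
    se[i] <- se_from_counts(f_ca, f_co, n_ca, n_co)
  }
  se
}
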