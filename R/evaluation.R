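# Discrimination and descriptive evaluation: ROC/AUC with DeLong variance,
# paired DeLong comparison, 2x2 odds ratios, category cross-tabulations and
# ordered risk-distribution exports.

# DeLong structural components: V10[i] = P(case_i beats a random control)
# (+1/2 per tie), V01[j] symmetric. mean(V10) = mean(V01) = Mann-Whitney AUC.
delong_components <- function(cases, controls) {
  m <- length(cases)
  n <- length(controls)
  r <- rank(c(cases, controls), ties.method = "average")
  rx <- rank(cases, ties.method = "average")
  ry <- rank(controls, ties.method = "average")
  V10 <- (r[seq_len(m)] - rx) / n
  V01 <- 1 - (r[m + seq_len(n)] - ry) / m
  list(V10 = V10, V01 = V01, auc = mean(V10))
}

#' ROC area under the curve with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen case
#' outscores a randomly chosen control (ties counting one half), with
#' variance from DeLong's structural components and a Wald CI truncated to
#' `[0, 1]`.
#'
#' @param scores_cases,scores_controls numeric score vectors (both
#'   nonempty).
#' @param level CI level.
#' @return object of class `"roc_auc"`: list with `auc`, `ci_low`,
#'   `ci_high`, `var_auc`, `n_cases`, `n_controls`.
#' @export
roc_auc <- function(scores_cases, scores_controls, level = 0.95) {
  scores_cases <- scores_cases[!is.na(scores_cases)]
  scores_controls <- scores_controls[!is.na(scores_controls)]
  if (!length(scores_cases) || !length(scores_controls))
    stop("both score groups must be nonempty", call. = FALSE)
  dc <- delong_components(scores_cases, scores_controls)
  v <- stats::var(dc$V10) / length(dc$V10) +
    stats::var(dc$V01) / length(dc$V01)
  if (is.na(v)) v <- 0  # single observation in a group
  z <- stats::qnorm((1 + level) / 2)
  structure(list(auc = dc$auc,
                 ci_low = max(0, dc$auc - z * sqrt(v)),
                 ci_high = min(1, dc$auc + z * sqrt(v)),
                 var_auc = v,
                 n_cases = length(scores_cases),
                 n_controls = length(scores_controls)),
            class = "roc_auc")
}

#' @export
print.roc_auc <- function(x, digits = 3, ...) {
  cat(sprintf("AUC %.*f (95%% CI %.*f-%.*f), %d cases / %d controls\n",
              digits, x$auc, digits, x$ci_low, digits, x$ci_high,
              x$n_cases, x$n_controls))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same individuals, using
#' the covariance of their DeLong structural components to account for the
#' pairing.
#'
#' @param scores_a,scores_b paired score vectors (same individuals, same
#'   order).
#' @param is_case logical (or 0/1) disease indicator, same length.
#' @return object of class `"delong_test"`: list with `auc_a`, `auc_b`,
#'   `z`, `p` (two-sided).
#' @export
delong_test <- function(scores_a, scores_b, is_case) {
  is_case <- as.logical(is_case)
  stopifnot(length(scores_a) == length(is_case),
            length(scores_b) == length(is_case))
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(is_case)
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]
  is_case <- is_case[keep]
  if (!any(is_case) || all(is_case))
    stop("need both cases and controls", call. = FALSE)
  da <- delong_components(scores_a[is_case], scores_a[!is_case])
  db <- delong_components(scores_b[is_case], scores_b[!is_case])
  m <- sum(is_case)
  n <- sum(!is_case)
  s10 <- stats::cov(cbind(da$V10, db$V10))
  s01 <- stats::cov(cbind(da$V01, db$V01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- da$auc - db$auc
  if (vd <= 0) {
    if (abs(d) < .Machine$double.eps^0.5)
      return(structure(list(auc_a = da$auc, auc_b = db$auc, z = 0, p = 1),
                       class = "delong_test"))
    stop("degenerate DeLong variance: AUC difference is not testable",
         call. = FALSE)
  }
  z <- d / sqrt(vd)
  structure(list(auc_a = da$auc, auc_b = db$auc, z = z,
                 p = 2 * stats::pnorm(-abs(z))),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, digits = 3, ...) {
  cat(sprintf("DeLong paired AUC comparison: %.*f vs %.*f, z = %.*f, p = %s\n",
              digits, x$auc_a, digits, x$auc_b, digits, x$z,
              format.pval(x$p, digits = digits)))
  invisible(x)
}

#' 2x2 contingency-table odds ratio with Woolf confidence interval
#'
#' @param a,b,c,d cell counts: case-exposed, case-unexposed,
#'   control-exposed, control-unexposed.
#' @param level CI level.
#' @return object of class `"contingency_or"`: list with the counts, `or`,
#'   `ci_low`, `ci_high` and a `haldane` flag, set when the
#'   Haldane-Anscombe +0.5 correction was applied because a cell was zero.
#'   Two zero cells sharing a margin leave the OR undefined and raise an
#'   error.
#' @examples
#' contingency_or(231, 56, 422, 317)   # male ever-smoking, first cohort
#' @export
contingency_or <- function(a, b, c, d, level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stop("a zero margin leaves the odds ratio undefined", call. = FALSE)
  haldane <- any(cells == 0)
  x <- cells + if (haldane) 0.5 else 0
  or <- (x[["a"]] * x[["d"]]) / (x[["b"]] * x[["c"]])
  se <- sqrt(sum(1 / x))
  z <- stats::qnorm((1 + level) / 2)
  structure(list(a = a, b = b, c = c, d = d, or = unname(or),
                 ci_low = unname(or * exp(-z * se)),
                 ci_high = unname(or * exp(z * se)),
                 haldane = haldane),
            class = "contingency_or")
}

#' @export
print.contingency_or <- function(x, digits = 2, ...) {
  cat(sprintf("OR %.*f (95%% CI %.*f-%.*f)%s  [%d/%d vs %d/%d]\n",
              digits, x$or, digits, x$ci_low, digits, x$ci_high,
              if (x$haldane) " [Haldane-Anscombe corrected]" else "",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Bundled cohort ever-smoking 2x2 tables
#'
#' Case/control ever-smoking counts by cohort and sex, reconstructed from
#' the published cohort characteristics (individuals with missing smoking
#' status excluded). Feeding each row to [contingency_or()] reproduces the
#' published sex-specific smoking odds ratios.
#'
#' @return data.frame with columns `cohort`, `sex`, `case_exposed`,
#'   `case_unexposed`, `control_exposed`, `control_unexposed`.
#' @export
ra_smoking_counts <- function() {
  utils::read.table(system.file("extdata", "smoking_2x2_counts.tsv",
                                package = "riskcat", mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Risk-category proportions by stratum
#'
#' Cross-tabulates assigned risk categories against a stratum label (e.g.
#' case/control status or serostatus) as within-stratum proportions, and -
#' when the strata include `"case"` and `"control"` - reports the
#' case:control high-risk ratio and the control:case reduced-risk ratio
#' (the headline enrichment summaries). A ratio with a zero denominator is
#' reported as `NA`.
#'
#' @param category factor of risk categories (e.g. from
#'   [predict.riskcat()]).
#' @param stratum parallel vector of stratum labels.
#' @return list with `proportions` (stratum x category matrix), `counts`,
#'   `high_risk_ratio`, `reduced_risk_ratio`.
#' @export
category_crosstab <- function(category, stratum) {
  keep <- !is.na(category) & !is.na(stratum)
  category <- factor(category[keep],
                     levels = c("reduced", "average", "elevated", "high"))
  stratum <- stratum[keep]
  if (!length(category)) stop("no classified records", call. = FALSE)
  counts <- table(stratum = stratum, category = category)
  props <- prop.table(counts, margin = 1)
  ratio <- function(num, den) if (is.na(den) || den == 0) NA_real_
                              else num / den
  hr <- rr <- NA_real_
  if (all(c("case", "control") %in% rownames(props))) {
    hr <- ratio(props["case", "high"], props["control", "high"])
    rr <- ratio(props["control", "reduced"], props["case", "reduced"])
  }
  list(proportions = props, counts = counts,
       high_risk_ratio = hr, reduced_risk_ratio = rr)
}

#' Ordered risk-distribution export
#'
#' Individuals ordered by risk within each stratum (ascending log OR, ties
#' broken by id), the table behind "log OR by rank" risk-distribution
#' plots.
#'
#' @param risks data.frame with columns `id` and `or` (e.g.
#'   [predict.riskcat()] output).
#' @param stratum optional stratum labels (single stratum when omitted).
#' @return data.frame with columns `stratum`, `rank`, `id`, `log_or`.
#' @export
risk_distribution <- function(risks, stratum = NULL) {
  if (is.null(stratum)) stratum <- rep("all", nrow(risks))
  keep <- !is.na(risks$or) & !is.na(stratum)
  d <- data.frame(stratum = stratum[keep], id = risks$id[keep],
                  log_or = log(risks$or[keep]), stringsAsFactors = FALSE)
  d <- d[order(d$stratum, d$log_or, d$id), , drop = FALSE]
  d$rank <- stats::ave(d$log_or, d$stratum, FUN = seq_along)
  rownames(d) <- NULL
  d[, c("stratum", "rank", "id", "log_or")]
}
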