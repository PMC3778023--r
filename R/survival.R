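# Age-of-onset analysis: native Kaplan-Meier product-limit estimation and
# the log-rank test, used to stratify onset by risk category and smoking.
# (Multivariate proportional-hazards modelling is deliberately left to
# dedicated survival tooling; yora_export() emits the table it needs.)

#' Kaplan-Meier product-limit curve
#'
#' With no censoring (the case-only onset analysis) the estimator reduces
#' to the empirical distribution of event times; censoring is supported for
#' generality. The median is the smallest time at which cumulative
#' incidence reaches one half.
#'
#' @param time positive event/censoring times (years of age at onset).
#' @param event 1 = event, 0 = censored (default: all events).
#' @return object of class `"km_curve"`: list with a step-function `table`
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `surv`) and `median`
#'   (`NA` when the curve never reaches 0.5).
#' @export
km_curve <- function(time, event = rep(1L, length(time))) {
  stopifnot(length(time) >= 1, length(event) == length(time))
  keep <- !is.na(time)
  time <- time[keep]; event <- event[keep]
  if (any(time <= 0)) stop("event times must be positive", call. = FALSE)
  ut <- sort(unique(time))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  med <- ut[which(surv <= 0.5)[1]]
  structure(list(table = data.frame(time = ut, n_risk = n_risk,
                                    n_event = n_event, n_censor = n_censor,
                                    surv = surv),
                 median = if (length(med)) med else NA_real_,
                 n = length(time), n_events = sum(event == 1)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d observations, %d events, median %s\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "age (years)", ylab = "survival",
                          ...) {
  tab <- x$table
  graphics::plot(stats::stepfun(tab$time, c(1, tab$surv)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Log-rank test for equality of event-time distributions
#'
#' Standard k-sample log-rank chi-square from observed-minus-expected event
#' counts over the shared risk sets, with tied event times handled by the
#' aggregate-increment convention. Invariant to any monotone rescaling of
#' the time axis.
#'
#' @param time event/censoring times.
#' @param group group labels (>= 2 nonempty groups).
#' @param event 1 = event, 0 = censored.
#' @return object of class `"logrank_test"`: list with `chi2`, `df`, `p`,
#'   `observed` and `expected` per group.
#' @export
logrank_test <- function(time, group, event = rep(1L, length(time))) {
  keep <- !is.na(time) & !is.na(group)
  time <- time[keep]; event <- event[keep]
  group <- factor(group[keep])
  k <- nlevels(group)
  if (k < 2) stop("need at least two nonempty groups", call. = FALSE)
  ut <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  # V_jl = sum_t d(n-d)/(n-1) * (delta_jl nj/n - nj nl/n^2), the
  # hypergeometric covariance of event counts over the shared risk set
  V <- matrix(0, k, k, dimnames = list(levels(group), levels(group)))
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    nj <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    dj <- vapply(levels(group), function(g)
      sum(at_risk & group == g & event == 1 & time == t), numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1)
      V <- V + d * (n - d) / (n - 1) *
        (diag(nj / n, k) - outer(nj / n, nj / n))
  }
  U <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  # pseudo-inverse quadratic form; a singular variance (e.g. all events
  # tied at a single time) contributes no evidence
  s <- svd(Vk)
  pos <- s$d > max(s$d[1], .Machine$double.eps) * 1e-10
  chi2 <- if (!any(pos)) 0 else
    drop(crossprod(crossprod(s$u[, pos, drop = FALSE], U) / sqrt(s$d[pos])))
  if (!is.finite(chi2)) chi2 <- 0
  df <- k - 1
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, digits = 3, ...) {
  cat(sprintf("Log-rank chi-square = %.*f on %d df, p = %s\n", digits,
              x$chi2, x$df, format.pval(x$p, digits = digits)))
  invisible(x)
}

#' Difference in median onset age between two strata
#'
#' @param time onset ages.
#' @param stratum stratum labels.
#' @param from,to stratum names; the returned delta is
#'   `median(to) - median(from)` in years (positive when `to` has later
#'   onset).
#' @param event optional censoring indicator.
#' @return numeric difference of Kaplan-Meier medians.
#' @export
median_onset_delta <- function(time, stratum, from, to,
                               event = rep(1L, length(time))) {
  med <- function(g) {
    sel <- !is.na(stratum) & stratum == g
    if (!any(sel)) stop("empty stratum: ", g, call. = FALSE)
    m <- km_curve(time[sel], event[sel])$median
    if (is.na(m)) stop("median not reached in stratum ", g, call. = FALSE)
    m
  }
  med(to) - med(from)
}

#' Export a tidy onset table for proportional-hazards tooling
#'
#' One row per case with onset age, the model-derived summary OR score and
#' the covariates used in published onset modelling (sex, ever-smoking and
#' their interaction, plus an optional study label) - ready for
#' `survival::coxph()` or equivalent.
#'
#' @param cohort cohort data.frame (cases with `onset_age`).
#' @param risks matching [predict.riskcat()] output (same row order).
#' @param study optional study label.
#' @return data.frame with columns `id`, `onset_age`, `or_score`,
#'   `category`, `sex`, `ever_smoker`, `sex_smoking`, `study`.
#' @export
yora_export <- function(cohort, risks, study = NA_character_) {
  stopifnot(nrow(cohort) == nrow(risks))
  keep <- !is.na(cohort$onset_age) &
    (if (is.null(cohort$status)) TRUE else cohort$status == "case") &
    risks$eligible
  male <- as.integer(!is.na(cohort$sex[keep]) & cohort$sex[keep] == "male")
  smoke <- cohort$ever_smoker[keep]
  data.frame(id = risks$id[keep], onset_age = cohort$onset_age[keep],
             or_score = risks$or[keep], category = risks$category[keep],
             sex = cohort$sex[keep], ever_smoker = smoke,
             sex_smoking = male * ifelse(is.na(smoke), NA, smoke),
             study = study, stringsAsFactors = FALSE)
}
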