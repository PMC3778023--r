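# Frozen classification boundaries from a simulated population, and the
# four-category CI-comparison rule.

#' Freeze risk-category boundaries from a population of profile risks
#'
#' The baseline profile is the one whose calibrated OR is nearest 1.0 (ties
#' broken by smaller variance, i.e. narrower CI); its CI becomes the
#' baseline interval. Scanning profiles in ascending OR order, the first
#' whose entire CI lies strictly above the baseline CI defines the
#' first-elevated interval; profiles whose CIs lie completely above that
#' interval are high-risk. When no profile separates from baseline the
#' first-elevated interval is absent and no profile can be elevated or
#' high-risk.
#'
#' @param population data.frame with columns `or`, `ci_low`, `ci_high`
#'   (optionally `var_log_or` for tie-breaking), one row per distinct risk
#'   profile. Need not be pre-sorted.
#' @param level CI level the intervals were built at (stored as provenance).
#' @return an object of class `"categoriser"`: a list with `baseline`
#'   (named vector `low`, `high`), `baseline_or`, `first_elevated` (same
#'   shape, or `NULL`) and `level`.
#' @export
build_categoriser <- function(population, level = 0.95) {
  if (!nrow(population)) stop("empty population", call. = FALSE)
  ord <- order(population$or,
               if (!is.null(population$var_log_or)) population$var_log_or
               else population$ci_high - population$ci_low)
  pop <- population[ord, , drop = FALSE]
  dist <- abs(pop$or - 1)
  ties <- which(dist == min(dist))
  width <- if (!is.null(pop$var_log_or)) pop$var_log_or[ties]
           else pop$ci_high[ties] - pop$ci_low[ties]
  base <- ties[which.min(width)]
  baseline <- c(low = pop$ci_low[base], high = pop$ci_high[base])

  above <- which(pop$ci_low > baseline[["high"]])
  first_elevated <- if (length(above))
    c(low = pop$ci_low[above[1]], high = pop$ci_high[above[1]]) else NULL
  structure(list(baseline = baseline, baseline_or = pop$or[base],
                 first_elevated = first_elevated, level = level),
            class = "categoriser")
}

#' @export
print.categoriser <- function(x, ...) {
  cat(sprintf("Risk categoriser (%g%% CIs)\n", 100 * x$level))
  cat(sprintf("  baseline profile OR %.3f, CI (%.3f, %.3f)\n",
              x$baseline_or, x$baseline[["low"]], x$baseline[["high"]]))
  if (is.null(x$first_elevated))
    cat("  no profile separates from baseline: elevated/high unreachable\n")
  else
    cat(sprintf("  first elevated profile CI (%.3f, %.3f)\n",
                x$first_elevated[["low"]], x$first_elevated[["high"]]))
  invisible(x)
}

#' Assign risk categories by confidence-interval comparison
#'
#' A profile is reduced-risk when its CI lies entirely below the baseline
#' CI, average when the CIs overlap (a shared endpoint counts as overlap),
#' high-risk when its CI lies entirely above the first-elevated CI, and
#' elevated otherwise (entirely above baseline but not beyond the high
#' threshold).
#'
#' @param risks data.frame with columns `ci_low`, `ci_high` (e.g. the
#'   population table or [predict.riskcat()] output).
#' @param categoriser a [build_categoriser()] object.
#' @return factor with levels `reduced`, `average`, `elevated`, `high`.
#' @export
categorise <- function(risks, categoriser) {
  lo <- risks$ci_low
  hi <- risks$ci_high
  b <- categoriser$baseline
  out <- rep("average", length(lo))
  out[hi < b[["low"]]] <- "reduced"
  above <- lo > b[["high"]]
  out[above] <- "elevated"
  fe <- categoriser$first_elevated
  if (!is.null(fe)) out[above & lo > fe[["high"]]] <- "high"
  factor(out, levels = c("reduced", "average", "elevated", "high"))
}
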