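#' Fit a CI-based risk categorisation model
#'
#' Stage 1 of the two-stage prediction method: draws (or exhaustively
#' enumerates) the general-population distribution of risk profiles implied
#' by the registered factor frequencies, scores every profile under the
#' multiplicative odds-ratio model, calibrates so the population mean OR is
#' 1.0 (the baseline profile), and freezes the four-category classification
#' boundaries by confidence-interval comparison.
#'
#' @param factors a `risk_factors` registry (see [ra_risk_factors()]).
#' @param config a [model_config()] naming the factors in this model.
#' @param m number of Monte-Carlo profiles (>= 1000; default 1e5). Ignored
#'   when the profile space is exhaustively enumerated.
#' @param seed optional integer seed; stored for provenance and set before
#'   simulation so identical `(config, m, seed)` give identical fits.
#' @param method `"auto"` (enumerate when the model has <= 12 factors and
#'   <= 1e6 profile states, otherwise Monte-Carlo), `"monte-carlo"` or
#'   `"enumerate"`.
#' @param mean_type calibration mean, see [calibrate()].
#' @return an object of class `"riskcat"` with components `population`
#'   (unique calibrated profiles with weights and categories),
#'   `categoriser`, `calibration_shift`, `factors`, `config`, `beta`
#'   (per-factor log ORs), `sigma2` (their variances), and provenance
#'   (`m`, `seed`, `method`).
#' @examples
#' toy <- risk_factors(data.frame(
#'   id = c("s1", "s2", "s3"), kind = "snp",
#'   or = c(1.5, 1.3, 1.2),
#'   ci_low = c(1.35, 1.17, 1.08), ci_high = c(1.67, 1.44, 1.33),
#'   control_freq = c(0.3, 0.2, 0.4)))
#' cfg <- model_config("toy", toy$id)
#' fit <- riskcat(toy, cfg, seed = 1)
#' fit
#' @export
riskcat <- function(factors, config, m = 1e5, seed = NULL,
                    method = c("auto", "monte-carlo", "enumerate"),
                    mean_type = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  mean_type <- match.arg(mean_type)
  stopifnot(inherits(config, "model_config"))
  cf <- config_factors(factors, config)
  restricted <- cf$kind == "environmental" & cf$applies_to != "all"
  if (any(restricted) && config$sex_restriction == "none")
    stop("config includes sex-specific exposure(s) ",
         paste(cf$id[restricted], collapse = ", "),
         " but carries no sex restriction", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_population(cf, config, m = m, method = method,
                             mean_type = mean_type)
  categoriser <- build_categoriser(sim$population, config$level)
  sim$population$category <- categorise(sim$population, categoriser)

  sigma2 <- factor_se(cf, config$level)^2
  structure(list(population = sim$population, categoriser = categoriser,
                 calibration_shift = sim$shift,
                 factors = cf, config = config,
                 beta = stats::setNames(log(cf$or), cf$id),
                 sigma2 = stats::setNames(sigma2, cf$id),
                 hla_dist = sim$hla_dist,
                 m = sim$n_profiles, seed = seed, method = sim$method,
                 mean_type = mean_type),
            class = "riskcat")
}

#' @export
print.riskcat <- function(x, digits = 3, ...) {
  cat("CI-based risk categorisation model:", x$config$name, "\n")
  cat(sprintf("  %d risk factors; %s over %s profiles (%d distinct)\n",
              nrow(x$factors),
              if (x$method == "enumerate") "exhaustive enumeration"
              else "Monte-Carlo simulation",
              format(x$m, big.mark = ","), nrow(x$population)))
  cat(sprintf("  calibration shift (log OR): %.*f\n", digits,
              x$calibration_shift))
  print(x$categoriser)
  cat("  population category mass:\n")
  w <- category_mass(x)
  print(round(w, digits))
  invisible(x)
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  out <- vapply(probs, function(p) x[o][which(cw >= p)[1]], numeric(1))
  stats::setNames(out, paste0(100 * probs, "%"))
}

# Probability mass of each category in the simulated population.
category_mass <- function(object) {
  w <- tapply(object$population$weight, object$population$category, sum,
              default = 0)
  w / sum(object$population$weight)
}

#' @export
summary.riskcat <- function(object, ...) {
  structure(list(config = object$config, method = object$method,
                 m = object$m, seed = object$seed,
                 calibration_shift = object$calibration_shift,
                 categoriser = object$categoriser,
                 category_mass = category_mass(object),
                 or_quantiles = weighted_quantile(
                   object$population$or, object$population$weight,
                   c(0.025, 0.25, 0.5, 0.75, 0.975)),
                 factors = object$factors[, c("id", "kind", "or", "ci_low",
                                              "ci_high")]),
            class = "summary.riskcat")
}

#' @export
print.summary.riskcat <- function(x, digits = 3, ...) {
  cat("Model:", x$config$name, "|", x$method, "| profiles:", x$m, "\n")
  cat("Calibration shift:", round(x$calibration_shift, digits), "\n\n")
  print(x$categoriser)
  cat("\nPopulation category mass:\n")
  print(round(x$category_mass, digits))
  cat("\nPopulation OR quantiles:\n")
  print(round(x$or_quantiles, digits))
  invisible(x)
}

#' @export
coef.riskcat <- function(object, ...) object$beta

#' Plot the simulated population risk distribution
#'
#' Profiles ordered by calibrated OR against their cumulative population
#' share, coloured by risk category, with the baseline and first-elevated
#' CI bounds drawn as horizontal reference lines.
#'
#' @param x a fitted [riskcat()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.riskcat <- function(x, ...) {
  pop <- x$population
  q <- cumsum(pop$weight) / sum(pop$weight)
  cols <- c(reduced = "#2166ac", average = "grey50",
            elevated = "#f4a582", high = "#b2182b")
  graphics::plot(q, log(pop$or), type = "n",
                 xlab = "population quantile", ylab = "log odds ratio",
                 main = paste("Population risk distribution:",
                              x$config$name), ...)
  graphics::segments(q, log(pop$ci_low), q, log(pop$ci_high),
                     col = grDevices::adjustcolor(
                       cols[as.character(pop$category)], 0.3))
  graphics::points(q, log(pop$or), pch = 16, cex = 0.4,
                   col = cols[as.character(pop$category)])
  b <- x$categoriser$baseline
  graphics::abline(h = log(b), lty = 2, col = "grey30")
  if (!is.null(x$categoriser$first_elevated))
    graphics::abline(h = log(x$categoriser$first_elevated[["high"]]),
                     lty = 3, col = cols[["high"]])
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   bty = "n", cex = 0.8)
  invisible(x)
}
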