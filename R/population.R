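# Stage 1: simulate (or enumerate) the general-population distribution of
# risk profiles, calibrate so the mean-OR profile is baseline 1.0, and sort.

# Allele sampling distribution for a multi-allelic HLA locus. Modelled
# four-digit alleles are drawn at their control frequencies; each two-digit
# group additionally carries its residual mass (group frequency minus the
# modelled four-digit subtypes), represented by a synthetic unmodelled
# four-digit code that scores the two-digit OR; remaining probability is
# "other" alleles outside every modelled group, which score nothing.
hla_allele_distribution <- function(factors, tol = 1e-8) {
  hla <- factors[factors$kind == "hla_allele", , drop = FALSE]
  if (!nrow(hla)) return(NULL)
  four <- hla[hla$resolution == "four_digit", , drop = FALSE]
  two <- hla[hla$resolution == "two_digit", , drop = FALSE]

  code <- four$id
  fid <- four$id
  freq <- four$control_freq

  groups <- unique(c(two$id, allele_group(four$id)))
  total <- 0
  for (g in groups) {
    child_mass <- sum(four$control_freq[allele_group(four$id) == g])
    if (g %in% two$id) {
      gmass <- two$control_freq[two$id == g]
      resid <- gmass - child_mass
      if (resid < -tol)
        stop("four-digit allele frequencies in group ", g,
             " exceed the group frequency", call. = FALSE)
      resid <- max(resid, 0)
      if (resid > 0) {
        code <- c(code, residual_code(g, four$id))
        fid <- c(fid, g)
        freq <- c(freq, resid)
      }
    } else {
      gmass <- child_mass
    }
    total <- total + gmass
  }
  if (total > 1 + tol)
    stop("HLA allele frequencies sum to ", signif(total, 4), " > 1",
         call. = FALSE)
  other <- max(1 - total, 0)
  if (other > 0) {
    ocodes <- other_group_codes(groups)
    code <- c(code, ocodes)
    fid <- c(fid, rep(NA_character_, length(ocodes)))
    freq <- c(freq, rep(other / length(ocodes), length(ocodes)))
  }
  data.frame(code = code, factor_id = fid, freq = freq,
             stringsAsFactors = FALSE)
}

# Smallest "*NN:SS" code in group g not used by a modelled allele.
residual_code <- function(g, modelled) {
  for (s in 2:99) {
    cand <- sprintf("%s:%02d", g, s)
    if (!cand %in% modelled) return(cand)
  }
  stop("no free residual code in group ", g, call. = FALSE)
}

# Plausible allele codes for the unmodelled "other" mass: real DRB1 groups
# absent from the model.
other_group_codes <- function(modelled_groups) {
  cand <- c("*09", "*12", "*16")
  cand <- setdiff(cand, modelled_groups)
  if (!length(cand)) cand <- "*99"
  paste0(cand, ":01")
}

# Draw n profiles from the population model: SNP dosages Binomial(2, freq)
# under HWE, HLA allele pairs as two independent categorical draws,
# exposures Bernoulli(prevalence). Returns the dosage matrix over the
# configuration's factors plus the raw allele codes.
sample_profiles <- function(n, cf, hla_dist = hla_allele_distribution(cf)) {
  p <- nrow(cf)
  D <- matrix(0, n, p, dimnames = list(NULL, cf$id))
  snp <- which(cf$kind == "snp")
  for (j in snp) D[, j] <- stats::rbinom(n, 2L, cf$control_freq[j])
  env <- which(cf$kind == "environmental")
  for (j in env) D[, j] <- stats::rbinom(n, 1L, cf$exposure_prev[j])

  codes <- NULL
  if (!is.null(hla_dist)) {
    k <- nrow(hla_dist)
    d1 <- sample.int(k, n, replace = TRUE, prob = hla_dist$freq)
    d2 <- sample.int(k, n, replace = TRUE, prob = hla_dist$freq)
    codes <- cbind(hla_dist$code[d1], hla_dist$code[d2])
    for (d in list(d1, d2)) {
      j <- match(hla_dist$factor_id[d], cf$id)
      ok <- which(!is.na(j))
      idx <- cbind(ok, j[ok])
      D[idx] <- D[idx] + 1
    }
  }
  list(dosage = D, hla_codes = codes)
}

# Exhaustively enumerate the profile space with its HWE / categorical /
# Bernoulli probabilities. Only feasible for small models; riskcat() guards
# the state-space size.
enumerate_profiles <- function(cf, hla_dist = hla_allele_distribution(cf),
                               max_states = 1e6) {
  blocks <- list()
  for (j in which(cf$kind == "snp")) {
    f <- cf$control_freq[j]
    blocks[[length(blocks) + 1]] <- list(
      D = matrix(0:2, 3, 1, dimnames = list(NULL, cf$id[j])),
      w = c((1 - f)^2, 2 * f * (1 - f), f^2))
  }
  for (j in which(cf$kind == "environmental")) {
    f <- cf$exposure_prev[j]
    blocks[[length(blocks) + 1]] <- list(
      D = matrix(0:1, 2, 1, dimnames = list(NULL, cf$id[j])),
      w = c(1 - f, f))
  }
  if (!is.null(hla_dist)) {
    k <- nrow(hla_dist)
    pairs <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
    hla_ids <- cf$id[cf$kind == "hla_allele"]
    Dh <- matrix(0, nrow(pairs), length(hla_ids),
                 dimnames = list(NULL, hla_ids))
    wh <- numeric(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      wh[r] <- if (i == j) hla_dist$freq[i]^2 else
        2 * hla_dist$freq[i] * hla_dist$freq[j]
      for (d in c(i, j)) {
        fi <- hla_dist$factor_id[d]
        if (!is.na(fi)) Dh[r, fi] <- Dh[r, fi] + 1
      }
    }
    blocks[[length(blocks) + 1]] <- list(D = Dh, w = wh)
  }
  if (!length(blocks))
    return(list(dosage = matrix(numeric(0), 1, 0), weight = 1))
  out <- blocks[[1]]
  for (b in blocks[-1]) {
    n1 <- nrow(out$D); n2 <- nrow(b$D)
    if (n1 * n2 > max_states)
      stop("enumeration state space exceeds ", max_states, call. = FALSE)
    i <- rep(seq_len(n1), times = n2)
    j <- rep(seq_len(n2), each = n1)
    out <- list(D = cbind(out$D[i, , drop = FALSE], b$D[j, , drop = FALSE]),
                w = out$w[i] * b$w[j])
  }
  list(dosage = out$D[, cf$id, drop = FALSE], weight = out$w)
}

#' Calibration shift making the mean-OR profile the baseline
#'
#' Raw profile log ORs are computed relative to a profile carrying no risk
#' factors. Subtracting `log(weighted mean of exp(log OR))` re-expresses
#' every profile relative to the population mean OR, so the calibrated
#' population mean OR is exactly 1 and a mean-OR profile has baseline risk.
#' The geometric alternative (`mean_type = "geometric"`) centres the mean
#' log OR instead and is provided for sensitivity analysis.
#'
#' @param raw_log_or numeric vector of uncalibrated profile log ORs.
#' @param weight profile weights (default equal).
#' @param mean_type `"arithmetic"` (default) or `"geometric"`.
#' @return the scalar shift to subtract from every raw log OR.
#' @export
calibrate <- function(raw_log_or, weight = NULL,
                      mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (!length(raw_log_or)) stop("empty profile set", call. = FALSE)
  if (is.null(weight)) weight <- rep(1, length(raw_log_or))
  w <- weight / sum(weight)
  if (mean_type == "arithmetic") log(sum(w * exp(raw_log_or)))
  else sum(w * raw_log_or)
}

# Score, calibrate, collapse to unique profiles and sort ascending by OR.
simulate_population <- function(factors, config, m = 1e5,
                                method = c("auto", "monte-carlo", "enumerate"),
                                mean_type = "arithmetic") {
  method <- match.arg(method)
  cf <- config_factors(factors, config)
  hla_dist <- hla_allele_distribution(cf)
  n_states <- prod(c(3^sum(cf$kind == "snp"),
                     2^sum(cf$kind == "environmental"),
                     if (!is.null(hla_dist))
                       nrow(hla_dist) * (nrow(hla_dist) + 1) / 2))
  if (method == "auto")
    method <- if (nrow(cf) <= 12 && n_states <= 1e6) "enumerate"
              else "monte-carlo"

  if (method == "enumerate") {
    en <- enumerate_profiles(cf, hla_dist)
    D <- en$dosage
    w <- en$weight
  } else {
    if (m < 1000) stop("m must be >= 1000 for Monte-Carlo simulation",
                       call. = FALSE)
    D <- sample_profiles(m, cf, hla_dist)$dosage
    w <- rep(1 / m, m)
  }
  pr <- profile_log_odds(D, cf, config$level)
  shift <- calibrate(pr$log_or, w, mean_type)
  lor <- pr$log_or - shift

  # collapse duplicate profiles (identical risk and precision) so boundary
  # scanning over "the first elevated profile" is well defined
  key <- paste(pr$log_or, pr$var_log_or)
  first <- !duplicated(key)
  wsum <- rowsum(w, key, reorder = FALSE)[, 1]
  pop <- data.frame(log_or = lor[first], var_log_or = pr$var_log_or[first],
                    weight = unname(wsum))
  pop <- cbind(pop, odds_ratio_ci(pop$log_or, pop$var_log_or, config$level))
  pop <- pop[order(pop$or, pop$var_log_or), , drop = FALSE]
  rownames(pop) <- NULL
  list(population = pop, shift = shift, method = method,
       n_profiles = length(w), hla_dist = hla_dist)
}
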