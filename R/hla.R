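#' Canonicalise HLA-DRB1 allele codes
#'
#' Accepts the common notations `"0401"`, `"04:01"`, `"*04:01"`,
#' `"DRB1*04:01"`, `"HLA-DRB1*04:01"` (and the two-digit forms `"04"`,
#' `"*04"`, ...) and canonicalises to `"*NN"` / `"*NN:NN"`. `NA` passes
#' through; anything else is a parse error.
#'
#' @param x character vector of allele codes.
#' @return character vector of canonical codes.
#' @examples
#' normalise_allele(c("0401", "DRB1*04", "*13:02"))
#' @export
normalise_allele <- function(x) {
  out <- as.character(x)
  todo <- !is.na(out)
  y <- trimws(out[todo])
  y <- sub("^(HLA-)?DRB1", "", y, ignore.case = TRUE)
  y <- sub("^\\*", "", y)
  bare4 <- grepl("^[0-9]{4}$", y)
  y[bare4] <- paste0(substr(y[bare4], 1, 2), ":", substr(y[bare4], 3, 4))
  ok <- grepl("^[0-9]{2}(:[0-9]{2})?$", y)
  if (any(!ok))
    stop("malformed HLA allele code(s): ",
         paste(unique(out[todo][!ok]), collapse = ", "), call. = FALSE)
  out[todo] <- paste0("*", y)
  out
}

# "*04:01" -> "*04"; two-digit codes unchanged; NA passes through.
allele_group <- function(code) {
  ifelse(is.na(code), NA_character_, sub(":.*$", "", code))
}

is_four_digit <- function(code) {
  !is.na(code) & grepl(":", code)
}

# Map one allele slot to the factor id it scores under: a four-digit code
# matching a four-digit factor uses it; otherwise its two-digit group (or a
# two-digit code directly) matches a two-digit factor; otherwise no
# contribution. Vectorised; input must already be canonical.
match_allele_factor <- function(code, factors) {
  four_ids <- factors$id[factors$kind == "hla_allele" &
                           factors$resolution == "four_digit"]
  two_ids <- factors$id[factors$kind == "hla_allele" &
                          factors$resolution == "two_digit"]
  out <- rep(NA_character_, length(code))
  hit4 <- is_four_digit(code) & code %in% four_ids
  out[hit4] <- code[hit4]
  grp <- allele_group(code)
  hit2 <- !hit4 & !is.na(code) & grp %in% two_ids
  out[hit2] <- grp[hit2]
  out
}

#' Resolve an HLA genotype to risk-factor contributions
#'
#' Each carried allele contributes at the highest typing resolution at which
#' it is known: a four-digit code matching a modelled four-digit allele
#' contributes that factor; otherwise its two-digit group is used; alleles
#' matching neither contribute nothing (baseline). An allele matched at
#' four-digit resolution never additionally contributes its two-digit parent
#' group, so no allele slot is double counted. Homozygous carriage of a
#' modelled allele contributes it twice.
#'
#' @param allele_1,allele_2 allele codes in any notation accepted by
#'   [normalise_allele()]; `NA` for an untyped slot.
#' @param factors a `risk_factors` registry.
#' @return named integer vector of per-factor allele counts (empty when
#'   neither allele matches a modelled factor).
#' @examples
#' resolve_hla("*04:01", "*03", ra_risk_factors())
#' @export
resolve_hla <- function(allele_1, allele_2, factors) {
  a <- normalise_allele(c(allele_1, allele_2))
  hits <- match_allele_factor(a, factors)
  hits <- hits[!is.na(hits)]
  if (!length(hits)) return(stats::setNames(integer(0), character(0)))
  tab <- table(hits)
  stats::setNames(as.integer(tab), names(tab))
}
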