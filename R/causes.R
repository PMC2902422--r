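#' Default cause schemes and broad cause groups
#'
#' Verbal autopsy (VA) interpretation methods assign causes on different
#' dictionaries: the probabilistic engine works on a 27-cause list while
#' physician coders use a 60-code abridged ICD-10-style list. For
#' comparison, both are harmonized into 14 broad cause groups of public
#' health importance (HIV/AIDS, pulmonary TB, pneumonia, malaria,
#' meningitis, diarrheal diseases, measles, other acute/infectious,
#' maternity-related, preterm/perinatal, malnutrition,
#' noncommunicable/chronic, injuries, and other/unspecified), with
#' `"indeterminate"` kept as a separate pass-through category.
#'
#' `va_cause_groups()` returns the 14 group labels; `va_causes()` the
#' 27-cause engine dictionary; `va_age_groups()` the four analysis age
#' bands. All dictionaries are conventions, not hard-wired: every function
#' in the package accepts user-supplied cause lists and mapping tables.
#'
#' @return A character vector of labels.
#' @examples
#' va_cause_groups()
#' length(va_causes())
#' @export
va_cause_groups <- function() {
  c(
    "hiv_aids", "pulmonary_tb", "pneumonia", "malaria", "meningitis",
    "diarrheal", "measles", "other_infectious", "maternity_related",
    "preterm_perinatal", "malnutrition", "noncommunicable", "injuries",
    "other_unspecified"
  )
}

#' @rdname va_cause_groups
#' @export
va_causes <- function() {
  va_default_map("interva")$source_code
}

#' @rdname va_cause_groups
#' @export
va_age_groups <- function() {
  c("<4 weeks", "4 weeks-<5 years", "5-<18 years", "18+ years")
}

#' Broad-category rollup of the 14 cause groups
#'
#' Aggregates the 14 harmonized cause groups into the four major
#' mortality categories used for population-level summaries: infectious,
#' noncommunicable, injuries, and maternal/perinatal/nutrition.
#' `"indeterminate"` rolls up to itself.
#'
#' @return A tibble with columns `group` and `category`.
#' @examples
#' va_rollup_map()
#' @export
va_rollup_map <- function() {
  readr::read_csv(
    system.file("extdata", "rollup_map.csv", package = "vacompare"),
    col_types = "cc", progress = FALSE
  )
}

#' Prevalence settings for prior adjustment
#'
#' The engine's prior cause distribution can be adapted to the local
#' epidemiology of malaria and HIV/AIDS: each disease's prevalence is
#' declared `"high"` or `"low"`, and the priors of the affected causes are
#' scaled by the corresponding multiplier before renormalization. The
#' defaults (high = 1.0, low = 0.1) leave high-prevalence causes untouched
#' and down-weight low-prevalence ones tenfold.
#'
#' @param malaria,hiv `"high"` or `"low"`.
#' @param multiplier_high,multiplier_low Positive scalars applied to the
#'   priors of affected causes under the respective setting.
#' @param malaria_causes,hiv_causes Cause labels whose priors the setting
#'   affects; defaults name the corresponding causes of the default
#'   27-cause dictionary.
#' @return A list of class `va_prevalence`.
#' @examples
#' # an urban population with rare malaria but high HIV prevalence
#' va_prevalence(malaria = "low", hiv = "high")
#' @export
va_prevalence <- function(malaria = c("low", "high"),
                          hiv = c("high", "low"),
                          multiplier_high = 1.0,
                          multiplier_low = 0.1,
                          malaria_causes = "malaria",
                          hiv_causes = "hiv_aids") {
  malaria <- arg_match(malaria)
  hiv <- arg_match(hiv)
  stopifnot(multiplier_high > 0, multiplier_low > 0)
  structure(
    list(
      malaria = malaria, hiv = hiv,
      multiplier_high = multiplier_high, multiplier_low = multiplier_low,
      malaria_causes = malaria_causes, hiv_causes = hiv_causes
    ),
    class = "va_prevalence"
  )
}

#' @export
print.va_prevalence <- function(x, ...) {
  cat("<va_prevalence>\n")
  cat("  malaria:", x$malaria, " hiv:", x$hiv, "\n")
  cat(
    "  multipliers: high =", x$multiplier_high,
    ", low =", x$multiplier_low, "\n"
  )
  invisible(x)
}
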