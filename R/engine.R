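# Bayesian cause-of-death engine.
#
# Model: causes C1..Cm with prior P(Ck) (the population CSMF); binary
# indicators I1..In assumed conditionally independent given cause, with a
# fixed matrix P(Ij | Ck). A reported ("yes") indicator updates every
# cause's probability multiplicatively; "no"/"unknown" responses leave the
# posterior unchanged by default, because in VA data the absence of a
# report is not evidence of absence of the symptom.

# guard value standing in for log(0) so one zero-probability indicator
# annihilates a cause without producing NaN in matrix products
LOGZERO <- -1e9

#' Adjust a prior cause distribution for local disease prevalence
#'
#' Scales the prior probability of causes affected by the malaria and
#' HIV/AIDS prevalence settings by the corresponding multiplier, then
#' renormalizes. With all multipliers at 1 the prior is returned unchanged.
#'
#' @param prior Prior cause distribution; named numeric vector or
#'   `cause,probability` data frame (see [as_prior()]).
#' @param prevalence A [va_prevalence()] object, or `NULL` to skip
#'   adjustment.
#' @return A named numeric probability vector over the same causes.
#' @examples
#' prior <- c(malaria = 0.3, hiv_aids = 0.3, other = 0.4)
#' va_adjust_prior(prior, va_prevalence(malaria = "low", hiv = "high"))
#' @export
va_adjust_prior <- function(prior, prevalence = va_prevalence()) {
  prior <- as_prior(prior)
  if (is.null(prevalence)) {
    return(prior)
  }
  stopifnot(inherits(prevalence, "va_prevalence"))
  mult <- function(setting) {
    if (setting == "high") prevalence$multiplier_high else prevalence$multiplier_low
  }
  for (disease in c("malaria", "hiv")) {
    affected <- prevalence[[paste0(disease, "_causes")]]
    missing_labels <- setdiff(affected, names(prior))
    if (length(missing_labels) > 0) {
      abort(paste0(
        "Prevalence setting names cause(s) absent from the prior: ",
        paste(missing_labels, collapse = ", ")
      ))
    }
    prior[affected] <- prior[affected] * mult(prevalence[[disease]])
  }
  prior / sum(prior)
}

#' Likelihood of an indicator under the complement of a cause
#'
#' For the two-hypothesis form of Bayes' theorem the engine needs
#' P(I | !C), the probability of observing indicator I when the cause is
#' anything other than C. Under the prior this is the prior-weighted
#' average of P(I | C') over the remaining causes:
#' \deqn{P(I | !C_k) = \sum_{k' \ne k} P(I | C_{k'}) P(C_{k'}) / (1 - P(C_k)).}
#'
#' @inheritParams va_adjust_prior
#' @param probbase Probability base matrix (indicators x causes).
#' @param indicator,cause Labels present in `probbase`.
#' @return A probability in \[0, 1\].
#' @export
va_complement_likelihood <- function(probbase, prior, indicator, cause) {
  probbase <- validate_probbase(probbase)
  prior <- as_prior(prior)
  stopifnot(identical(sort(names(prior)), sort(colnames(probbase))))
  if (!indicator %in% rownames(probbase)) {
    abort(paste0("Unknown indicator: ", indicator))
  }
  if (!cause %in% colnames(probbase)) {
    abort(paste0("Unknown cause: ", cause))
  }
  p_c <- prior[[cause]]
  if (p_c >= 1 - 1e-12) {
    abort("P(cause) = 1: complement likelihood undefined under a degenerate prior.")
  }
  others <- setdiff(colnames(probbase), cause)
  sum(probbase[indicator, others] * prior[others]) / (1 - p_c)
}

# normalize case responses to the Y/N/. dialect
normalize_responses <- function(x) {
  x <- toupper(as.character(x))
  x[x %in% c("YES", "Y", "1", "TRUE")] <- "Y"
  x[x %in% c("NO", "N", "0", "FALSE")] <- "N"
  x[x %in% c("UNKNOWN", ".", "", "NA") | is.na(x)] <- "."
  bad <- setdiff(unique(x), c("Y", "N", "."))
  if (length(bad) > 0) {
    abort(paste0(
      "Invalid indicator response(s): ", paste(bad, collapse = ", "),
      " (expected Y/N/.)"
    ))
  }
  x
}

# log-space posterior for a cohort: cases x causes matrix of log
# unnormalized posteriors. yes/no are 0/1 incidence matrices.
log_posterior_matrix <- function(yes, no, probbase, prior, update_negative) {
  logb <- log(probbase)
  logb[probbase == 0] <- LOGZERO
  lp <- yes %*% logb
  if (update_negative) {
    log1mb <- log1p(-probbase)
    log1mb[probbase == 1] <- LOGZERO
    lp <- lp + no %*% log1mb
  }
  sweep(lp, 2, log(prior), "+")
}

#' Posterior cause distribution for a single VA case
#'
#' Starts from the prior and, for each indicator reported `"Y"`, multiplies
#' each cause's probability by P(indicator | cause), renormalizing at the
#' end. `"N"` and `"."` (unknown) responses do not update the posterior
#' unless `update_negative = TRUE`, in which case `"N"` multiplies by
#' 1 - P(indicator | cause). Updates are accumulated in log space so that
#' products over ~100 indicators cannot underflow.
#'
#' If every cause is annihilated (each has probability zero for at least
#' one reported indicator) the case is uninterpretable and an error of
#' class `va_uninterpretable` is thrown; [va_interpret()] converts this
#' into an indeterminate assignment rather than aborting a cohort run.
#'
#' @param responses Named character vector of responses (`"Y"`, `"N"`,
#'   `"."`), named by indicator; every indicator of `probbase` must be
#'   present.
#' @inheritParams va_complement_likelihood
#' @param update_negative Should `"N"` responses update by 1 - P? Default
#'   `FALSE`.
#' @return Named numeric posterior over causes, summing to 1.
#' @examples
#' pb <- matrix(c(0.9, 0.1, 0.1, 0.1, 0.8, 0.1), nrow = 2, byrow = TRUE,
#'              dimnames = list(c("fever", "cough"), c("a", "b", "c")))
#' va_posterior(c(fever = "Y", cough = "."), pb, c(a = 0.5, b = 0.3, c = 0.2))
#' @export
va_posterior <- function(responses, probbase, prior, update_negative = FALSE) {
  probbase <- validate_probbase(probbase)
  prior <- as_prior(prior)
  stopifnot(identical(sort(names(prior)), sort(colnames(probbase))))
  prior <- prior[colnames(probbase)]
  ind <- rownames(probbase)
  if (is.null(names(responses)) || !all(ind %in% names(responses))) {
    abort("`responses` must be named and cover every indicator in `probbase`.")
  }
  resp <- normalize_responses(responses[ind])
  yes <- matrix(as.numeric(resp == "Y"), nrow = 1, dimnames = list(NULL, ind))
  no <- matrix(as.numeric(resp == "N"), nrow = 1, dimnames = list(NULL, ind))
  lp <- log_posterior_matrix(yes, no, probbase, prior, update_negative)[1, ]
  if (max(lp) < LOGZERO / 2) {
    abort(
      "All causes have zero probability under the observed indicators.",
      class = "va_uninterpretable"
    )
  }
  post <- exp(lp - max(lp))
  post / sum(post)
}

#' Select up to three ranked causes from a posterior
#'
#' Reduces a posterior cause distribution to the reported assignment: if
#' the most probable cause falls below `tau_top` the case is
#' indeterminate; otherwise the top cause is reported together with up to
#' two further causes whose posterior is at least `tau_rel` times the top
#' posterior. Likelihoods are reported as percentages (100 x posterior).
#' Ties are broken by cause order in the posterior vector.
#'
#' @param posterior Named posterior vector (e.g. from [va_posterior()]).
#' @param tau_top Minimum posterior of the leading cause for any
#'   assignment to be made (default 0.4).
#' @param tau_rel Minimum posterior of a secondary cause relative to the
#'   leading cause (default 0.5).
#' @return A tibble with columns `rank`, `cause`, `likelihood_pct`,
#'   `indeterminate`; a single `NA`-ranked `"indeterminate"` row when no
#'   assignment is made.
#' @examples
#' va_select_causes(c(a = 0.55, b = 0.30, c = 0.15))
#' @export
va_select_causes <- function(posterior, tau_top = 0.4, tau_rel = 0.5) {
  stopifnot(
    is.numeric(posterior), !is.null(names(posterior)),
    abs(sum(posterior) - 1) < 1e-6
  )
  ord <- order(-posterior)  # stable: ties keep cause-list order
  top <- posterior[[ord[1]]]
  if (top < tau_top) {
    return(indeterminate_assignment())
  }
  keep <- ord[posterior[ord] >= tau_rel * top]
  keep <- keep[seq_len(min(3L, length(keep)))]
  tibble(
    rank = seq_along(keep),
    cause = names(posterior)[keep],
    likelihood_pct = 100 * unname(posterior[keep]),
    indeterminate = FALSE
  )
}

indeterminate_assignment <- function() {
  tibble(
    rank = NA_integer_, cause = VA_INDETERMINATE,
    likelihood_pct = NA_real_, indeterminate = TRUE
  )
}

#' Interpret a cohort of VA cases
#'
#' Runs the full engine over a case table: adjusts the prior once for the
#' prevalence settings, computes each case's posterior over the observed
#' indicators, and reduces it to a ranked assignment of up to three causes.
#' Cases whose indicators annihilate every cause are assigned
#' `"indeterminate"` with a warning; a cohort run never aborts on a single
#' case. Deterministic: output order follows input order.
#'
#' @param cases Data frame with columns `id`, `age_group`, `sex`, `site`
#'   (extra metadata columns are allowed) plus one `Y`/`N`/`.` column per
#'   indicator of `probbase`.
#' @inheritParams va_posterior
#' @inheritParams va_select_causes
#' @param prevalence A [va_prevalence()] object or `NULL`.
#' @return A tibble of assignments, one row per (case, rank):
#'   `id`, `rank`, `cause`, `likelihood_pct`, `indeterminate`, `method`
#'   (always `"model"`).
#' @export
va_interpret <- function(cases, probbase, prior = va_default_prior(),
                         prevalence = NULL, tau_top = 0.4, tau_rel = 0.5,
                         update_negative = FALSE) {
  probbase <- validate_probbase(probbase)
  prior <- va_adjust_prior(prior, prevalence)
  stopifnot(identical(sort(names(prior)), sort(colnames(probbase))))
  prior <- prior[colnames(probbase)]
  ind <- rownames(probbase)
  if (!"id" %in% names(cases)) {
    abort("`cases` must have an `id` column.")
  }
  missing_ind <- setdiff(ind, names(cases))
  if (length(missing_ind) > 0) {
    abort(paste0(
      "Case table lacks indicator column(s): ",
      paste(head(missing_ind, 5), collapse = ", "),
      if (length(missing_ind) > 5) ", ..."
    ))
  }
  if (nrow(cases) == 0) {
    return(tibble(
      id = character(), rank = integer(), cause = character(),
      likelihood_pct = double(), indeterminate = logical(),
      method = character()
    ))
  }
  resp <- apply(as.matrix(cases[, ind, drop = FALSE]), 2, normalize_responses)
  resp <- matrix(resp, nrow = nrow(cases), dimnames = list(NULL, ind))
  yes <- (resp == "Y") * 1
  no <- (resp == "N") * 1
  lp <- log_posterior_matrix(yes, no, probbase, prior, update_negative)

  ids <- as.character(cases$id)
  out <- purrr::map(seq_len(nrow(lp)), function(i) {
    row <- lp[i, ]
    if (max(row) < LOGZERO / 2) {
      warn(paste0(
        "Case ", ids[i],
        ": all causes have zero probability; assigned indeterminate."
      ))
      asg <- indeterminate_assignment()
    } else {
      post <- exp(row - max(row))
      asg <- va_select_causes(post / sum(post), tau_top, tau_rel)
    }
    mutate(asg, id = ids[i], .before = 1)
  })
  mutate(bind_rows(out), method = "model")
}
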