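# Synthetic VA cohorts with known truth.
#
# The generator mirrors the engine's own generative assumptions: a true
# cause drawn from a known CSMF, conditionally independent Bernoulli
# indicator emission given cause, and missingness that masks responses to
# "unknown" — inflated for injury deaths, whose circumstances live mostly
# in the narrative section of real questionnaires and leave the
# structured indicators sparse. A three-coder physician panel with a
# 2-of-3 / consensus-meeting / indeterminate reconciliation rule
# completes the study design.

# deterministic per-stage seed derivation; stays below 2^31
derive_seed <- function(seed, offset) {
  (as.double(seed) * 10007 + offset * 97) %% 2147483647
}

#' Generate a synthetic conditional probability base
#'
#' Stands in for a real (expert-derived) probability base. Each cause
#' receives a signature subset of indicators — dealt out so every
#' indicator is informative for exactly one cause — whose conditional
#' probability is elevated to
#' `base_rate + informativeness * (1 - base_rate)`; all other entries sit
#' at `base_rate`. As `informativeness` approaches 0 all rows become
#' constant and the engine's posterior collapses to its prior.
#'
#' @param n_causes,n_indicators Dimensions; `n_indicators >= n_causes`
#'   (otherwise some cause would have no signature).
#' @param informativeness In (0, 1): how strongly a signature indicator
#'   separates its cause from the rest.
#' @param base_rate In (0, 1): background probability of any indicator
#'   under a non-signature cause.
#' @param causes,indicators Optional label vectors (defaults
#'   `cause_01`..., `ind_001`...; the default 27-cause dictionary is used
#'   when `n_causes` matches it).
#' @param seed Integer seed; the same seed yields an identical base.
#' @return A probability base matrix (see [va_read_probbase()]).
#' @examples
#' pb <- va_simulate_probbase(4, 12, informativeness = 0.9, seed = 7)
#' range(pb)
#' @export
va_simulate_probbase <- function(n_causes = 27, n_indicators = 100,
                                 informativeness = 0.9, base_rate = 0.05,
                                 causes = NULL, indicators = NULL,
                                 seed = 1) {
  stopifnot(
    informativeness > 0, informativeness < 1,
    base_rate > 0, base_rate < 1
  )
  if (n_indicators < n_causes) {
    abort("Need at least as many indicators as causes to give every cause a signature.")
  }
  if (is.null(causes)) {
    causes <- if (n_causes == length(va_causes())) {
      va_causes()
    } else {
      sprintf("cause_%02d", seq_len(n_causes))
    }
  }
  if (is.null(indicators)) {
    indicators <- sprintf("ind_%03d", seq_len(n_indicators))
  }
  stopifnot(length(causes) == n_causes, length(indicators) == n_indicators)
  p_sig <- base_rate + informativeness * (1 - base_rate)
  withr::with_seed(seed, {
    owner <- sample(rep_len(seq_len(n_causes), n_indicators))
  })
  pb <- matrix(base_rate, nrow = n_indicators, ncol = n_causes,
               dimnames = list(indicators, causes))
  pb[cbind(seq_len(n_indicators), owner)] <- p_sig
  validate_probbase(pb)
}

#' Simulation configuration for a synthetic VA cohort
#'
#' Bundles every parameter of the synthetic study design. Defaults mirror
#' a demographic-surveillance VA series from an urban low-income
#' population: 1,823 deaths of which 31.4% are under five and 64% adult,
#' a high-infectious-burden true CSMF over the 27-cause dictionary, 100
#' binary indicators, 10% item missingness (sharply inflated for injury
#' deaths), and a three-physician panel of moderate accuracy.
#'
#' @param n Number of deaths.
#' @param csmf True cause distribution (named vector or
#'   `cause,probability` data frame); default [va_default_prior()].
#' @param probbase Probability base whose causes match `csmf`; `NULL`
#'   generates one via [va_simulate_probbase()] with `informativeness`,
#'   `base_rate` and `n_indicators`.
#' @param n_indicators,informativeness,base_rate Passed to
#'   [va_simulate_probbase()] when `probbase` is `NULL`.
#' @param missingness Per-indicator probability that a response is masked
#'   to unknown (`"."`).
#' @param injury_sparsity Extra masking for injury-cause deaths: their
#'   missingness is `missingness + injury_sparsity * (1 - missingness)`.
#' @param injury_causes Causes treated as injuries for sparsity.
#' @param theta Coder accuracy: probability each physician assigns the
#'   true cause.
#' @param confusion Optional confusion kernel (square matrix over causes,
#'   rows = true cause) for coder errors; `NULL` = uniform over the other
#'   causes.
#' @param gamma Probability that a consensus meeting (needed when all
#'   three coders differ) succeeds.
#' @param age_mix Named probabilities over [va_age_groups()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `va_sim_config`.
#' @export
va_sim_config <- function(n = 1823,
                          csmf = va_default_prior(),
                          probbase = NULL,
                          n_indicators = 100,
                          informativeness = 0.9,
                          base_rate = 0.05,
                          missingness = 0.1,
                          injury_sparsity = 0.6,
                          injury_causes = c("transport_accident", "other_injury"),
                          theta = 0.7,
                          confusion = NULL,
                          gamma = 0.8,
                          age_mix = c(
                            "<4 weeks" = 0.070, "4 weeks-<5 years" = 0.244,
                            "5-<18 years" = 0.046, "18+ years" = 0.640
                          ),
                          seed = 1) {
  csmf <- as_prior(csmf)
  stopifnot(
    n >= 0, missingness >= 0, missingness <= 1,
    injury_sparsity >= 0, injury_sparsity <= 1,
    theta >= 0, theta <= 1, gamma >= 0, gamma <= 1,
    abs(sum(age_mix) - 1) < 1e-9
  )
  if (is.null(probbase)) {
    probbase <- va_simulate_probbase(
      n_causes = length(csmf), n_indicators = n_indicators,
      informativeness = informativeness, base_rate = base_rate,
      causes = names(csmf), seed = derive_seed(seed, 1)
    )
  }
  probbase <- validate_probbase(probbase)
  stopifnot(setequal(colnames(probbase), names(csmf)))
  structure(
    list(
      n = n, csmf = csmf, probbase = probbase,
      missingness = missingness, injury_sparsity = injury_sparsity,
      injury_causes = injury_causes,
      theta = theta, confusion = confusion, gamma = gamma,
      age_mix = age_mix, seed = seed
    ),
    class = "va_sim_config"
  )
}

#' @export
print.va_sim_config <- function(x, ...) {
  cat("<va_sim_config> n =", x$n,
      "| causes =", length(x$csmf),
      "| indicators =", nrow(x$probbase), "\n")
  cat("  missingness =", x$missingness,
      "(injury sparsity", x$injury_sparsity, ")\n")
  cat("  panel: theta =", x$theta, ", gamma =", x$gamma,
      "| seed =", x$seed, "\n")
  invisible(x)
}

#' Simulate a VA cohort with known causes of death
#'
#' Draws each death's true cause from the configured CSMF, its age group
#' from the age mix, and each binary indicator as
#' Bernoulli(P(indicator | cause)); responses are then masked to unknown
#' at the missingness rate (inflated for injury deaths). Byte-identical
#' output under a fixed config seed.
#'
#' @param config A [va_sim_config()].
#' @return A list with two tibbles: `cases` (`id`, `age_group`, `sex`,
#'   `site`, one `Y`/`N`/`.` column per indicator) and `truth` (`id`,
#'   `cause`, `age_group`).
#' @examples
#' sim <- va_simulate_cohort(va_sim_config(n = 50, seed = 42))
#' dim(sim$cases)
#' head(sim$truth)
#' @export
va_simulate_cohort <- function(config) {
  stopifnot(inherits(config, "va_sim_config"))
  pb <- config$probbase
  causes <- names(config$csmf)
  indicators <- rownames(pb)
  n <- config$n
  if (n == 0) {
    empty_cases <- as_tibble(c(
      list(id = character(), age_group = character(),
           sex = character(), site = character()),
      setNames(rep(list(character()), length(indicators)), indicators)
    ))
    return(list(
      cases = empty_cases,
      truth = tibble(id = character(), cause = character(),
                     age_group = character())
    ))
  }
  ids <- sprintf("case_%05d", seq_len(n))
  withr::with_seed(derive_seed(config$seed, 2), {
    cause <- sample(causes, n, replace = TRUE, prob = config$csmf)
    age_group <- sample(names(config$age_mix), n, replace = TRUE,
                        prob = config$age_mix)
    sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.56, 0.44))
    site <- sample(c("site_a", "site_b"), n, replace = TRUE, prob = c(0.66, 0.34))
    # emission: P(indicator | true cause), cases x indicators
    pmat <- t(pb)[cause, , drop = FALSE]
    yes <- matrix(rbinom(n * length(indicators), 1, pmat) == 1, nrow = n)
    p_miss <- ifelse(
      cause %in% config$injury_causes,
      config$missingness + config$injury_sparsity * (1 - config$missingness),
      config$missingness
    )
    masked <- matrix(
      rbinom(n * length(indicators), 1, rep(p_miss, length(indicators))) == 1,
      nrow = n
    )
  })
  resp <- matrix(ifelse(yes, "Y", "N"), nrow = n)
  resp[masked] <- "."
  colnames(resp) <- indicators
  cases <- dplyr::bind_cols(
    tibble(id = ids, age_group = age_group, sex = sex, site = site),
    as_tibble(resp)
  )
  truth <- tibble(id = ids, cause = cause, age_group = age_group)
  list(cases = cases, truth = truth)
}

#' Two-of-three consensus rule
#'
#' The reconciliation rule of a three-physician panel: any cause assigned
#' by at least two coders is the final cause; when all three differ there
#' is no majority and `NA` is returned (the consensus-meeting stage then
#' decides).
#'
#' @param codes Character vector of length 3: the three coders'
#'   assignments.
#' @return The majority cause, or `NA_character_` when all three differ.
#' @examples
#' va_consensus(c("malaria", "malaria", "pneumonia_sepsis"))
#' va_consensus(c("a", "b", "c"))
#' @export
va_consensus <- function(codes) {
  stopifnot(length(codes) == 3)
  counts <- table(codes)
  if (max(counts) >= 2) {
    names(counts)[which.max(counts)]
  } else {
    NA_character_
  }
}

#' Simulate a three-physician coding panel
#'
#' Each of three independent coders assigns the true cause with
#' probability `theta`, otherwise an error drawn from the confusion
#' kernel (uniform over the other causes by default). The panel's final
#' cause follows the study rule: any cause held by at least two coders
#' stands; when all three differ, a consensus meeting succeeds with
#' probability `gamma` and settles uniformly on one of the three
#' proposals, otherwise the death is `"indeterminate"`.
#'
#' @param truth Truth tibble (`id`, `cause`, ...) from
#'   [va_simulate_cohort()].
#' @param theta Coder accuracy in \[0, 1\].
#' @param confusion Optional confusion kernel: square matrix over causes,
#'   row = true cause; the true cause's own column is ignored and the row
#'   renormalized. `NULL` = uniform errors.
#' @param gamma Consensus-meeting success probability in \[0, 1\].
#' @param causes Cause dictionary coders may assign from; defaults to the
#'   causes present in `truth`.
#' @param seed Integer seed.
#' @return An assignment tibble (`id`, `rank`, `cause`, `likelihood_pct`,
#'   `indeterminate`, `method = "physician"`), one row per case, with the
#'   three per-coder assignments attached as attribute `"coders"`.
#' @export
va_simulate_panel <- function(truth, theta = 0.7, confusion = NULL,
                              gamma = 0.8, causes = NULL, seed = 1) {
  stopifnot(theta >= 0, theta <= 1, gamma >= 0, gamma <= 1)
  if (is.null(causes)) {
    causes <- sort(unique(as.character(truth$cause)))
  }
  if (length(causes) < 2) {
    abort("Panel simulation needs at least two causes in the dictionary.")
  }
  stopifnot(all(truth$cause %in% causes))
  n <- nrow(truth)
  m <- length(causes)
  if (!is.null(confusion)) {
    stopifnot(
      is.matrix(confusion), all(rownames(confusion) == causes),
      all(colnames(confusion) == causes), all(confusion >= 0)
    )
  }
  draw_error <- function(true_cause) {
    if (is.null(confusion)) {
      sample(setdiff(causes, true_cause), 1)
    } else {
      w <- confusion[true_cause, ]
      w[true_cause] <- 0
      if (sum(w) == 0) {
        abort("Confusion kernel row has no mass off the true cause.")
      }
      sample(causes, 1, prob = w)
    }
  }
  withr::with_seed(derive_seed(seed, 3), {
    coders <- matrix(NA_character_, nrow = n, ncol = 3)
    for (j in 1:3) {
      correct <- stats::runif(n) < theta
      coders[, j] <- as.character(truth$cause)
      err_idx <- which(!correct)
      for (i in err_idx) {
        coders[i, j] <- draw_error(as.character(truth$cause[i]))
      }
    }
    final <- vapply(seq_len(n), function(i) {
      maj <- va_consensus(coders[i, ])
      if (!is.na(maj)) {
        return(maj)
      }
      if (stats::runif(1) < gamma) {
        sample(coders[i, ], 1)
      } else {
        VA_INDETERMINATE
      }
    }, character(1))
  })
  out <- tibble(
    id = as.character(truth$id),
    rank = ifelse(final == VA_INDETERMINATE, NA_integer_, 1L),
    cause = final,
    likelihood_pct = NA_real_,
    indeterminate = final == VA_INDETERMINATE,
    method = "physician"
  )
  attr(out, "coders") <- coders
  out
}

#' Truth as an assignment table
#'
#' Recasts a truth tibble in the assignment dialect shared by
#' [va_interpret()] and [va_simulate_panel()], so the true causes flow
#' through the same harmonization and agreement machinery.
#'
#' @param truth Truth tibble (`id`, `cause`, ...).
#' @return An assignment tibble with `method = "truth"`.
#' @export
va_truth_assignments <- function(truth) {
  tibble(
    id = as.character(truth$id),
    rank = 1L,
    cause = as.character(truth$cause),
    likelihood_pct = 100,
    indeterminate = FALSE,
    method = "truth"
  )
}
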