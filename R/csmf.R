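#' Cause-specific mortality fractions
#'
#' Tabulates the fraction of deaths attributed to each broad cause group
#' — the population-level quantity VA interpretation aims at. Under the
#' default `"all_cases"` convention `"indeterminate"` is kept as an
#' explicit category and fractions sum to 1 over the full stratum; under
#' `"determined_only"` indeterminate cases are removed from the
#' denominator, so each remaining fraction can only grow.
#'
#' @param groups Data frame `id`, `group` (one row per case), e.g. from
#'   [va_harmonize()].
#' @param denominator `"all_cases"` (default) or `"determined_only"`.
#' @param stratum,method Labels recorded on the table.
#' @param levels Optional character vector fixing the group rows (zero
#'   counts included); defaults to the observed groups in canonical
#'   order.
#' @return A tibble of class `va_csmf` with columns `stratum`, `method`,
#'   `group`, `count`, `fraction`; attributes `denominator` and `n`.
#' @examples
#' g <- data.frame(id = 1:5,
#'                 group = c("malaria", "malaria", "hiv_aids",
#'                           "indeterminate", "injuries"))
#' va_csmf(g)
#' va_csmf(g, denominator = "determined_only")
#' @export
va_csmf <- function(groups, denominator = c("all_cases", "determined_only"),
                    stratum = "overall", method = "unspecified",
                    levels = NULL) {
  denominator <- arg_match(denominator)
  if (nrow(groups) == 0) {
    abort("Cannot compute CSMF on an empty cohort.")
  }
  g <- as.character(groups$group)
  if (denominator == "determined_only") {
    g <- g[g != VA_INDETERMINATE]
    if (length(g) == 0) {
      abort("No determined cases: CSMF undefined under `determined_only`.")
    }
  }
  if (is.null(levels)) {
    canonical <- c(va_cause_groups(), VA_INDETERMINATE)
    observed <- unique(g)
    levels <- c(
      intersect(canonical, observed),
      sort(setdiff(observed, canonical))
    )
  }
  counts <- table(factor(g, levels = levels))
  out <- tibble(
    stratum = stratum,
    method = method,
    group = levels,
    count = as.integer(counts),
    fraction = as.integer(counts) / length(g)
  )
  structure(out,
    class = c("va_csmf", class(out)),
    denominator = denominator, n = length(g)
  )
}

#' Roll CSMF groups up into major mortality categories
#'
#' Aggregates a CSMF table into broader categories (by default the
#' four-way infectious / noncommunicable / injuries /
#' maternal-perinatal-nutrition split of [va_rollup_map()]).
#' `"indeterminate"` always rolls up to itself; counts and fractions are
#' conserved.
#'
#' @param t A `va_csmf` table.
#' @param rollup Data frame `group`, `category` mapping every group of
#'   `t` (other than `"indeterminate"`) to a category.
#' @return A `va_csmf` table over the categories.
#' @export
va_rollup <- function(t, rollup = va_rollup_map()) {
  stopifnot(inherits(t, "va_csmf"))
  key <- setNames(as.character(rollup$category), as.character(rollup$group))
  key[VA_INDETERMINATE] <- VA_INDETERMINATE
  unmapped <- setdiff(t$group, names(key))
  if (length(unmapped) > 0) {
    abort(paste0(
      "Rollup map lacks group(s): ", paste(unmapped, collapse = ", ")
    ))
  }
  cat_levels <- unique(unname(key[t$group]))
  agg <- t %>%
    as_tibble() %>%
    mutate(category = unname(key[.data$group])) %>%
    group_by(.data$stratum, .data$method, .data$category) %>%
    summarise(
      count = sum(.data$count), fraction = sum(.data$fraction),
      .groups = "drop"
    ) %>%
    rename(group = "category") %>%
    arrange(match(.data$group, cat_levels))
  structure(agg,
    class = c("va_csmf", class(agg)),
    denominator = attr(t, "denominator"), n = attr(t, "n")
  )
}

#' CSMF accuracy
#'
#' Standard single-number summary of how well an estimated cause
#' distribution recovers a reference one:
#' \deqn{1 - \frac{\sum_g |a_g - b_g|}{2\,(1 - \min_g b_g)}}
#' where `b` is the reference (e.g. the true CSMF of a synthetic cohort).
#' Equals 1 iff the distributions are identical and is bounded in
#' \[0, 1\].
#'
#' @param a,b Numeric fraction vectors over the same groups (`b` is the
#'   reference), or two `va_csmf` tables with identical group sets.
#' @return A scalar in \[0, 1\].
#' @export
va_csmf_accuracy <- function(a, b) {
  if (inherits(a, "va_csmf")) {
    a <- setNames(a$fraction, a$group)
  }
  if (inherits(b, "va_csmf")) {
    b <- setNames(b$fraction, b$group)
  }
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      abort("CSMF accuracy requires identical group sets.")
    }
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b))
  acc <- 1 - sum(abs(a - b)) / (2 * (1 - min(b)))
  max(0, min(1, acc))
}

#' Compare two CSMF tables side by side
#'
#' Joins two CSMF tables over the same stratum and group set, reporting
#' per-group counts, fractions and absolute differences, plus the
#' [va_csmf_accuracy()] of `a` against reference `b` as an attribute.
#'
#' @param a,b `va_csmf` tables with identical group sets (`b` is the
#'   reference method).
#' @return A tibble of class `va_csmf_comparison` with columns `group`,
#'   `count_a`, `fraction_a`, `count_b`, `fraction_b`, `abs_diff`;
#'   attributes `csmf_accuracy`, `method_a`, `method_b`, `stratum`.
#' @export
va_compare_csmf <- function(a, b) {
  stopifnot(inherits(a, "va_csmf"), inherits(b, "va_csmf"))
  if (!setequal(a$group, b$group)) {
    abort("CSMF tables have different group sets; cannot compare.")
  }
  bb <- b[match(a$group, b$group), ]
  out <- tibble(
    group = a$group,
    count_a = a$count, fraction_a = a$fraction,
    count_b = bb$count, fraction_b = bb$fraction,
    abs_diff = abs(a$fraction - bb$fraction)
  )
  structure(out,
    class = c("va_csmf_comparison", class(out)),
    csmf_accuracy = va_csmf_accuracy(
      setNames(a$fraction, a$group), setNames(bb$fraction, bb$group)
    ),
    method_a = a$method[1], method_b = bb$method[1],
    stratum = a$stratum[1]
  )
}
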