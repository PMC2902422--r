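#' Cross-tabulate two methods' harmonized cause groups
#'
#' Builds the square contingency table underlying all case-by-case
#' agreement statistics: cell (g, h) counts the cases assigned group g by
#' method `a` and group h by method `b`. Both inputs must cover exactly
#' the same case ids. The shared label set is the union of observed
#' labels in a fixed order (canonical group order first, then any other
#' labels alphabetically, `"indeterminate"` last).
#'
#' @param a,b Data frames with columns `id`, `group` (e.g. from
#'   [va_harmonize()]).
#' @param stratum Label attached to the table (e.g. `"overall"`,
#'   `"under-5"`).
#' @return A square integer matrix of class `va_xtab` (rows = method a,
#'   columns = method b) with a `stratum` attribute.
#' @export
va_cross_tabulate <- function(a, b, stratum = "overall") {
  ida <- as.character(a$id)
  idb <- as.character(b$id)
  if (anyDuplicated(ida) || anyDuplicated(idb)) {
    abort("Case ids must be unique within each method.")
  }
  bad <- c(setdiff(ida, idb), setdiff(idb, ida))
  if (length(bad) > 0) {
    abort(paste0(
      "Case ids do not match between methods: ",
      paste(head(unique(bad), 10), collapse = ", ")
    ))
  }
  ga <- setNames(as.character(a$group), ida)[ida]
  gb <- setNames(as.character(b$group), idb)[ida]
  observed <- unique(c(ga, gb))
  canonical <- c(va_cause_groups(), VA_INDETERMINATE)
  labels <- c(
    intersect(canonical, observed),
    sort(setdiff(observed, canonical))
  )
  # keep indeterminate last even for non-canonical label sets
  if (VA_INDETERMINATE %in% labels) {
    labels <- c(setdiff(labels, VA_INDETERMINATE), VA_INDETERMINATE)
  }
  tab <- table(
    factor(ga, levels = labels),
    factor(gb, levels = labels)
  )
  out <- matrix(as.integer(tab), nrow = length(labels),
                dimnames = list(a = labels, b = labels))
  structure(out, class = c("va_xtab", "matrix"), stratum = stratum)
}

#' @export
print.va_xtab <- function(x, ...) {
  cat("<va_xtab> stratum:", attr(x, "stratum"),
      " n =", sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

drop_indeterminate <- function(t) {
  keep <- rownames(t) != VA_INDETERMINATE
  structure(
    t[keep, keep, drop = FALSE],
    class = class(t), stratum = attr(t, "stratum")
  )
}

#' Percent case-by-case agreement
#'
#' Fraction of cases receiving the same broad group from both methods
#' (diagonal sum over grand total). With `exclude_indeterminate = TRUE`
#' the `"indeterminate"` row and column are removed from both axes first
#' — the sensitivity analysis asking how methods agree on the cases where
#' both committed to a cause.
#'
#' @param t A `va_xtab` contingency table.
#' @param exclude_indeterminate Drop the indeterminate row/column first?
#' @return One-row tibble: `stratum`, `n_agree`, `n_total`, `percent`.
#' @export
va_percent_agreement <- function(t, exclude_indeterminate = FALSE) {
  stopifnot(inherits(t, "va_xtab"))
  if (exclude_indeterminate) {
    t <- drop_indeterminate(t)
  }
  n_total <- sum(t)
  if (n_total == 0) {
    abort("Agreement undefined: no cases remain in the table.")
  }
  n_agree <- sum(diag(t))
  tibble(
    stratum = attr(t, "stratum") %||% "overall",
    n_agree = as.integer(n_agree),
    n_total = as.integer(n_total),
    percent = 100 * n_agree / n_total
  )
}

#' Cohen's kappa for a contingency table
#'
#' Chance-corrected agreement between two categorical raters:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} where \eqn{p_o} is the observed
#' agreement (diagonal proportion) and \eqn{p_e} the agreement expected
#' from the margins (\eqn{\sum_i p_{i.} p_{.i}}). The standard error uses
#' the asymptotic large-sample (Fleiss–Cohen–Everitt) variance, and the
#' 95% confidence interval is \eqn{\kappa \pm 1.96\,\mathrm{SE}}.
#'
#' Unweighted, multi-category kappa: all disagreements count equally.
#' Kappa is 1 for a purely diagonal table and 0 when observed cell
#' proportions equal the products of the margins.
#'
#' @param t A `va_xtab` contingency table (or any square numeric matrix
#'   with identical row/column labels).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `va_kappa`: a list with elements `po`,
#'   `pe`, `kappa`, `se`, `ci_low`, `ci_high`, `n`, `n_categories`,
#'   `stratum`. Supports [tidy()] and [glance()].
#' @examples
#' t <- va_cross_tabulate(
#'   data.frame(id = 1:4, group = c("a", "a", "b", "b")),
#'   data.frame(id = 1:4, group = c("a", "a", "b", "a"))
#' )
#' va_kappa(t)
#' @export
va_kappa <- function(t, conf_level = 0.95) {
  stopifnot(is.matrix(t), nrow(t) == ncol(t), nrow(t) >= 2, all(t >= 0))
  n <- sum(t)
  if (n <= 0) {
    abort("Kappa undefined on an empty table.")
  }
  p <- t / n
  prow <- rowSums(p)
  pcol <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(prow * pcol)
  if (pe >= 1 - 1e-12) {
    abort("Kappa undefined: expected agreement is 1 (all margin mass in one category).")
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance of kappa-hat
  i <- seq_len(nrow(p))
  a_term <- sum(diag(p) * ((1 - pe) - (pcol + prow) * (1 - po))^2)
  sum_mat <- outer(pcol, prow, "+")^2 * p  # cell (i,j): p_ij (p_.i + p_j.)^2
  diag(sum_mat) <- 0
  b_term <- (1 - po)^2 * sum(sum_mat)
  c_term <- (po * pe - 2 * pe + po)^2
  var_k <- (a_term + b_term - c_term) / (n * (1 - pe)^4)
  se <- sqrt(max(var_k, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      po = po, pe = pe, kappa = kappa, se = se,
      ci_low = kappa - z * se, ci_high = kappa + z * se,
      conf_level = conf_level,
      n = n, n_categories = nrow(t),
      stratum = attr(t, "stratum") %||% "overall"
    ),
    class = "va_kappa"
  )
}

#' @export
print.va_kappa <- function(x, digits = 3, ...) {
  cat("Cohen's kappa (", x$stratum, "): ",
    format(round(x$kappa, digits)), " [",
    format(round(x$ci_low, digits)), ", ",
    format(round(x$ci_high, digits)), "]  n = ", x$n, "\n",
    sep = ""
  )
  cat("  observed agreement ", format(round(100 * x$po, 2)),
    "%, expected ", format(round(100 * x$pe, 2)), "%\n",
    sep = ""
  )
  invisible(x)
}

#' Agreement restricted to the k-th ranked model cause
#'
#' Physician review assigns one cause per death while the engine reports
#' up to three ranked causes. This compares the physician groups with the
#' model's rank-`k` cause: the model assignments are harmonized at rank
#' `k` and agreement is computed on the case subset holding at least `k`
#' model causes (all cases when `restrict = FALSE`).
#'
#' @param physician Data frame `id`, `group` of physician-assigned groups.
#' @param assignments Model assignment tibble (see [va_interpret()]).
#' @inheritParams va_harmonize
#' @param k Model cause rank to compare (1, 2 or 3).
#' @param restrict Keep only cases with at least `k` model causes?
#'   Default `TRUE`.
#' @return A list with elements `table` (`va_xtab`), `agreement` (one-row
#'   tibble from [va_percent_agreement()]) and `kappa` (`va_kappa`).
#' @export
va_rank_agreement <- function(physician, assignments, map, k = 1,
                              restrict = TRUE) {
  stopifnot(k %in% 1:3)
  if (restrict) {
    eligible <- assignments %>%
      filter(!is.na(.data$rank)) %>%
      group_by(.data$id) %>%
      summarise(n_causes = max(.data$rank), .groups = "drop") %>%
      filter(.data$n_causes >= k) %>%
      pull(.data$id)
    if (length(eligible) == 0) {
      abort(paste0("No cases have ", k, " or more model causes."))
    }
    assignments <- filter(assignments, .data$id %in% eligible)
    physician <- filter(physician, as.character(.data$id) %in% as.character(eligible))
  }
  model_groups <- va_harmonize(assignments, map, rank = k)
  t <- va_cross_tabulate(physician, model_groups,
                         stratum = paste0("rank-", k))
  list(
    table = t,
    agreement = va_percent_agreement(t),
    kappa = va_kappa(t)
  )
}
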