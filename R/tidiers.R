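#' Tidy and glance methods
#'
#' broom-style summaries of the package's result objects.
#'
#' * `tidy(<va_kappa>)`: one row with `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' * `glance(<va_kappa>)`: one row adding observed/expected agreement,
#'   `n` and category count.
#' * `tidy(<va_xtab>)`: the contingency table in long form (`a`, `b`,
#'   `n`).
#' * `glance(<va_csmf_comparison>)`: the CSMF accuracy and method labels.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name va_tidiers
NULL

#' @rdname va_tidiers
#' @method tidy va_kappa
#' @export
tidy.va_kappa <- function(x, ...) {
  tibble(
    stratum = x$stratum,
    estimate = x$kappa,
    std.error = x$se,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
}

#' @rdname va_tidiers
#' @method glance va_kappa
#' @export
glance.va_kappa <- function(x, ...) {
  tibble(
    stratum = x$stratum,
    kappa = x$kappa,
    std.error = x$se,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    p.observed = x$po,
    p.expected = x$pe,
    n = x$n,
    n.categories = x$n_categories
  )
}

#' @rdname va_tidiers
#' @method tidy va_xtab
#' @export
tidy.va_xtab <- function(x, ...) {
  long <- as.data.frame.table(unclass(x), responseName = "n",
                              stringsAsFactors = FALSE)
  as_tibble(setNames(long, c("a", "b", "n")))
}

#' @rdname va_tidiers
#' @method glance va_csmf_comparison
#' @export
glance.va_csmf_comparison <- function(x, ...) {
  tibble(
    stratum = attr(x, "stratum"),
    method_a = attr(x, "method_a"),
    method_b = attr(x, "method_b"),
    csmf_accuracy = attr(x, "csmf_accuracy")
  )
}
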