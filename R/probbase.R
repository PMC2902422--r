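#' Read and validate a conditional probability base
#'
#' The engine's knowledge is a matrix of conditional probabilities
#' P(indicator | cause): one row per binary VA indicator, one column per
#' cause of death. `va_read_probbase()` reads the CSV dialect used
#' throughout the package (header row = cause labels, first column =
#' indicator labels, cells = probabilities in \[0, 1\]).
#'
#' No indicator row may be all-zero: such an indicator could never be
#' observed under any cause, so a case reporting it would be
#' uninterpretable by construction.
#'
#' @param path Path to a probability base CSV.
#' @return A numeric matrix (indicators x causes) with dimnames.
#' @seealso [va_simulate_probbase()] to generate a synthetic base.
#' @export
va_read_probbase <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), comment = "#",
                        progress = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1]])
  validate_probbase(mat)
}

#' @rdname va_read_probbase
#' @param probbase A probability base matrix.
#' @export
va_write_probbase <- function(probbase, path) {
  probbase <- validate_probbase(probbase)
  df <- dplyr::bind_cols(
    tibble(indicator = rownames(probbase)),
    as_tibble(probbase)
  )
  readr::write_csv(df, path)
  invisible(path)
}

validate_probbase <- function(probbase) {
  if (!is.matrix(probbase) || !is.numeric(probbase)) {
    abort("`probbase` must be a numeric matrix (indicators x causes).")
  }
  if (is.null(rownames(probbase)) || is.null(colnames(probbase))) {
    abort("`probbase` must carry indicator rownames and cause colnames.")
  }
  if (anyDuplicated(rownames(probbase)) || anyDuplicated(colnames(probbase))) {
    abort("Indicator and cause labels must be unique.")
  }
  if (VA_INDETERMINATE %in% colnames(probbase)) {
    abort("\"indeterminate\" is a reserved label and cannot be a cause.")
  }
  if (anyNA(probbase) || any(probbase < 0) || any(probbase > 1)) {
    abort("All probability base entries must lie in [0, 1].")
  }
  zero_rows <- rownames(probbase)[rowSums(probbase) == 0]
  if (length(zero_rows) > 0) {
    abort(paste0(
      "Indicator row(s) all zero (never observable under any cause): ",
      paste(zero_rows, collapse = ", ")
    ))
  }
  probbase
}

#' Read or coerce a prior cause distribution
#'
#' The prior over causes is the population-level cause-specific mortality
#' fraction (CSMF) the engine starts from before seeing any indicator.
#' `va_read_prior()` reads a two-column `cause,probability` CSV;
#' `as_prior()` accepts a named numeric vector or such a data frame and
#' returns a validated named vector (entries in (0, 1\], summing to 1; a
#' non-normalized input is rescaled).
#'
#' @param path Path to a `cause,probability` CSV.
#' @return A named numeric probability vector over causes.
#' @export
va_read_prior <- function(path) {
  df <- readr::read_csv(path, col_types = "cd", comment = "#",
                        progress = FALSE)
  as_prior(setNames(df[[2]], df[[1]]))
}

#' @rdname va_read_prior
#' @param prior Named numeric vector or `cause,probability` data frame.
#' @export
as_prior <- function(prior) {
  if (is.data.frame(prior)) {
    prior <- setNames(prior[[2]], as.character(prior[[1]]))
  }
  if (!is.numeric(prior) || is.null(names(prior)) || anyDuplicated(names(prior))) {
    abort("`prior` must be a numeric vector uniquely named by cause.")
  }
  if (anyNA(prior) || any(prior <= 0)) {
    abort("Prior probabilities must be strictly positive.")
  }
  prior <- prior / sum(prior)
  stopifnot(abs(sum(prior) - 1) < 1e-9)
  prior
}

#' Default prior cause-specific mortality fractions
#'
#' A plausible all-ages CSMF over the default 27-cause dictionary for an
#' urban low-income population with a high infectious disease burden.
#' Shipped as `extdata/default_csmf.csv`; replace with a local CSMF
#' whenever one is available.
#'
#' @return Named numeric vector over [va_causes()], summing to 1.
#' @examples
#' round(sort(va_default_prior(), decreasing = TRUE)[1:5], 3)
#' @export
va_default_prior <- function() {
  va_read_prior(
    system.file("extdata", "default_csmf.csv", package = "vacompare")
  )
}
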