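# CSV dialects shared by every pipeline stage. All writers embed run
# metadata (seed, config hash) as leading "# key: value" comment lines;
# all readers skip such lines, so every writer's output round-trips
# through its reader.

write_csv_meta <- function(df, path, meta = NULL) {
  writeLines(
    if (length(meta) > 0) paste0("# ", names(meta), ": ", unlist(meta)) else character(),
    path
  )
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_csv_meta <- function(path, col_types = readr::cols()) {
  readr::read_csv(path, comment = "#", col_types = col_types,
                  progress = FALSE)
}

#' Read and write pipeline CSV files
#'
#' The pipeline speaks three table dialects: case tables (`id`,
#' `age_group`, `sex`, `site`, one `Y`/`N`/`.` column per indicator),
#' assignment tables (`id`, `rank`, `cause`, `likelihood_pct`,
#' `indeterminate`, `method`) and truth tables (`id`, `cause`,
#' `age_group`). Writers prepend `# key: value` metadata comment lines
#' (e.g. seed and config hash); readers skip them.
#'
#' @param path File path.
#' @param cases,assignments,truth The tibble to write.
#' @param meta Named list written as leading comment lines.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @export
va_read_cases <- function(path) {
  df <- read_csv_meta(path, readr::cols(.default = readr::col_character()))
  required <- c("id", "age_group", "sex", "site")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Case file ", path, " lacks column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  df
}

#' @rdname va_read_cases
#' @export
va_write_cases <- function(cases, path, meta = NULL) {
  write_csv_meta(cases, path, meta)
}

#' @rdname va_read_cases
#' @export
va_read_assignments <- function(path) {
  read_csv_meta(path, readr::cols(
    id = readr::col_character(), rank = readr::col_integer(),
    cause = readr::col_character(),
    likelihood_pct = readr::col_double(),
    indeterminate = readr::col_logical(),
    method = readr::col_character()
  ))
}

#' @rdname va_read_cases
#' @export
va_write_assignments <- function(assignments, path, meta = NULL) {
  write_csv_meta(assignments, path, meta)
}

#' @rdname va_read_cases
#' @export
va_read_truth <- function(path) {
  read_csv_meta(path, readr::cols(.default = readr::col_character()))
}

#' @rdname va_read_cases
#' @export
va_write_truth <- function(truth, path, meta = NULL) {
  write_csv_meta(truth, path, meta)
}
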