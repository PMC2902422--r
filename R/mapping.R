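#' Cause mapping tables
#'
#' Physicians and the probabilistic engine assign causes on different
#' dictionaries (a 60-code abridged ICD-10-style list vs. a 27-cause model
#' list); comparison requires harmonizing both into the same 14 broad
#' cause groups. A mapping table is a two-column `source_code,group` CSV:
#' a total function from source codes to group labels (no duplicate
#' sources, no empty groups). `"indeterminate"` always maps to itself and
#' never appears as a source code.
#'
#' `va_read_mapping()` reads and validates any such CSV;
#' `va_default_map()` returns the mapping shipped for each scheme.
#'
#' @param path Path to a `source_code,group` CSV.
#' @return A tibble of class `va_cause_map` with columns `source_code`,
#'   `group`.
#' @examples
#' nrow(va_default_map("physician"))  # 60 codes
#' nrow(va_default_map("interva"))    # 27 causes
#' @export
va_read_mapping <- function(path) {
  map <- readr::read_csv(path, col_types = "cc", comment = "#",
                         progress = FALSE)
  if (!identical(names(map)[1:2], c("source_code", "group"))) {
    abort("Mapping CSV must have columns `source_code,group`.")
  }
  dup <- map$source_code[duplicated(map$source_code)]
  if (length(dup) > 0) {
    abort(paste0(
      "Duplicate source code(s) in mapping: ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  if (anyNA(map$group) || any(!nzchar(map$group))) {
    abort("Mapping contains empty group labels.")
  }
  if (VA_INDETERMINATE %in% map$source_code) {
    abort("\"indeterminate\" is a reserved label, not a mappable source code.")
  }
  structure(map, class = c("va_cause_map", class(map)))
}

#' @rdname va_read_mapping
#' @param scheme `"physician"` (60-code abridged ICD-10 list) or
#'   `"interva"` (27-cause model list).
#' @export
va_default_map <- function(scheme = c("physician", "interva")) {
  scheme <- arg_match(scheme)
  file <- paste0(scheme, "_map.csv")
  va_read_mapping(system.file("extdata", file, package = "vacompare"))
}

#' Map a cause code to its broad group
#'
#' Looks a source code up in a mapping table. `"indeterminate"` passes
#' through unchanged; any other unmapped code is an error naming the code
#' (codes are never silently dropped).
#'
#' @param code Character vector of source codes.
#' @param map A mapping table from [va_read_mapping()] or
#'   [va_default_map()].
#' @return Character vector of group labels.
#' @examples
#' va_map_cause("eclampsia", va_default_map("physician"))
#' va_map_cause("kidney_disease", va_default_map("interva"))
#' @export
va_map_cause <- function(code, map) {
  stopifnot(inherits(map, "va_cause_map"))
  idx <- match(code, map$source_code)
  out <- map$group[idx]
  out[code == VA_INDETERMINATE] <- VA_INDETERMINATE
  unmapped <- unique(code[is.na(out)])
  if (length(unmapped) > 0) {
    abort(paste0(
      "Unmapped cause code(s): ", paste(unmapped, collapse = ", ")
    ))
  }
  out
}

#' Harmonize a cohort's assignments into broad cause groups
#'
#' Reduces a ranked assignment table to one broad group per case: the
#' rank-`rank` cause is mapped through `map`; cases without a cause at
#' that rank (including indeterminate cases) are assigned
#' `"indeterminate"`. Comparative analyses conventionally use the most
#' probable cause (`rank = 1`), since physician review assigns a single
#' cause per death.
#'
#' @param assignments Assignment tibble (`id`, `rank`, `cause`, ...), as
#'   produced by [va_interpret()] or [va_simulate_panel()].
#' @inheritParams va_map_cause
#' @param rank Which ranked cause to harmonize (1, 2 or 3).
#' @return A tibble with columns `id`, `group`, one row per case, in
#'   first-appearance order of `id`.
#' @export
va_harmonize <- function(assignments, map, rank = 1) {
  stopifnot(rank %in% 1:3)
  ids <- unique(as.character(assignments$id))
  at_rank <- assignments[!is.na(assignments$rank) & assignments$rank == rank, ]
  group <- setNames(rep(VA_INDETERMINATE, length(ids)), ids)
  group[as.character(at_rank$id)] <- va_map_cause(at_rank$cause, map)
  tibble(id = ids, group = unname(group))
}
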