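# End-to-end orchestration: simulate -> interpret -> panel -> compare,
# driven by one run configuration. Every stage is deterministic given the
# config seed; stage outputs carry the seed and a config hash so reports
# are traceable to the exact settings that produced them. No stage
# mutates its inputs.

#' Analysis strata from age groups
#'
#' Comparative analyses focus on the under-5 and adult (18+) strata,
#' where mortality from preventable conditions concentrates; 5–17-year
#' deaths are reported as `"other (5-17)"` rather than dropped, so
#' stratum counts always reconcile with the cohort total.
#'
#' @param age_group Character vector of [va_age_groups()] labels.
#' @return Character vector: `"under-5"`, `"other (5-17)"` or `"adult"`.
#' @export
va_stratum <- function(age_group) {
  out <- rep(NA_character_, length(age_group))
  out[age_group %in% c("<4 weeks", "4 weeks-<5 years")] <- "under-5"
  out[age_group == "5-<18 years"] <- "other (5-17)"
  out[age_group == "18+ years"] <- "adult"
  if (anyNA(out)) {
    abort(paste0(
      "Unknown age group(s): ",
      paste(unique(age_group[is.na(out)]), collapse = ", ")
    ))
  }
  out
}

#' Stratified agreement report for two methods
#'
#' The headline comparison table: for the overall cohort and each age
#' stratum, the number and percent of deaths on which both methods agree
#' and Cohen's kappa with its 95% confidence interval. An optional
#' sensitivity row recomputes overall agreement with all indeterminate
#' cases dropped from both axes.
#'
#' @param physician,model Data frames `id`, `group` of harmonized
#'   assignments from the two methods (same id set).
#' @param meta Data frame `id`, `age_group` giving each case's age group
#'   (e.g. the simulated case table).
#' @param sensitivity Add an `"overall (excl. indeterminate)"` row?
#'   Default `TRUE`.
#' @return A tibble of class `va_agreement_report`: one row per stratum
#'   with `stratum`, `n`, `n_agree`, `percent`, `kappa`, `ci_low`,
#'   `ci_high`.
#' @export
va_agreement_report <- function(physician, model, meta,
                                sensitivity = TRUE) {
  meta <- mutate(meta, stratum = va_stratum(.data$age_group))
  strata <- list(overall = as.character(meta$id))
  for (s in c("under-5", "adult", "other (5-17)")) {
    ids <- as.character(meta$id[meta$stratum == s])
    if (length(ids) > 0) {
      strata[[s]] <- ids
    }
  }
  one_row <- function(name, ids, exclude = FALSE) {
    t <- va_cross_tabulate(
      filter(physician, as.character(.data$id) %in% ids),
      filter(model, as.character(.data$id) %in% ids),
      stratum = name
    )
    pa <- va_percent_agreement(t, exclude_indeterminate = exclude)
    kp <- va_kappa(if (exclude) drop_indeterminate(t) else t)
    tibble(
      stratum = name, n = pa$n_total, n_agree = pa$n_agree,
      percent = pa$percent, kappa = kp$kappa,
      ci_low = kp$ci_low, ci_high = kp$ci_high
    )
  }
  rows <- purrr::imap(strata, function(ids, name) one_row(name, ids))
  if (sensitivity) {
    rows <- c(rows, list(
      one_row("overall (excl. indeterminate)", strata$overall,
              exclude = TRUE)
    ))
  }
  out <- bind_rows(rows)
  structure(out, class = c("va_agreement_report", class(out)))
}

default_run_config <- function() {
  list(
    seed = 1,
    outdir = "va_run",
    simulate = list(
      n_cases = 1823, n_indicators = 100, informativeness = 0.9,
      base_rate = 0.05, missingness = 0.1, injury_sparsity = 0.6,
      theta = 0.7, gamma = 0.8
    ),
    prevalence = list(
      malaria = "low", hiv = "high",
      multiplier_high = 1.0, multiplier_low = 0.1
    ),
    thresholds = list(tau_top = 0.4, tau_rel = 0.5),
    paths = list(
      probbase = NULL, prior = NULL, cases = NULL, truth = NULL,
      model_assignments = NULL, physician_assignments = NULL,
      interva_map = NULL, physician_map = NULL
    )
  )
}

#' Run configuration for the end-to-end pipeline
#'
#' Reads a YAML run configuration (or builds one from arguments),
#' merging user settings over the defaults: master `seed`, output
#' directory, simulation parameters, prevalence settings, reporting
#' thresholds, and optional input-file paths overriding the simulated
#' defaults. Every referenced input file must exist.
#'
#' @param path Optional YAML file.
#' @param ... Named overrides merged over the file/defaults (nested lists
#'   merge element-wise).
#' @return A list of class `va_run_config`.
#' @export
va_run_config <- function(path = NULL, ...) {
  cfg <- default_run_config()
  merge_into <- function(base, new) {
    for (k in names(new)) {
      if (is.list(base[[k]]) && is.list(new[[k]])) {
        base[[k]] <- merge_into(base[[k]], new[[k]])
      } else {
        base[[k]] <- new[[k]]
      }
    }
    base
  }
  if (!is.null(path)) {
    cfg <- merge_into(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_into(cfg, list(...))
  given <- purrr::compact(cfg$paths)
  missing_files <- names(given)[!vapply(given, file.exists, logical(1))]
  if (length(missing_files) > 0) {
    abort(paste0(
      "Configured input file(s) do not exist: ",
      paste(missing_files, collapse = ", ")
    ))
  }
  structure(cfg, class = "va_run_config")
}

run_meta <- function(cfg) {
  # hash the analytic settings only: where outputs land is not part of
  # what identifies a run
  settings <- unclass(cfg)
  settings$outdir <- NULL
  list(seed = cfg$seed, config_hash = rlang::hash(settings))
}

cfg_path <- function(cfg, key, default_file) {
  cfg$paths[[key]] %||% file.path(cfg$outdir, default_file)
}

#' Pipeline stages
#'
#' Config-driven entry points tying the stages into the end-to-end
#' comparison; each reads its inputs from the paths in `cfg` (falling
#' back to the previous stage's outputs under `cfg$outdir`), writes CSV
#' outputs stamped with the seed and config hash, and returns its result
#' invisibly. Deterministic under a fixed config.
#'
#' * `va_run_simulate()`: synthetic cohort -> `cases.csv`, `truth.csv`,
#'   `probbase.csv`, `prior.csv`
#' * `va_run_interpret()`: Bayes engine -> `model_assignments.csv`
#' * `va_run_panel()`: physician panel -> `physician_assignments.csv`
#' * `va_run_compare()`: harmonization + agreement + CSMF ->
#'   `agreement_report.csv`, `csmf_report.csv`
#'
#' @param cfg A [va_run_config()].
#' @return The stage's main result, invisibly.
#' @export
va_run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "va_run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  s <- cfg$simulate
  sim_cfg <- va_sim_config(
    n = s$n_cases, n_indicators = s$n_indicators,
    informativeness = s$informativeness, base_rate = s$base_rate,
    missingness = s$missingness, injury_sparsity = s$injury_sparsity,
    theta = s$theta, gamma = s$gamma, seed = cfg$seed
  )
  sim <- va_simulate_cohort(sim_cfg)
  meta <- run_meta(cfg)
  va_write_cases(sim$cases, file.path(cfg$outdir, "cases.csv"), meta)
  va_write_truth(sim$truth, file.path(cfg$outdir, "truth.csv"), meta)
  va_write_probbase(sim_cfg$probbase, file.path(cfg$outdir, "probbase.csv"))
  write_csv_meta(
    tibble(cause = names(sim_cfg$csmf), probability = unname(sim_cfg$csmf)),
    file.path(cfg$outdir, "prior.csv"), meta
  )
  invisible(sim)
}

#' @rdname va_run_simulate
#' @export
va_run_interpret <- function(cfg) {
  stopifnot(inherits(cfg, "va_run_config"))
  cases <- va_read_cases(cfg_path(cfg, "cases", "cases.csv"))
  probbase <- va_read_probbase(cfg_path(cfg, "probbase", "probbase.csv"))
  prior <- va_read_prior(cfg_path(cfg, "prior", "prior.csv"))
  prev <- va_prevalence(
    malaria = cfg$prevalence$malaria, hiv = cfg$prevalence$hiv,
    multiplier_high = cfg$prevalence$multiplier_high,
    multiplier_low = cfg$prevalence$multiplier_low
  )
  if (!all(c(prev$malaria_causes, prev$hiv_causes) %in% names(prior))) {
    prev <- NULL  # prior over a dictionary without the adjusted causes
  }
  asg <- va_interpret(
    cases, probbase, prior, prevalence = prev,
    tau_top = cfg$thresholds$tau_top, tau_rel = cfg$thresholds$tau_rel
  )
  va_write_assignments(
    asg, file.path(cfg$outdir, "model_assignments.csv"), run_meta(cfg)
  )
  invisible(asg)
}

#' @rdname va_run_simulate
#' @export
va_run_panel <- function(cfg) {
  stopifnot(inherits(cfg, "va_run_config"))
  truth <- va_read_truth(cfg_path(cfg, "truth", "truth.csv"))
  prior <- va_read_prior(cfg_path(cfg, "prior", "prior.csv"))
  panel <- va_simulate_panel(
    truth, theta = cfg$simulate$theta, gamma = cfg$simulate$gamma,
    causes = names(prior), seed = cfg$seed
  )
  va_write_assignments(
    panel, file.path(cfg$outdir, "physician_assignments.csv"), run_meta(cfg)
  )
  invisible(panel)
}

#' @rdname va_run_simulate
#' @export
va_run_compare <- function(cfg) {
  stopifnot(inherits(cfg, "va_run_config"))
  cases <- va_read_cases(cfg_path(cfg, "cases", "cases.csv"))
  model_asg <- va_read_assignments(
    cfg_path(cfg, "model_assignments", "model_assignments.csv")
  )
  phys_asg <- va_read_assignments(
    cfg_path(cfg, "physician_assignments", "physician_assignments.csv")
  )
  map_path <- cfg$paths$interva_map
  map <- if (is.null(map_path)) va_default_map("interva") else va_read_mapping(map_path)

  model_groups <- va_harmonize(model_asg, map, rank = 1)
  phys_groups <- va_harmonize(phys_asg, map, rank = 1)
  meta_df <- select(cases, "id", "age_group")

  report <- va_agreement_report(phys_groups, model_groups, meta_df)
  meta <- run_meta(cfg)
  write_csv_meta(
    as_tibble(report),
    file.path(cfg$outdir, "agreement_report.csv"), meta
  )

  strata <- c(overall = NA, `under-5` = "under-5", adult = "adult")
  csmf_rows <- purrr::imap(strata, function(s, name) {
    ids <- if (is.na(s)) {
      as.character(meta_df$id)
    } else {
      as.character(meta_df$id[va_stratum(meta_df$age_group) == s])
    }
    bind_rows(
      as_tibble(va_csmf(filter(phys_groups, .data$id %in% ids),
                        stratum = name, method = "physician")),
      as_tibble(va_csmf(filter(model_groups, .data$id %in% ids),
                        stratum = name, method = "model"))
    )
  })
  csmf_report <- bind_rows(csmf_rows)
  write_csv_meta(csmf_report, file.path(cfg$outdir, "csmf_report.csv"), meta)
  invisible(list(agreement = report, csmf = csmf_report))
}

#' @rdname va_run_simulate
#' @export
va_run_pipeline <- function(cfg) {
  va_run_simulate(cfg)
  va_run_interpret(cfg)
  va_run_panel(cfg)
  va_run_compare(cfg)
}
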