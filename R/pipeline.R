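#' Variables tested per task in the group-comparison report
#'
#' RJA compares the face-to-object transition rates, their normalized
#' score, first-look accuracy and the fixation-duration shares; the
#' initiating tasks add the object-to-face direction, between-object
#' transitions (IJA1) and the congruent-first-look conditional face FD.
#'
#' @param task Task name.
#' @return Character vector of measure columns.
#' @export
study_variables <- function(task) {
  switch(task,
    RJA = c("t_face_target", "t_face_non_target", "norm_transition_score",
            "norm_accuracy", "fd_pct_face", "fd_pct_target",
            "fd_pct_non_target", "fd_pct_target_first_target",
            "fd_pct_non_target_first_target"),
    IJA1 = c("t_target_face", "t_non_target_face", "norm_transition_score",
             "t_face_target", "t_face_non_target", "t_between_objects",
             "norm_accuracy", "fd_pct_face", "fd_pct_target",
             "fd_pct_non_target", "fd_pct_face_first_target"),
    IJA2 = c("t_target_face", "t_face_target", "fd_pct_face",
             "fd_pct_target", "fd_pct_face_first_target"),
    stop("unknown task: ", task, call. = FALSE)
  )
}

#' Correlations of comparable measures across the two initiating tasks
#'
#' Within each group, correlates the per-trial transition rates that
#' exist in both initiating tasks (target-to-face and face-to-target),
#' Pearson or Spearman according to the distribution gate.
#'
#' @param measures Per-participant measures tibble with a `task` column.
#' @return Tibble of correlation rows with a `group` column.
#' @export
cross_task_correlations <- function(measures) {
  vars <- c("t_target_face", "t_face_target")
  rows <- list()
  for (grp in unique(measures$group)) {
    m <- measures[measures$group == grp, ]
    wide <- m |>
      dplyr::select(dplyr::all_of(c("participant_id", "task", vars))) |>
      tidyr::pivot_wider(names_from = "task", values_from = dplyr::all_of(vars))
    for (v in vars) {
      c1 <- paste0(v, "_IJA1"); c2 <- paste0(v, "_IJA2")
      if (!all(c(c1, c2) %in% names(wide))) next
      res <- tryCatch(correlate_auto(wide, c1, c2), error = function(e) NULL)
      if (!is.null(res)) {
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(group = grp), res
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

.config_error <- function(...) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Run a full study from a configuration
#'
#' Orchestrates the pipeline end to end: obtain recordings (either by
#' simulation from presets or by reading gaze logs named after the
#' metadata's participant ids), run event detection, trial segmentation
#' and exclusion, compute per-participant measures, group comparisons
#' with FDR, the usable-trial repeated-measures ANOVA, fixation-duration
#' summaries and cross-task correlations, and (optionally) write the
#' report bundle as plain CSVs plus a JSON manifest.
#'
#' The configuration is a JSON file or an equivalent list with:
#' \describe{
#'   \item{simulate}{`n_asd`, `n_td`, optional `tasks`}
#'   \item{data}{`gaze_dir` and `metadata` (CSV path) for real logs}
#'   \item{task_config}{path to a task/AOI config; packaged default
#'     when omitted}
#'   \item{analysis}{`q` (FDR level), `fdr_family` (`task`/`global`),
#'     `dispersion_max_deg`, `min_duration_ms`}
#'   \item{seed}{integer, recorded in the manifest}
#' }
#' Exactly one of `simulate`/`data` must be present.
#'
#' @param config Path to a JSON study config, or a list.
#' @param out_dir Output directory for the report bundle; `NULL` skips
#'   writing.
#' @return A list of result tables (invisible when writing):
#'   `measures`, `comparisons`, `usable`, `usable_anova`, `fd_summary`,
#'   `correlations`, `manifest`.
#' @export
run_study <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) .config_error("study config not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (sum(c("simulate", "data") %in% names(config)) != 1) {
    .config_error("study config error: exactly one of 'simulate' or 'data' required")
  }
  an <- modifyList(
    list(q = 0.05, fdr_family = "task", dispersion_max_deg = 1.0,
         min_duration_ms = 60),
    if (is.null(config$analysis)) list() else as.list(config$analysis)
  )
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  task_cfg <- load_task_config(config$task_config)

  if ("data" %in% names(config)) {
    d <- config$data
    if (is.null(d$metadata) || !file.exists(d$metadata)) {
      .config_error("study config error: metadata file missing or not found")
    }
    meta <- read_participant_metadata(d$metadata)
    paths <- file.path(d$gaze_dir, paste0(meta$participant_id, ".csv"))
    absent <- !file.exists(paths)
    if (any(absent)) {
      .config_error("study config error: gaze log(s) not found: ",
                    paste(paths[absent], collapse = ", "))
    }
    recordings <- lapply(seq_len(nrow(meta)), function(i) {
      read_gaze_csv(paths[i], task_cfg$screen,
                    participant_id = meta$participant_id[i],
                    group = meta$group[i], covariate = meta$covariate[i])
    })
  } else {
    s <- config$simulate
    sim <- simulate_study(
      n_asd = if (is.null(s$n_asd)) 17 else s$n_asd,
      n_td = if (is.null(s$n_td)) 15 else s$n_td,
      config = task_cfg, tasks = s$tasks, seed = seed
    )
    recordings <- lapply(sim$participants, function(p) p$recording)
  }

  trials <- dplyr::bind_rows(lapply(recordings, function(rec) {
    analyze_recording(rec, task_cfg,
                      dispersion_max_deg = an$dispersion_max_deg,
                      min_duration_ms = an$min_duration_ms)
  }))
  measures <- participant_measures(trials)
  usable <- usable_trial_summary(trials)
  usable_rm <- tryCatch({
    counts <- trials |>
      dplyr::group_by(.data$participant_id, .data$group, .data$task) |>
      dplyr::summarise(n_usable = sum(.data$usable), .groups = "drop")
    usable_trials_anova(counts)
  }, error = function(e) tibble::tibble(term = character(), df1 = numeric(),
                                        df2 = numeric(), F = numeric(),
                                        p = numeric()))
  comparisons <- dplyr::bind_rows(lapply(unique(measures$task), function(tk) {
    compare_groups(measures[measures$task == tk, ], study_variables(tk),
                   q = an$q, family = an$fdr_family)
  }))
  fd_summary <- measures |>
    tidyr::pivot_longer(dplyr::starts_with("fd_pct_"),
                        names_to = "measure", values_to = "fd_pct") |>
    dplyr::group_by(.data$task, .data$group, .data$measure) |>
    dplyr::summarise(
      mean_fd_pct = mean(.data$fd_pct, na.rm = TRUE),
      sd_fd_pct = sd(.data$fd_pct, na.rm = TRUE),
      n = sum(is.finite(.data$fd_pct)), .groups = "drop"
    )
  correlations <- if (all(c("IJA1", "IJA2") %in% measures$task)) {
    cross_task_correlations(measures)
  } else {
    tibble::tibble()
  }
  excl <- trials |>
    dplyr::group_by(.data$exclusion_reason) |>
    dplyr::summarise(n_trials = dplyr::n(), .groups = "drop")
  manifest <- list(
    package_version = as.character(utils::packageVersion("jagaze")),
    seed = seed,
    n_participants = length(recordings),
    analysis = an,
    excluded_trials = excl,
    config = config[setdiff(names(config), "analysis")]
  )
  results <- list(
    measures = measures, comparisons = comparisons,
    usable = usable, usable_anova = usable_rm,
    fd_summary = fd_summary, correlations = correlations,
    manifest = manifest, trials = trials
  )
  if (!is.null(out_dir)) {
    write_report_bundle(results, out_dir)
    return(invisible(results))
  }
  results
}

#' Write the report bundle of a study run
#'
#' Plain CSVs (diff-able, deterministic for a fixed seed) plus a JSON
#' manifest. Columns are documented in the package's data dictionary
#' (`inst/extdata/data_dictionary.md`).
#'
#' @param results A [run_study()] result list.
#' @param out_dir Directory to create/populate.
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(results$measures, file.path(out_dir, "participant_measures.csv"))
  readr::write_csv(results$comparisons, file.path(out_dir, "group_comparisons.csv"))
  readr::write_csv(results$usable$by_participant, file.path(out_dir, "usable_trials.csv"))
  readr::write_csv(results$usable$by_group, file.path(out_dir, "usable_trials_by_group.csv"))
  readr::write_csv(results$usable_anova, file.path(out_dir, "usable_trials_anova.csv"))
  readr::write_csv(results$fd_summary, file.path(out_dir, "fd_summary.csv"))
  if (nrow(results$correlations) > 0) {
    readr::write_csv(results$correlations, file.path(out_dir, "correlations.csv"))
  }
  jsonlite::write_json(results$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
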