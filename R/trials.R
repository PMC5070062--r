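#' Build the default trial timeline of a study configuration
#'
#' Trials run in the configured block order with an attention-getter gap
#' before each trial; the gap re-centres the child's gaze between trials
#' and is not part of any analysed phase.
#'
#' @param config A [load_task_config()] result.
#' @param gap_ms Attention-getter gap before each trial, ms.
#' @param t0_ms Recording time of the first gap start.
#' @return Tibble `task, trial_index, onset_ms, duration_ms`.
#' @export
trial_plan <- function(config, gap_ms = 1000, t0_ms = 0) {
  rows <- list()
  t <- t0_ms
  for (task in task_order(config)) {
    dur <- sum(task_segments(config, task))
    for (j in seq_len(task_n_trials(config, task))) {
      t <- t + gap_ms
      rows[[length(rows) + 1]] <- tibble::tibble(
        task = task, trial_index = j, onset_ms = t, duration_ms = dur
      )
      t <- t + dur
    }
  }
  dplyr::bind_rows(rows)
}

#' Segment detected fixations into trials and phases
#'
#' Each trial is split into its three contiguous phases (looking-down,
#' interaction, joint attention). A fixation is assigned to the trial,
#' and within it the phase, holding the majority of its duration; ties go
#' to the earlier phase. Fixations are then AOI-labelled with the trial's
#' AOI set (target side varies by trial).
#'
#' @param fixations Tibble from [detect_fixations()].
#' @param plan Tibble from [trial_plan()] (or the same columns with
#'   measured onsets). Trials must not overlap in time.
#' @param config A [load_task_config()] result.
#' @return A trial tibble: `task, trial_index, onset_ms` plus a
#'   list-column `fixations` whose elements carry `phase` and `aoi`.
#' @export
segment_trials <- function(fixations, plan, config) {
  plan <- dplyr::arrange(tibble::as_tibble(plan), .data$onset_ms)
  if (!"duration_ms" %in% names(plan)) {
    plan$duration_ms <- vapply(plan$task, function(tk) sum(task_segments(config, tk)),
                               numeric(1))
  }
  if (nrow(plan) > 1 &&
      any(plan$onset_ms[-1] < (plan$onset_ms + plan$duration_ms)[-nrow(plan)])) {
    stop("timeline error: trials overlap", call. = FALSE)
  }
  n_f <- nrow(fixations)
  n_t <- nrow(plan)
  # trial assignment by majority overlap
  assigned <- rep(0L, n_f)
  if (n_f > 0) {
    ov <- matrix(0, n_f, n_t)
    for (k in seq_len(n_t)) {
      ov[, k] <- pmax(0, pmin(fixations$offset_ms, plan$onset_ms[k] + plan$duration_ms[k]) -
                        pmax(fixations$onset_ms, plan$onset_ms[k]))
    }
    best <- max.col(ov, ties.method = "first")
    assigned <- ifelse(ov[cbind(seq_len(n_f), best)] > 0, best, 0L)
  }
  plan$fixations <- lapply(seq_len(n_t), function(k) {
    fx <- fixations[assigned == k, , drop = FALSE]
    segs <- task_segments(config, plan$task[k])
    bounds <- plan$onset_ms[k] + cumsum(c(0, unname(segs)))
    phases <- c("looking_down", "interaction", "ja")
    if (nrow(fx) > 0) {
      pov <- vapply(1:3, function(p) {
        pmax(0, pmin(fx$offset_ms, bounds[p + 1]) - pmax(fx$onset_ms, bounds[p]))
      }, numeric(nrow(fx)))
      pov <- matrix(pov, nrow = nrow(fx))
      fx$phase <- phases[max.col(pov, ties.method = "first")]
    } else {
      fx$phase <- character(0)
    }
    assign_aoi(fx, trial_aois(config, plan$task[k], plan$trial_index[k]))
  })
  plan
}

#' Apply the trial-exclusion criteria
#'
#' Criterion 1 (checked first): no face-AOI fixation during the
#' interaction phase, i.e. the child never looked at the face that
#' anchors the upcoming joint-attention bid. Criterion 2: no on-screen
#' fixation at all during the joint-attention phase (the child looked
#' away for the entire phase). "Looking at" is operationalised as at
#' least one detected fixation (>= 60 ms); "on-screen" as a fixation
#' centroid inside the screen bounds.
#'
#' @param trials Trial tibble from [segment_trials()].
#' @param geometry A [screen_geometry()] for the screen bounds.
#' @return `trials` with logical `usable` and character
#'   `exclusion_reason` (`"none"`, `"no_face_interactive"`,
#'   `"away_whole_ja"`) columns.
#' @export
apply_exclusions <- function(trials, geometry = screen_geometry()) {
  reason <- vapply(trials$fixations, function(fx) {
    face_int <- any(fx$phase == "interaction" & fx$aoi == "face")
    if (!face_int) return("no_face_interactive")
    ja_on <- any(fx$phase == "ja" &
                   fx$cx_px >= 0 & fx$cx_px < geometry$width_px &
                   fx$cy_px >= 0 & fx$cy_px < geometry$height_px)
    if (!ja_on) return("away_whole_ja")
    "none"
  }, character(1))
  trials$exclusion_reason <- reason
  trials$usable <- reason == "none"
  trials
}

#' Run the event and trial layers on one recording
#'
#' Convenience wrapper: fixation detection, trial/phase segmentation,
#' AOI labelling and exclusion flagging in one call.
#'
#' @param rec A [gaze_recording()].
#' @param config A [load_task_config()] result.
#' @param plan Trial timeline; defaults to [trial_plan()] of the config
#'   (the layout the simulator emits).
#' @param ... Passed to [detect_fixations()].
#' @return Trial tibble with `participant_id` and `group` columns added.
#' @export
analyze_recording <- function(rec, config, plan = NULL, ...) {
  if (is.null(plan)) plan <- trial_plan(config)
  fx <- detect_fixations(rec, ...)
  trials <- segment_trials(fx, plan, config)
  trials <- apply_exclusions(trials, rec$geometry)
  trials$participant_id <- rec$participant_id
  trials$group <- rec$group
  trials$covariate <- rec$covariate
  trials
}

#' Summarise usable-trial counts
#'
#' @param trials Trial tibble (rows from [apply_exclusions()], possibly
#'   several participants bound together) with `participant_id`, `group`,
#'   `task` and `usable` columns.
#' @return A list with `by_participant` (usable counts overall and per
#'   task) and `by_group` (group mean and sd of the overall count).
#' @export
usable_trial_summary <- function(trials) {
  if (nrow(trials) == 0) {
    return(list(
      by_participant = tibble::tibble(participant_id = character(),
                                      group = character(), n_usable = integer()),
      by_group = tibble::tibble(group = character(), mean_usable = numeric(),
                                sd_usable = numeric(), n = integer())
    ))
  }
  per_task <- trials |>
    dplyr::group_by(.data$participant_id, .data$group, .data$task) |>
    dplyr::summarise(n_usable = sum(.data$usable), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "task", values_from = "n_usable",
                       names_prefix = "usable_")
  overall <- trials |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(n_usable = sum(.data$usable), .groups = "drop")
  by_participant <- dplyr::left_join(overall, per_task,
                                     by = c("participant_id", "group"))
  by_group <- overall |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_usable = mean(.data$n_usable),
                     sd_usable = sd(.data$n_usable),
                     n = dplyr::n(), .groups = "drop")
  list(by_participant = by_participant, by_group = by_group)
}
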