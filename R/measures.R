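#' Normalized first-look accuracy
#'
#' `(n_target - n_nontarget) / (n_target + n_nontarget)` over the trials
#' in which the child looked at either object; `NA` (undefined) when the
#' child never looked at either object. Positive values mean a
#' preference for the cued/moving object.
#'
#' @param n_first_target,n_first_nontarget Trial counts (>= 0).
#' @return A score in `[-1, 1]`, or `NA`.
#' @examples
#' normalized_accuracy(6, 2) # 0.5
#' @export
normalized_accuracy <- function(n_first_target, n_first_nontarget) {
  .norm_score(n_first_target, n_first_nontarget)
}

.norm_score <- function(a, b) {
  if (any(c(a, b) < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  ifelse(is.na(a) | is.na(b) | (a + b) == 0, NA_real_, (a - b) / (a + b))
}

#' Normalized transition score, responding-JA form
#'
#' Difference between the total number of face-to-target and
#' face-to-non-target transitions, divided by the total number of
#' transitions from the face to either object (totals across a
#' participant's usable trials). Note the denominator: with the same
#' absolute imbalance, more total transitions give a smaller score.
#'
#' @param t_face_to_target,t_face_to_nontarget Transition totals.
#' @return Score in `[-1, 1]`, or `NA` when no such transition occurred.
#' @export
norm_transition_score_rja <- function(t_face_to_target, t_face_to_nontarget) {
  .norm_score(t_face_to_target, t_face_to_nontarget)
}

#' Normalized transition score, initiating-JA form
#'
#' Same construction on the object-to-face direction: target-to-face
#' minus non-target-to-face transitions over all object-to-face
#' transitions.
#'
#' @param t_target_to_face,t_nontarget_to_face Transition totals.
#' @return Score in `[-1, 1]`, or `NA`.
#' @export
norm_transition_score_ija1 <- function(t_target_to_face, t_nontarget_to_face) {
  .norm_score(t_target_to_face, t_nontarget_to_face)
}

.ja_fix <- function(trial_fixations) {
  trial_fixations[trial_fixations$phase == "ja", , drop = FALSE]
}

.count_pair <- function(tr, from, to) sum(tr$from_aoi == from & tr$to_aoi == to)

#' Transition counts over the usable trials of a trial table
#'
#' Extracts joint-attention-phase transitions per usable trial and
#' returns totals and per-trial means for the ordered AOI pairs the
#' analysis uses, with target-to-non-target and non-target-to-target
#' pooled as `between_objects`.
#'
#' @param trials Trial tibble from [analyze_recording()] (one
#'   participant; filter or group upstream for several).
#' @return Tibble `task, pair, total, n_usable_trials, per_trial_mean`;
#'   means are `NA` when a task has no usable trials.
#' @export
transition_counts <- function(trials) {
  pairs <- tibble::tribble(
    ~pair, ~from, ~to,
    "face_target", "face", "target",
    "target_face", "target", "face",
    "face_non_target", "face", "non_target",
    "non_target_face", "non_target", "face",
    "target_non_target", "target", "non_target",
    "non_target_target", "non_target", "target"
  )
  out <- lapply(unique(trials$task), function(tk) {
    tt <- trials[trials$task == tk & trials$usable, , drop = FALSE]
    trans <- lapply(tt$fixations, function(fx) extract_transitions(.ja_fix(fx)))
    totals <- vapply(seq_len(nrow(pairs)), function(i) {
      sum(vapply(trans, .count_pair, numeric(1), pairs$from[i], pairs$to[i]))
    }, numeric(1))
    res <- tibble::tibble(task = tk, pair = pairs$pair, total = totals)
    res <- dplyr::bind_rows(res, tibble::tibble(
      task = tk, pair = "between_objects",
      total = sum(totals[pairs$pair %in% c("target_non_target", "non_target_target")])
    ))
    res$n_usable_trials <- nrow(tt)
    res$per_trial_mean <- ifelse(res$n_usable_trials > 0,
                                 res$total / res$n_usable_trials, NA_real_)
    res
  })
  dplyr::bind_rows(out)
}

#' Fixation-duration percentage on an AOI
#'
#' Summed joint-attention-phase fixation time on `aoi` across the usable
#' trials, as a percentage of the participant's total on-trial fixation
#' time (all detected JA-phase fixations, including those on empty
#' screen). `NA` when there is no fixation time at all.
#'
#' @param trials Trial tibble (one participant, one task after
#'   filtering; the function uses all usable rows it is given).
#' @param aoi AOI name (`"face"`, `"target"`, `"non_target"`).
#' @return Percentage in `[0, 100]`, or `NA`.
#' @export
fixation_duration_pct <- function(trials, aoi) {
  tt <- trials[trials$usable, , drop = FALSE]
  ja <- lapply(tt$fixations, .ja_fix)
  total <- sum(vapply(ja, function(fx) sum(fx$duration_ms), numeric(1)))
  if (total == 0) return(NA_real_)
  on_aoi <- sum(vapply(ja, function(fx) sum(fx$duration_ms[fx$aoi == aoi]),
                       numeric(1)))
  100 * on_aoi / total
}

#' Conditional fixation-duration percentage
#'
#' [fixation_duration_pct()] restricted to the usable trials whose first
#' object look satisfies `condition` (by default a congruent first look,
#' i.e. first look on the target). Used to ask how gaze is distributed
#' once the child engaged with the cued object.
#'
#' @inheritParams fixation_duration_pct
#' @param condition First-look value selecting trials (default
#'   `"target"`).
#' @return Percentage, or `NA` when no trial satisfies the condition.
#' @export
conditional_fd <- function(trials, aoi, condition = "target") {
  fl <- vapply(trials$fixations, function(fx) first_look(.ja_fix(fx)), character(1))
  sub <- trials[trials$usable & fl == condition, , drop = FALSE]
  if (nrow(sub) == 0) return(NA_real_)
  fixation_duration_pct(sub, aoi)
}

#' Per-participant, per-task measures table
#'
#' Computes every participant-level quantity the group statistics use:
#' first-look counts and normalized accuracy, transition totals and
#' per-trial means, the task-appropriate normalized transition score
#' (face-to-object form for RJA, object-to-face form for IJA1),
#' fixation-duration percentages per AOI and their congruent-first-look
#' conditional versions. Only usable trials contribute; undefined scores
#' are `NA` and later drop that participant from the affected
#' comparison.
#'
#' @param trials Trial tibble from [analyze_recording()], any number of
#'   participants bound together.
#' @return A tibble with one row per participant x task.
#' @export
participant_measures <- function(trials) {
  groups <- dplyr::distinct(trials, .data$participant_id, .data$group,
                            .data$covariate, .data$task)
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    tt <- trials[trials$participant_id == groups$participant_id[i] &
                   trials$task == groups$task[i], , drop = FALSE]
    usable <- tt[tt$usable, , drop = FALSE]
    fl <- vapply(usable$fixations, function(fx) first_look(.ja_fix(fx)), character(1))
    n_ft <- sum(fl == "target")
    n_fn <- sum(fl == "non_target")
    tc <- transition_counts(tt)
    tot <- function(p) tc$total[tc$pair == p]
    ptm <- function(p) tc$per_trial_mean[tc$pair == p]
    score <- switch(groups$task[i],
      RJA = norm_transition_score_rja(tot("face_target"), tot("face_non_target")),
      IJA1 = norm_transition_score_ija1(tot("target_face"), tot("non_target_face")),
      NA_real_
    )
    tibble::tibble(
      participant_id = groups$participant_id[i],
      group = groups$group[i],
      covariate = groups$covariate[i],
      task = groups$task[i],
      n_trials = nrow(tt),
      n_usable = nrow(usable),
      n_first_target = n_ft,
      n_first_nontarget = n_fn,
      norm_accuracy = normalized_accuracy(n_ft, n_fn),
      t_face_target = ptm("face_target"),
      t_target_face = ptm("target_face"),
      t_face_non_target = ptm("face_non_target"),
      t_non_target_face = ptm("non_target_face"),
      t_between_objects = ptm("between_objects"),
      total_face_target = tot("face_target"),
      total_target_face = tot("target_face"),
      total_face_non_target = tot("face_non_target"),
      total_non_target_face = tot("non_target_face"),
      total_between_objects = tot("between_objects"),
      norm_transition_score = score,
      fd_pct_face = fixation_duration_pct(usable, "face"),
      fd_pct_target = fixation_duration_pct(usable, "target"),
      fd_pct_non_target = fixation_duration_pct(usable, "non_target"),
      fd_pct_face_first_target = conditional_fd(usable, "face", "target"),
      fd_pct_target_first_target = conditional_fd(usable, "target", "target"),
      fd_pct_non_target_first_target = conditional_fd(usable, "non_target", "target")
    )
  })
  dplyr::bind_rows(rows)
}
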