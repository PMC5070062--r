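test_that("normalized scores reproduce hand-computed values", {
  expect_equal(normalized_accuracy(6, 2), 0.5)
  expect_equal(normalized_accuracy(3, 3), 0)
  expect_true(is.na(normalized_accuracy(0, 0)))
  expect_error(normalized_accuracy(-1, 2), "non-negative")

  expect_equal(norm_transition_score_rja(4, 4), 0)
  expect_equal(norm_transition_score_rja(3, 1), 0.5)
  expect_true(is.na(norm_transition_score_rja(0, 0)))

  expect_equal(norm_transition_score_ija1(5, 0), 1)
  expect_equal(norm_transition_score_ija1(7, 3), 0.4)
})

test_that("normalized scores shrink with total transitions at fixed difference", {
  # same imbalance ratio: unchanged; same absolute difference: halved
  expect_equal(norm_transition_score_ija1(14, 6), norm_transition_score_ija1(7, 3))
  expect_equal(norm_transition_score_ija1(10, 6),
               norm_transition_score_ija1(6, 2) / 2)
})

test_that("normalized scores stay in [-1, 1] and are antisymmetric", {
  for (a in 0:8) for (b in 0:8) {
    if (a + b == 0) next
    s <- normalized_accuracy(a, b)
    expect_true(s >= -1 && s <= 1)
    expect_equal(normalized_accuracy(b, a), -s)
  }
})

# build a minimal analysed trial table directly from AOI label runs
trial_from_labels <- function(labels, task = "IJA1", trial_index = 1,
                              usable = TRUE, durations = NULL) {
  n <- length(labels)
  if (is.null(durations)) durations <- rep(100, n)
  fx <- tibble::tibble(
    onset_ms = cumsum(c(0, durations + 50))[seq_len(n)],
    offset_ms = cumsum(c(0, durations + 50))[seq_len(n)] + durations,
    duration_ms = durations,
    cx_px = 0, cy_px = 0, n_samples = 12L,
    phase = rep("ja", n), aoi = labels
  )
  tibble::tibble(
    task = task, trial_index = trial_index, onset_ms = 0,
    duration_ms = 11000, fixations = list(fx),
    exclusion_reason = ifelse(usable, "none", "away_whole_ja"),
    usable = usable,
    participant_id = "p1", group = "ASD", covariate = 100
  )
}

test_that("transition counts match hand traces, with between-object pooling", {
  t1 <- trial_from_labels(c("face", "target", "face"))
  tc <- transition_counts(t1)
  expect_equal(tc$total[tc$pair == "face_target"], 1)
  expect_equal(tc$total[tc$pair == "target_face"], 1)
  expect_equal(tc$total[tc$pair == "between_objects"], 0)

  t2 <- trial_from_labels(c("target", "non_target", "target"))
  tc2 <- transition_counts(t2)
  expect_equal(tc2$total[tc2$pair == "between_objects"], 2)
  expect_equal(tc2$per_trial_mean[tc2$pair == "between_objects"], 2)

  t3 <- trial_from_labels(c("face", "target"), usable = FALSE)
  tc3 <- transition_counts(t3)
  expect_true(all(is.na(tc3$per_trial_mean)))
  expect_equal(tc3$total, rep(0, 7))
})

test_that("transition totals over several trials equal per-trial brute force", {
  set.seed(13)
  labels <- c("face", "target", "non_target", "none")
  trials <- dplyr::bind_rows(lapply(1:4, function(j) {
    trial_from_labels(sample(labels, 10, replace = TRUE), trial_index = j)
  }))
  tc <- transition_counts(trials)
  brute <- Reduce(`+`, lapply(trials$fixations, function(fx) {
    or <- oracle_transitions(fx$aoi)
    c(
      face_target = sum(or$from_aoi == "face" & or$to_aoi == "target"),
      target_face = sum(or$from_aoi == "target" & or$to_aoi == "face"),
      between = sum(or$from_aoi %in% c("target", "non_target") &
                      or$to_aoi %in% c("target", "non_target"))
    )
  }))
  expect_equal(tc$total[tc$pair == "face_target"], unname(brute["face_target"]))
  expect_equal(tc$total[tc$pair == "target_face"], unname(brute["target_face"]))
  expect_equal(tc$total[tc$pair == "between_objects"], unname(brute["between"]))
})

test_that("fixation-duration percentages are shares of all on-trial fixation time", {
  tr <- trial_from_labels(c("face", "target", "none"),
                          durations = c(1000, 500, 500))
  expect_equal(fixation_duration_pct(tr, "face"), 50)
  expect_equal(fixation_duration_pct(tr, "target"), 25)
  expect_equal(fixation_duration_pct(tr, "non_target"), 0)
  only <- trial_from_labels("face", durations = 800)
  expect_equal(fixation_duration_pct(only, "face"), 100)
  # AOI shares plus the off-AOI share always close to 100
  shares <- sum(fixation_duration_pct(tr, "face"),
                fixation_duration_pct(tr, "target"),
                fixation_duration_pct(tr, "non_target"))
  off <- 100 * 500 / 2000
  expect_equal(shares + off, 100)
  none_tr <- trial_from_labels(character(0), durations = numeric(0))
  expect_true(is.na(fixation_duration_pct(none_tr, "face")))
})

test_that("conditional FD restricts to congruent-first-look trials", {
  t1 <- trial_from_labels(c("target", "face"), trial_index = 1,
                          durations = c(400, 600))   # first look target
  t2 <- trial_from_labels(c("non_target", "face"), trial_index = 2,
                          durations = c(500, 500))   # first look non-target
  both <- dplyr::bind_rows(t1, t2)
  expect_equal(conditional_fd(both, "face", "target"), 60)
  expect_equal(conditional_fd(t1, "face", "target"),
               fixation_duration_pct(t1, "face"))
  expect_true(is.na(conditional_fd(t2, "face", "target")))
})

test_that("swapping object labels negates scores and swaps counts", {
  set.seed(17)
  labels <- sample(c("face", "target", "non_target", "none"), 30, replace = TRUE)
  tr <- trial_from_labels(labels)
  swapped_labels <- c(target = "non_target", non_target = "target",
                      face = "face", none = "none")[labels]
  tr2 <- trial_from_labels(unname(swapped_labels))
  m1 <- participant_measures(tr)
  m2 <- participant_measures(tr2)
  expect_equal(m1$norm_transition_score, -m2$norm_transition_score)
  expect_equal(m1$t_face_target, m2$t_face_non_target)
  expect_equal(m1$t_between_objects, m2$t_between_objects)
})
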