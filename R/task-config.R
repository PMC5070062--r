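#' Load and validate a task/AOI configuration
#'
#' A task configuration describes the stimulus timeline and the named
#' screen regions of a joint-attention study: for each task (RJA,
#' IJA1, IJA2) the three segment durations (looking-down, interaction,
#' joint attention), the trial list with the per-trial target side, and
#' the AOI rectangles. Rectangles are `[x0, y0, x1, y1]` in pixels with
#' half-open bounds: a point on the right or bottom edge is outside.
#'
#' Validation rejects non-positive segment durations, unknown task names,
#' empty trial lists and AOI rectangles that overlap within a trial.
#'
#' @param path Path to a JSON config; defaults to the packaged layout
#'   (three tasks, four trials each, target side alternating left/right
#'   for RJA and IJA1, a single crossing-object region for IJA2).
#' @return A `task_config` object (a validated nested list).
#' @export
load_task_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_task_config.json", package = "jagaze")
  }
  if (!file.exists(path)) stop("task config not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  problems <- character()
  req_top <- c("screen", "aois", "tasks")
  miss <- setdiff(req_top, names(cfg))
  if (length(miss) > 0) problems <- c(problems, paste0("missing /", miss))
  if (length(problems) == 0) {
    for (nm in names(cfg$aois)) {
      r <- unlist(cfg$aois[[nm]])
      if (length(r) != 4 || !all(is.finite(r)) || r[1] >= r[3] || r[2] >= r[4]) {
        problems <- c(problems, paste0("/aois/", nm, ": invalid rectangle"))
      }
    }
    for (i in seq_along(cfg$tasks)) {
      tk <- cfg$tasks[[i]]
      at <- paste0("/tasks/", i)
      if (is.null(tk$task) || !tk$task %in% c("RJA", "IJA1", "IJA2")) {
        problems <- c(problems, paste0(at, "/task: must be RJA, IJA1 or IJA2"))
        next
      }
      segs <- unlist(tk$segments_ms)
      if (!all(c("looking_down", "interaction", "ja") %in% names(segs)) ||
          any(!is.finite(segs)) || any(segs <= 0)) {
        problems <- c(problems, paste0(at, "/segments_ms: three positive durations required"))
      }
      if (length(tk$trials) < 1) {
        problems <- c(problems, paste0(at, "/trials: at least one trial required"))
      }
      for (j in seq_along(tk$trials)) {
        side <- tk$trials[[j]]$target_side
        if (is.null(side) || !side %in% c("left", "right", "center")) {
          problems <- c(problems, paste0(at, "/trials/", j, "/target_side: left, right or center"))
        }
      }
    }
  }
  if (length(problems) > 0) {
    stop("task config error:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  }
  cfg$screen <- do.call(screen_geometry, cfg$screen)
  cfg <- structure(cfg, class = "task_config")
  # per-trial AOI overlap check needs resolved AOI sets
  for (tk in cfg$tasks) {
    for (j in seq_along(tk$trials)) {
      aois <- trial_aois(cfg, tk$task, j)
      ov <- .aoi_overlaps(aois)
      if (!is.null(ov)) {
        stop(sprintf("task config error: AOIs %s and %s overlap in %s trial %d",
                     ov[1], ov[2], tk$task, j), call. = FALSE)
      }
    }
  }
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  for (tk in x$tasks) {
    segs <- unlist(tk$segments_ms)
    cat(sprintf("  %-5s %d trials, segments %s ms\n", tk$task,
                length(tk$trials), paste(segs, collapse = "/")))
  }
  invisible(x)
}

.rects_tbl <- function(names, rects) {
  m <- do.call(rbind, rects)
  tibble::new_tibble(
    list(aoi = names, x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4]),
    nrow = length(names)
  )
}

.aoi_overlaps <- function(aois) {
  n <- nrow(aois)
  if (n < 2) return(NULL)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (aois$x0[i] < aois$x1[j] && aois$x0[j] < aois$x1[i] &&
          aois$y0[i] < aois$y1[j] && aois$y0[j] < aois$y1[i]) {
        return(c(aois$aoi[i], aois$aoi[j]))
      }
    }
  }
  NULL
}

#' Resolve the AOI set of one trial
#'
#' Maps the configured rectangles onto the trial's roles: the face is
#' fixed; for RJA and IJA1 the cued/moving side is `target` and the
#' opposite object is `non_target`; for IJA2 the crossing-object region
#' is `target` and there is no non-target object on the scene.
#'
#' @param config A [load_task_config()] result.
#' @param task `"RJA"`, `"IJA1"` or `"IJA2"`.
#' @param trial Trial index within the task (1-based).
#' @return Tibble with columns `aoi, x0, y0, x1, y1`.
#' @export
trial_aois <- function(config, task, trial) {
  tk <- NULL
  for (t in config$tasks) if (t$task == task) tk <- t
  if (is.null(tk)) stop("task not in config: ", task, call. = FALSE)
  if (trial < 1 || trial > length(tk$trials)) {
    stop("trial index out of range for ", task, call. = FALSE)
  }
  side <- tk$trials[[trial]]$target_side
  a <- lapply(config$aois, unlist)
  if (side == "center") {
    .rects_tbl(c("face", "target"), list(a$face, a$moving_object))
  } else {
    tgt <- if (side == "left") a$object_left else a$object_right
    ntg <- if (side == "left") a$object_right else a$object_left
    .rects_tbl(c("face", "target", "non_target"), list(a$face, tgt, ntg))
  }
}

#' Segment durations of a task
#' @inheritParams trial_aois
#' @return Named numeric vector `looking_down, interaction, ja` in ms.
#' @export
task_segments <- function(config, task) {
  for (t in config$tasks) {
    if (t$task == task) {
      return(unlist(t$segments_ms)[c("looking_down", "interaction", "ja")])
    }
  }
  stop("task not in config: ", task, call. = FALSE)
}

#' Number of trials configured per task
#' @inheritParams trial_aois
#' @export
task_n_trials <- function(config, task) {
  for (t in config$tasks) if (t$task == task) return(length(t$trials))
  stop("task not in config: ", task, call. = FALSE)
}

#' Block order of the configured tasks
#' @param config A [load_task_config()] result.
#' @export
task_order <- function(config) {
  vapply(config$tasks, function(t) t$task, character(1))
}
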