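#' Gaze recordings
#'
#' A `gaze_recording` couples a participant's raw gaze samples (a tibble)
#' with the screen geometry and the participant-level metadata the
#' statistical layer needs (group label and developmental covariate).
#'
#' The sample table has one row per 120 Hz sample:
#' \describe{
#'   \item{t_ms}{time since recording start, strictly increasing}
#'   \item{x_px, y_px}{gaze point in screen pixels (origin top-left,
#'     x rightward, y downward); `NA` for invalid samples}
#'   \item{valid_l, valid_r}{per-eye validity flags}
#'   \item{valid}{overall validity: at least one eye valid and finite
#'     coordinates. Only valid samples ever reach event detection.}
#' }
#'
#' @param samples Tibble with columns `t_ms, x_px, y_px, valid_l, valid_r`.
#' @param geometry A [screen_geometry()].
#' @param participant_id Opaque identifier.
#' @param group `"ASD"`, `"TD"` or `NA`.
#' @param covariate Nonverbal developmental score (dimensionless), used as
#'   the covariate in all group comparisons.
#' @param sample_rate_hz Nominal sampling rate.
#' @return A `gaze_recording` object.
#' @export
gaze_recording <- function(samples, geometry = screen_geometry(),
                           participant_id = "p1", group = NA_character_,
                           covariate = NA_real_, sample_rate_hz = 120) {
  samples <- tibble::as_tibble(samples)
  req <- c("t_ms", "x_px", "y_px", "valid_l", "valid_r")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0) {
    stop("samples is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) < 1) stop("a recording needs at least one sample", call. = FALSE)
  if (any(samples$t_ms < 0, na.rm = TRUE)) {
    stop("t_ms must be non-negative", call. = FALSE)
  }
  dt <- diff(samples$t_ms)
  if (length(dt) > 0 && any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    stop(sprintf("timestamps not strictly increasing at sample row %d", bad),
         call. = FALSE)
  }
  samples$valid <- (samples$valid_l | samples$valid_r) &
    is.finite(samples$x_px) & is.finite(samples$y_px)
  structure(
    list(
      participant_id = participant_id,
      group = group,
      covariate = covariate,
      samples = samples,
      geometry = geometry,
      sample_rate_hz = sample_rate_hz
    ),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf(
    "<gaze_recording> %s (%s), %d samples (%.1f s), %.1f%% valid\n",
    x$participant_id, ifelse(is.na(x$group), "group ?", x$group),
    nrow(x$samples), diff(range(x$samples$t_ms)) / 1000,
    100 * mean(x$samples$valid)
  ))
  invisible(x)
}

#' Read a gaze log in the canonical CSV dialect
#'
#' The canonical dialect is comma-separated UTF-8 with header
#' `t_ms,x_px,y_px,valid_l,valid_r`. Invalid samples may carry `NA`
#' coordinates. Malformed rows (unparseable numbers, missing timestamp)
#' are dropped with a warning naming the data row numbers;
#' non-monotone timestamps are an error naming the first offending row.
#'
#' @param path Path to the CSV file.
#' @param geometry A [screen_geometry()].
#' @inheritParams gaze_recording
#' @return A [gaze_recording()].
#' @seealso [write_gaze_csv()] for the exact inverse, [read_smi_txt()] for
#'   the tab-separated vendor-style export.
#' @export
read_gaze_csv <- function(path, geometry = screen_geometry(),
                          participant_id = NULL, group = NA_character_,
                          covariate = NA_real_) {
  if (!file.exists(path)) stop("gaze file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  req <- c("t_ms", "x_px", "y_px", "valid_l", "valid_r")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("gaze CSV format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(v) suppressWarnings(as.numeric(ifelse(v == "NA" | v == "", NA, v)))
  t_ms <- parse_num(raw$t_ms)
  x_px <- parse_num(raw$x_px)
  y_px <- parse_num(raw$y_px)
  vl <- raw$valid_l %in% c("1", "TRUE", "true")
  vr <- raw$valid_r %in% c("1", "TRUE", "true")
  vl_ok <- raw$valid_l %in% c("0", "1", "TRUE", "FALSE", "true", "false")
  vr_ok <- raw$valid_r %in% c("0", "1", "TRUE", "FALSE", "true", "false")
  malformed <- !is.finite(t_ms) | !vl_ok | !vr_ok
  if (any(malformed)) {
    warning("dropping malformed gaze row(s): ",
            paste(which(malformed), collapse = ", "), call. = FALSE)
  }
  keep <- !malformed
  samples <- tibble::tibble(
    t_ms = t_ms[keep], x_px = x_px[keep], y_px = y_px[keep],
    valid_l = vl[keep], valid_r = vr[keep]
  )
  if (nrow(samples) == 0) stop("gaze data error: no well-formed rows in ", path,
                               call. = FALSE)
  dt <- diff(samples$t_ms)
  if (length(dt) > 0 && any(dt <= 0)) {
    bad <- which(keep)[which(dt <= 0)[1] + 1L]
    stop(sprintf("gaze data error: non-monotone timestamp at row %d of %s",
                 bad, path), call. = FALSE)
  }
  if (is.null(participant_id)) {
    participant_id <- sub("\\.csv$", "", basename(path))
  }
  gaze_recording(samples, geometry,
                 participant_id = participant_id,
                 group = group, covariate = covariate)
}

#' Write a gaze log in the canonical CSV dialect
#'
#' Formats are fixed (`t_ms` with 4 decimals, coordinates with 2, validity
#' flags as 0/1) so that write -> read -> write round trips are
#' byte-identical, which the reporting layer relies on for determinism
#' checks.
#'
#' @param rec A [gaze_recording()] or a sample tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(rec, path) {
  samples <- if (inherits(rec, "gaze_recording")) rec$samples else tibble::as_tibble(rec)
  fmt <- function(v, digits) ifelse(is.na(v), "NA", sprintf(paste0("%.", digits, "f"), v))
  lines <- c(
    "t_ms,x_px,y_px,valid_l,valid_r",
    paste(
      fmt(samples$t_ms, 4), fmt(samples$x_px, 2), fmt(samples$y_px, 2),
      as.integer(samples$valid_l), as.integer(samples$valid_r),
      sep = ","
    )
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a tab-separated SMI-style raw export
#'
#' Maps a minimal tab-separated vendor-style export (columns `Time` in
#' microseconds, `L POR X [px]`, `L POR Y [px]`, `R POR X [px]`,
#' `R POR Y [px]`, `L Validity`, `R Validity`) onto the canonical dialect.
#' Binocular combination: average the two eyes when both are valid, use
#' the valid eye when only one is, mark the sample invalid otherwise.
#'
#' @inheritParams read_gaze_csv
#' @return A [gaze_recording()].
#' @export
read_smi_txt <- function(path, geometry = screen_geometry(),
                         participant_id = NULL, group = NA_character_,
                         covariate = NA_real_) {
  if (!file.exists(path)) stop("gaze file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, check.names = FALSE)
  req <- c("Time", "L POR X [px]", "L POR Y [px]", "R POR X [px]",
           "R POR Y [px]", "L Validity", "R Validity")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("SMI export format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  t_ms <- (raw$Time - raw$Time[1]) / 1000 # microseconds -> ms from start
  vl <- raw$`L Validity` == 1
  vr <- raw$`R Validity` == 1
  x <- ifelse(vl & vr, (raw$`L POR X [px]` + raw$`R POR X [px]`) / 2,
              ifelse(vl, raw$`L POR X [px]`,
                     ifelse(vr, raw$`R POR X [px]`, NA_real_)))
  y <- ifelse(vl & vr, (raw$`L POR Y [px]` + raw$`R POR Y [px]`) / 2,
              ifelse(vl, raw$`L POR Y [px]`,
                     ifelse(vr, raw$`R POR Y [px]`, NA_real_)))
  samples <- tibble::tibble(t_ms = t_ms, x_px = x, y_px = y,
                            valid_l = vl, valid_r = vr)
  if (is.null(participant_id)) participant_id <- sub("\\.[^.]*$", "", basename(path))
  gaze_recording(samples, geometry, participant_id = participant_id,
                 group = group, covariate = covariate)
}

#' Read a participant metadata table
#'
#' Expects columns `participant_id, group, covariate`; `group` must be
#' ASD or TD; `covariate` is the nonverbal developmental score entering
#' every group comparison.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_participant_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  meta <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("participant_id", "group", "covariate")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(meta$group %in% c("ASD", "TD"))) {
    stop("metadata error: group must be ASD or TD", call. = FALSE)
  }
  if (any(!is.finite(meta$covariate))) {
    stop("metadata error: covariate must be finite", call. = FALSE)
  }
  meta$participant_id <- as.character(meta$participant_id)
  meta
}

#' Calibration accuracy as root-mean-square deviation
#'
#' Pools the x and y deviation components of every calibration point and
#' takes the root mean square over all components. The pass criterion is
#' the usual re-run rule: every individual component must deviate by less
#' than 2 degrees.
#'
#' @param deviations A data frame (or tibble) with columns `dx_deg` and
#'   `dy_deg`, one row per calibration point, in degrees of visual angle.
#' @param criterion_deg Per-component pass threshold, degrees.
#' @return A one-row tibble with columns `rms_deg`, `max_component_deg`,
#'   `n_points`, `pass`.
#' @examples
#' compute_calibration_rms(data.frame(dx_deg = c(1, 1), dy_deg = c(1, 1)))
#' @export
compute_calibration_rms <- function(deviations, criterion_deg = 2) {
  deviations <- tibble::as_tibble(deviations)
  if (!all(c("dx_deg", "dy_deg") %in% names(deviations))) {
    stop("deviations needs columns dx_deg and dy_deg", call. = FALSE)
  }
  if (nrow(deviations) < 1) {
    stop("at least one calibration deviation pair is required", call. = FALSE)
  }
  comp <- c(deviations$dx_deg, deviations$dy_deg)
  if (any(!is.finite(comp))) stop("deviations must be finite", call. = FALSE)
  tibble::tibble(
    rms_deg = sqrt(mean(comp^2)),
    max_component_deg = max(abs(comp)),
    n_points = nrow(deviations),
    pass = max(abs(comp)) < criterion_deg
  )
}
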