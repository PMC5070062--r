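#' Detect fixations with a dispersion-threshold (I-DT) algorithm
#'
#' Scans the valid samples left to right and emits maximal windows whose
#' bounding-box dispersion (width plus height, in degrees of visual
#' angle) stays at or below `dispersion_max_deg` and whose duration is at
#' least `min_duration_ms`. The 60 ms default duration threshold removes
#' very short, "unconscious" looks before any AOI analysis. Invalid
#' spans (blinks, tracking loss) of up to `max_gap_ms` inside a window
#' are bridged; longer ones terminate it.
#'
#' Windows are grown greedily: dispersion is monotone in the window end,
#' so the maximal extension from a given start is well defined. When a
#' window cannot reach the minimum duration the start advances by one
#' sample. Fixations never overlap and are returned in time order.
#'
#' @param samples A [gaze_recording()] or a sample tibble (columns
#'   `t_ms, x_px, y_px` and `valid`, or `valid_l`/`valid_r`).
#' @param geometry A [screen_geometry()]; taken from the recording when
#'   one is supplied.
#' @param dispersion_max_deg Dispersion ceiling in degrees. The default
#'   1.0 matches the nominal accuracy of remote infant eye trackers.
#' @param min_duration_ms Minimum fixation duration, ms.
#' @param max_gap_ms Longest invalid span bridged inside a fixation, ms.
#' @return Tibble with one row per fixation: `onset_ms, offset_ms,
#'   duration_ms, cx_px, cy_px, n_samples`.
#' @examples
#' geom <- screen_geometry()
#' s <- tibble::tibble(
#'   t_ms = seq(0, by = 1000 / 120, length.out = 24),
#'   x_px = 500, y_px = 400, valid_l = TRUE, valid_r = TRUE
#' )
#' detect_fixations(s, geom)
#' @export
detect_fixations <- function(samples, geometry = screen_geometry(),
                             dispersion_max_deg = 1.0,
                             min_duration_ms = 60,
                             max_gap_ms = 75) {
  if (inherits(samples, "gaze_recording")) {
    geometry <- samples$geometry
    samples <- samples$samples
  }
  samples <- tibble::as_tibble(samples)
  if (!"valid" %in% names(samples)) {
    samples$valid <- (samples$valid_l | samples$valid_r) &
      is.finite(samples$x_px) & is.finite(samples$y_px)
  }
  v <- samples[samples$valid & is.finite(samples$x_px) & is.finite(samples$y_px), ]
  empty <- tibble::tibble(
    onset_ms = numeric(), offset_ms = numeric(), duration_ms = numeric(),
    cx_px = numeric(), cy_px = numeric(), n_samples = integer()
  )
  if (nrow(v) == 0) return(empty)
  t <- v$t_ms; x <- v$x_px; y <- v$y_px
  run <- cumsum(c(1, as.integer(diff(t) > max_gap_ms)))
  res <- lapply(split(seq_along(t), run), function(idx) {
    .idt_run(t[idx], x[idx], y[idx], geometry, dispersion_max_deg, min_duration_ms)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) empty else out
}

# Greedy maximal-window scan of one gap-free run of valid samples.
# Extension uses cummax/cummin over a geometrically growing lookahead so
# the amortised cost stays linear in the run length.
.idt_run <- function(t, x, y, geometry, disp_max, min_dur) {
  n <- length(t)
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i <= n) {
    hor <- min(n, i + 299L)
    j <- i - 1L
    repeat {
      seg <- i:hor
      w <- cummax(x[seg]) - cummin(x[seg])
      h <- cummax(y[seg]) - cummin(y[seg])
      disp <- px_to_deg(w, geometry) + px_to_deg(h, geometry)
      bad <- which(disp > disp_max)
      if (length(bad) > 0) { j <- i + bad[1] - 2L; break }
      if (hor == n) { j <- n; break }
      hor <- min(n, i + (hor - i + 1L) * 2L)
    }
    if (j >= i && t[j] - t[i] >= min_dur) {
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(starts) == 0) {
    return(tibble::tibble(
      onset_ms = numeric(), offset_ms = numeric(), duration_ms = numeric(),
      cx_px = numeric(), cy_px = numeric(), n_samples = integer()
    ))
  }
  tibble::tibble(
    onset_ms = t[starts],
    offset_ms = t[ends],
    duration_ms = t[ends] - t[starts],
    cx_px = vapply(seq_along(starts), function(k) mean(x[starts[k]:ends[k]]), numeric(1)),
    cy_px = vapply(seq_along(starts), function(k) mean(y[starts[k]:ends[k]]), numeric(1)),
    n_samples = ends - starts + 1L
  )
}

#' Label fixations with the AOI containing their centroid
#'
#' Containment uses half-open rectangles: `x0 <= cx < x1` and
#' `y0 <= cy < y1`, so a centroid exactly on a shared right/bottom edge
#' belongs to the neighbouring region, never to both. Fixations outside
#' every AOI get the label `"none"`.
#'
#' @param fixations Tibble from [detect_fixations()].
#' @param aois Tibble with columns `aoi, x0, y0, x1, y1` (see
#'   [trial_aois()]); rectangles must not overlap.
#' @return `fixations` with an `aoi` column added (or replaced).
#' @export
assign_aoi <- function(fixations, aois) {
  ov <- .aoi_overlaps(aois)
  if (!is.null(ov)) {
    stop(sprintf("AOI config error: %s and %s overlap", ov[1], ov[2]),
         call. = FALSE)
  }
  lab <- rep("none", nrow(fixations))
  for (k in seq_len(nrow(aois))) {
    inside <- fixations$cx_px >= aois$x0[k] & fixations$cx_px < aois$x1[k] &
      fixations$cy_px >= aois$y0[k] & fixations$cy_px < aois$y1[k]
    lab[inside] <- aois$aoi[k]
  }
  fixations$aoi <- lab
  fixations
}

#' Extract ordered AOI-to-AOI transitions
#'
#' Walks the AOI-labelled fixations in time order, ignoring fixations
#' labelled `"none"` (gaze travelling across empty screen between regions
#' does not break a transition), and emits one transition for every
#' consecutive pair of retained fixations with differing AOI.
#' Consecutive same-AOI fixations emit nothing.
#'
#' @param fixations AOI-labelled fixation tibble (see [assign_aoi()]).
#' @return Tibble `from_aoi, to_aoi, t_ms` where `t_ms` is the onset of
#'   the destination fixation.
#' @export
extract_transitions <- function(fixations) {
  aoi <- fixations$aoi
  onset <- fixations$onset_ms
  if (is.null(aoi)) { aoi <- character(0); onset <- numeric(0) }
  if (is.unsorted(onset)) {
    ord <- order(onset); aoi <- aoi[ord]; onset <- onset[ord]
  }
  real <- !is.na(aoi) & aoi != "none"
  aoi <- aoi[real]; onset <- onset[real]
  n <- length(aoi)
  keep <- if (n < 2) logical(0) else aoi[-1] != aoi[-n]
  tibble::new_tibble(
    list(
      from_aoi = if (n < 2) character(0) else aoi[-n][keep],
      to_aoi = if (n < 2) character(0) else aoi[-1][keep],
      t_ms = if (n < 2) numeric(0) else onset[-1][keep]
    ),
    nrow = sum(keep)
  )
}

#' First object look of a joint-attention segment
#'
#' Returns the AOI of the first fixation (in time) landing on the target
#' or non-target object. Face fixations before it are ignored: the face
#' is the interaction anchor, not an object. `"neither"` when no object
#' fixation exists; such trials drop out of accuracy denominators.
#'
#' @param fixations AOI-labelled fixations of one JA segment.
#' @return `"target"`, `"non_target"` or `"neither"`.
#' @export
first_look <- function(fixations) {
  if (nrow(fixations) == 0) return("neither")
  f <- fixations[order(fixations$onset_ms), ]
  obj <- f$aoi[f$aoi %in% c("target", "non_target")]
  if (length(obj) == 0) "neither" else obj[1]
}
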