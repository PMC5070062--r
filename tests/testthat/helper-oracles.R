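# Independent oracles and fixture builders shared across the suite.
# Oracles re-derive expected results from the definitions by explicit
# enumeration; they never call the package's optimised code paths.

SAMPLE_DT <- 1000 / 120

# Exhaustive maximal-window fixation search. For every window start it
# enumerates all candidate ends, checking the dispersion ceiling
# (bounding-box width + height, degrees), the bridgeable-gap limit and
# the duration threshold from scratch on the raw slice.
oracle_fixations <- function(samples, geometry,
                             disp_max = 1.0, min_dur = 60, max_gap = 75) {
  s <- tibble::as_tibble(samples)
  if (!"valid" %in% names(s)) {
    s$valid <- (s$valid_l | s$valid_r) & is.finite(s$x_px) & is.finite(s$y_px)
  }
  s <- s[s$valid & is.finite(s$x_px) & is.finite(s$y_px), ]
  t <- s$t_ms; x <- s$x_px; y <- s$y_px
  n <- length(t)
  rows <- list()
  i <- 1
  while (i <= n) {
    ok <- logical(n)
    for (j in i:n) {
      seg <- i:j
      gaps_ok <- j == i || all(diff(t[seg]) <= max_gap)
      disp <- px_to_deg(max(x[seg]) - min(x[seg]), geometry) +
        px_to_deg(max(y[seg]) - min(y[seg]), geometry)
      ok[j] <- gaps_ok && disp <= disp_max
    }
    j <- if (any(ok)) max(which(ok)) else i - 1L
    if (j >= i && t[j] - t[i] >= min_dur) {
      rows[[length(rows) + 1]] <- data.frame(
        onset_ms = t[i], offset_ms = t[j],
        cx_px = mean(x[i:j]), cy_px = mean(y[i:j]),
        n_samples = j - i + 1L
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(rows) == 0) {
    data.frame(onset_ms = numeric(), offset_ms = numeric(),
               cx_px = numeric(), cy_px = numeric(), n_samples = integer())
  } else {
    do.call(rbind, rows)
  }
}

# Hand-trace transition oracle over an AOI label sequence:
# drop the "none" labels, then walk consecutive pairs.
oracle_transitions <- function(aoi_seq) {
  real <- aoi_seq[aoi_seq != "none" & !is.na(aoi_seq)]
  from <- character(0); to <- character(0)
  if (length(real) >= 2) {
    for (k in 2:length(real)) {
      if (real[k] != real[k - 1]) {
        from <- c(from, real[k - 1]); to <- c(to, real[k])
      }
    }
  }
  data.frame(from_aoi = from, to_aoi = to)
}

# Literal Benjamini-Hochberg step-up: largest k with p_(k) <= k q / m.
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  ks <- which(p[ord] <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ks) > 0) rej[ord[seq_len(max(ks))]] <- TRUE
  rej
}

# OLS through the normal equations (independent of lm) for the ANCOVA
# cross-checks: returns the residual sum of squares.
oracle_rss <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% beta)^2)
}

# Build a 120 Hz sample stream from a dwell specification
# (data.frame x, y, dur_ms, valid).
dwell_stream <- function(spec, t0 = 0) {
  chunks <- list()
  t <- t0
  for (i in seq_len(nrow(spec))) {
    n <- round(spec$dur_ms[i] / SAMPLE_DT)
    tt <- t + (seq_len(n) - 1) * SAMPLE_DT
    chunks[[i]] <- tibble::tibble(
      t_ms = tt,
      x_px = if (spec$valid[i]) rep(spec$x[i], n) else NA_real_,
      y_px = if (spec$valid[i]) rep(spec$y[i], n) else NA_real_,
      valid_l = spec$valid[i], valid_r = spec$valid[i]
    )
    t <- t + spec$dur_ms[i]
  }
  dplyr::bind_rows(chunks)
}

# Small AOI set used by the event-layer tests: face top-centre, two
# objects left/right, all comfortably separated.
toy_aois <- function() {
  tibble::tibble(
    aoi = c("face", "target", "non_target"),
    x0 = c(700, 100, 1300), y0 = c(100, 600, 600),
    x1 = c(900, 400, 1600), y1 = c(300, 850, 850)
  )
}

aoi_center <- function(aois, name) {
  r <- aois[aois$aoi == name, ]
  c(x = (r$x0 + r$x1) / 2, y = (r$y0 + r$y1) / 2)
}

# Random gaze stream mixing stationary clusters, drifting noise and
# invalid gaps, for the fixation oracle comparison.
random_stream <- function(n, geometry) {
  t <- cumsum(c(0, sample(c(rep(SAMPLE_DT, 8), 30, 90, 200), n - 1, replace = TRUE)))
  x <- numeric(n); y <- numeric(n)
  mode_len <- 0; cx <- 0; cy <- 0; spread <- 0
  for (k in seq_len(n)) {
    if (mode_len == 0) {
      mode_len <- sample(3:25, 1)
      cx <- runif(1, 0, geometry$width_px)
      cy <- runif(1, 0, geometry$height_px)
      spread <- sample(c(1, 4, 40), 1)
    }
    x[k] <- cx + rnorm(1, 0, spread)
    y[k] <- cy + rnorm(1, 0, spread)
    mode_len <- mode_len - 1
  }
  valid <- runif(n) > 0.08
  tibble::tibble(t_ms = t, x_px = x, y_px = y,
                 valid_l = valid, valid_r = valid)
}
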