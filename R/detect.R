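#' Detector configuration
#'
#' Parameters of the preprocessing and gradient-steepness R-peak
#' detector. Preprocessing is a zero-phase 5th-order 0.5 Hz high-pass
#' Butterworth filter followed by a zero-phase powerline notch. QRS
#' complexes are then located by the steepness of the smoothed absolute
#' gradient, and R-peaks taken as the local extrema within those regions.
#'
#' @param highpass_cutoff_hz High-pass design cutoff in Hz (default 0.5).
#' @param highpass_order Butterworth order (default 5).
#' @param powerline_hz Powerline notch frequency in Hz (default 50;
#'   set 60 for North American data).
#' @param min_rr_ms Refractory period between accepted QRS regions in ms
#'   (default 200).
#' @param gradient_smooth_ms Moving-average window for the
#'   absolute-gradient envelope in ms (default 100).
#' @param signal_smooth_ms Mild moving-average applied to the cleaned
#'   signal before the gradient is taken, in ms (default 10); suppresses
#'   wideband noise in the gradient without blunting the QRS.
#' @param qrs_threshold_frac Fraction of the envelope's running amplitude
#'   (above its running mean) used to gate QRS regions (default 0.1).
#' @param amplitude_window_ms Window of the running mean/max envelope
#'   statistics in ms (default 1500; spans at least one beat down to
#'   40 bpm).
#' @param min_region_ms Minimum QRS region duration in ms (default 10).
#' @param edge_ms QRS regions touching the first or last `edge_ms` of the
#'   record are dropped (default 100): incomplete cycles cannot be
#'   resampled reliably.
#' @param refine_ms Half-width of the raw-signal refinement window around
#'   the cleaned-signal extremum, ms (default 20).
#' @return Object of class `detector_config`.
#' @export
detector_config <- function(highpass_cutoff_hz = 0.5, highpass_order = 5,
                            powerline_hz = 50, min_rr_ms = 200,
                            gradient_smooth_ms = 100, signal_smooth_ms = 10,
                            qrs_threshold_frac = 0.1,
                            amplitude_window_ms = 1500, min_region_ms = 10,
                            edge_ms = 100, refine_ms = 20) {
  vals <- c(highpass_cutoff_hz, highpass_order, powerline_hz, min_rr_ms,
            gradient_smooth_ms, qrs_threshold_frac, amplitude_window_ms,
            min_region_ms, edge_ms, refine_ms)
  if (any(vals <= 0) || signal_smooth_ms < 0)
    stop("detector_config parameters must be positive")
  structure(list(highpass_cutoff_hz = highpass_cutoff_hz,
                 highpass_order = as.integer(highpass_order),
                 powerline_hz = powerline_hz, min_rr_ms = min_rr_ms,
                 gradient_smooth_ms = gradient_smooth_ms,
                 signal_smooth_ms = signal_smooth_ms,
                 qrs_threshold_frac = qrs_threshold_frac,
                 amplitude_window_ms = amplitude_window_ms,
                 min_region_ms = min_region_ms, edge_ms = edge_ms,
                 refine_ms = refine_ms),
            class = "detector_config")
}

## ---- zero-phase filtering --------------------------------------------------

# One forward pass of an IIR filter started from the steady state of a
# constant input x0 (removes the step transient at the boundary).
lfilter_ss <- function(b, a, x, x0) {
  y0 <- x0 * sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x0, length(b) - 1L),
                            init.y = rep(y0, length(a) - 1L)))
}

# Zero-phase (forward-backward) filtering with odd-extension padding and
# steady-state initial conditions, so that fiducial positions are not
# lagged and edge transients stay out of the analysed span.
zerophase_filter <- function(b, a, x, pad = 500L) {
  n <- length(x)
  pad <- min(as.integer(pad), n - 1L)
  if (pad < 1L) stop("series too short for zero-phase filtering")
  ext <- c(2 * x[1] - x[(pad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- lfilter_ss(b, a, ext, ext[1])
  y <- rev(lfilter_ss(b, a, rev(y), y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

#' Clean a single-lead ECG series
#'
#' Zero-phase high-pass (removes baseline wander and DC) followed by a
#' zero-phase second-order Butterworth band-stop of +/- 1 Hz around the
#' powerline frequency. Output length equals input length.
#'
#' @param series Numeric vector (one lead).
#' @param fs Sampling rate in Hz.
#' @param config A [detector_config()].
#' @return Numeric vector of the same length.
#' @export
clean_signal <- function(series, fs, config = detector_config()) {
  if (fs <= 2 * config$highpass_cutoff_hz)
    stop("fs must exceed twice the high-pass cutoff")
  minlen <- 6L * (config$highpass_order + 1L)
  if (length(series) < minlen)
    stop(sprintf("series too short to filter (%d < %d samples)",
                 length(series), minlen))
  hp <- signal::butter(config$highpass_order,
                       config$highpass_cutoff_hz / (fs / 2), type = "high")
  pad <- min(length(series) - 1L, max(500L, round(3 * fs / config$highpass_cutoff_hz / 10)))
  y <- zerophase_filter(hp$b, hp$a, series, pad = pad)
  if (config$powerline_hz < fs / 2 - 1) {
    bs <- signal::butter(2, c(config$powerline_hz - 1, config$powerline_hz + 1) / (fs / 2),
                         type = "stop")
    y <- zerophase_filter(bs$b, bs$a, y, pad = pad)
  }
  y
}

## ---- gradient envelope ------------------------------------------------------

moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - 1L - (w %/% 2L))
  hi <- pmin(n, seq_len(n) - 1L + ((w + 1L) %/% 2L))
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

rolling_max <- function(x, w) {
  w <- max(1L, as.integer(w))
  n <- length(x)
  half <- w %/% 2L
  vapply(seq_len(n), function(i)
    max(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

gradient_envelope <- function(series, fs, config) {
  s <- if (config$signal_smooth_ms > 0)
    moving_average(series, round(config$signal_smooth_ms * fs / 1000))
  else series
  n <- length(s)
  g <- numeric(n)
  g[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / 2
  g[1] <- s[2] - s[1]; g[n] <- s[n] - s[n - 1]
  moving_average(abs(g), round(config$gradient_smooth_ms * fs / 1000))
}

## ---- QRS regions and peaks --------------------------------------------------

#' Locate QRS regions by gradient steepness
#'
#' Computes the smoothed absolute-gradient envelope of the (cleaned)
#' series and gates regions where it exceeds an adaptive threshold —
#' the running envelope mean plus `qrs_threshold_frac` of the running
#' envelope amplitude. Overlapping candidates closer than the refractory
#' period keep only the steepest region, so returned intervals are
#' disjoint, sorted, and separated by at least `min_rr_ms`.
#'
#' @param series Cleaned single-lead series.
#' @param fs Sampling rate in Hz.
#' @param config A [detector_config()].
#' @return List of half-open 0-based intervals `c(start, stop)`; possibly
#'   empty.
#' @export
qrs_regions <- function(series, fs, config = detector_config()) {
  n <- length(series)
  env <- gradient_envelope(series, fs, config)
  w_amp <- round(config$amplitude_window_ms * fs / 1000)
  run_mean <- moving_average(env, w_amp)
  run_max <- rolling_max(env, w_amp)
  thr <- run_mean + config$qrs_threshold_frac * (run_max - run_mean)
  above <- env > thr & run_max > 0
  if (!any(above)) return(list())
  r <- rle(above)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; stops <- stops[keep]  # 1-based inclusive
  min_len <- round(config$min_region_ms * fs / 1000)
  ok <- (stops - starts + 1L) >= min_len
  starts <- starts[ok]; stops <- stops[ok]
  if (!length(starts)) return(list())
  # edge policy: drop regions touching the first/last edge_ms
  edge <- round(config$edge_ms * fs / 1000)
  ok <- starts > edge & stops <= n - edge
  starts <- starts[ok]; stops <- stops[ok]
  if (!length(starts)) return(list())
  # refractory suppression: keep the steepest region among conflicts
  score <- vapply(seq_along(starts), function(i)
    max(env[starts[i]:stops[i]]), numeric(1))
  centre <- vapply(seq_along(starts), function(i)
    starts[i] - 1L + which.max(env[starts[i]:stops[i]]), numeric(1))
  min_rr <- config$min_rr_ms * fs / 1000
  ord <- order(score, decreasing = TRUE)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(centre[i] - centre[accepted]) >= min_rr))
      accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  lapply(accepted, function(i) c(starts[i] - 1L, stops[i]))  # 0-based half-open
}

#' Detect R-peaks on a reference lead
#'
#' Cleans the configured lead, gates QRS regions by gradient steepness,
#' and takes one R-peak per region at the extremum of largest magnitude
#' of the cleaned signal (robust to inverted QRS polarity), refined to
#' the largest-magnitude extremum of the raw signal within
#' `+/- refine_ms`.
#'
#' @param record An [ecg_record()].
#' @param lead Lead name or 0-based index; default `"II"`.
#' @param config A [detector_config()].
#' @return Object of class `rpeak_set` with fields `indices` (0-based,
#'   strictly increasing), `fs`, and `mean_hr_bpm`
#'   (`60 * fs / mean(diff(indices))`).
#' @export
detect_rpeaks <- function(record, lead = "II", config = detector_config()) {
  stopifnot(inherits(record, "ecg_record"))
  raw <- slice_lead(record, lead)
  fs <- record$fs
  cleaned <- clean_signal(as.numeric(raw), fs, config)
  regions <- qrs_regions(cleaned, fs, config)
  refine <- round(config$refine_ms * fs / 1000)
  n <- length(cleaned)
  peaks <- vapply(regions, function(iv) {
    i0 <- iv[1] + 1L; i1 <- iv[2]          # 1-based inclusive span
    p <- i0 - 1L + which.max(abs(cleaned[i0:i1]))
    lo <- max(1L, p - refine); hi <- min(n, p + refine)
    lo - 1L + which.max(abs(raw[lo:hi]))
  }, numeric(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) >= 2L) {
    min_rr <- config$min_rr_ms * fs / 1000
    peaks <- peaks[c(TRUE, diff(peaks) >= min_rr)]
  }
  if (length(peaks) < 2L)
    stop(structure(class = c("alignment_infeasible", "error", "condition"),
                   list(message = sprintf(
                     "alignment infeasible: %d R-peak(s) detected (need >= 2 for an RR estimate)",
                     length(peaks)), call = sys.call(-1),
                     n_peaks = length(peaks))))
  rpeak_set(as.integer(peaks - 1L), fs)
}

#' Construct an R-peak set
#'
#' @param indices Strictly increasing 0-based sample indices.
#' @param fs Sampling rate in Hz.
#' @return Object of class `rpeak_set`.
#' @export
rpeak_set <- function(indices, fs) {
  indices <- as.integer(indices)
  if (length(indices) >= 2L && any(diff(indices) <= 0L))
    stop("R-peak indices must be strictly increasing")
  mean_hr <- if (length(indices) >= 2L) 60 * fs / mean(diff(indices)) else NA_real_
  structure(list(indices = indices, fs = fs, mean_hr_bpm = mean_hr),
            class = "rpeak_set")
}

#' @export
print.rpeak_set <- function(x, ...) {
  cat(sprintf("<rpeak_set> %d peaks @ %g Hz, mean hr %.1f bpm\n",
              length(x$indices), x$fs, x$mean_hr_bpm))
  invisible(x)
}
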