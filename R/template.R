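#' Heart-rate-corrected interval model
#'
#' Constants of the two linear, heart-rate-dependent interval estimates
#' used by the hrc alignment strategy, together with the fixed
#' (rate-independent) QRS window around the R-peak.
#'
#' The interval from P-onset to QRS-onset is modelled in milliseconds as
#' `pr_slope * hr + pr_intercept` (shortening as heart rate rises), and
#' the QRS-onset-to-T-offset interval as
#' `qt_intercept + qt_rr_coeff * RR_s` with `RR_s = 60/hr` seconds — a
#' standard linear QT-RR estimate. The QRS complex itself is represented
#' by a fixed window from `qrs_pre_ms` before to `qrs_post_ms` after the
#' R-peak and is never rescaled.
#'
#' @param pr_slope ms per bpm (default -0.351).
#' @param pr_intercept ms (default 176.7).
#' @param qrs_pre_ms Fixed window before the R-peak, ms (default 35).
#' @param qrs_post_ms Fixed window after the R-peak, ms (default 55).
#' @param qt_intercept ms (default 230).
#' @param qt_rr_coeff ms per second of RR interval (default 170).
#' @return Object of class `hrc_model`.
#' @export
hrc_model <- function(pr_slope = -0.351, pr_intercept = 176.7,
                      qrs_pre_ms = 35, qrs_post_ms = 55,
                      qt_intercept = 230, qt_rr_coeff = 170) {
  stopifnot(qrs_pre_ms > 0, qrs_post_ms > 0)
  structure(list(pr_slope = pr_slope, pr_intercept = pr_intercept,
                 qrs_pre_ms = qrs_pre_ms, qrs_post_ms = qrs_post_ms,
                 qt_intercept = qt_intercept, qt_rr_coeff = qt_rr_coeff),
            class = "hrc_model")
}

hr_range_supported <- c(30, 220)

#' hrc landmark distances from the R-peak
#'
#' Evaluates the heart-rate-dependent interval model at a given heart
#' rate, returning the four landmark distances (in samples, real-valued)
#' that delimit the hrc segments of one cardiac cycle:
#' P-onset and QRS-onset before the R-peak, QRS-offset and T-offset after
#' it. The two rate-dependent distances are computed as relative scale
#' factors of the RR interval,
#' `d_ponset = ((pr_slope*hr + pr_intercept + qrs_pre_ms) / rr_ms) * rr_samples`
#' and
#' `d_toffset = ((qt_intercept + qt_rr_coeff*(60/hr) - qrs_pre_ms) / rr_ms) * rr_samples`,
#' which algebraically reduce to `interval_ms * fs / 1000`; the fraction
#' form is kept because the scale-factor construction is how the model is
#' defined. The QRS window distances are rate-independent:
#' `qrs_pre_ms * fs / 1000` and `qrs_post_ms * fs / 1000`.
#'
#' @param hr_bpm Heart rate in bpm, within `[30, 220]`.
#' @param fs Sampling rate in Hz.
#' @param model An [hrc_model()].
#' @return List with elements `d_ponset`, `d_qrspre`, `d_qrspost`,
#'   `d_toffset` (samples, distances from the R-peak; the first two lie
#'   before it, the last two after it) plus `rr_samples`.
#' @export
hrc_landmarks <- function(hr_bpm, fs, model = hrc_model()) {
  if (!is.numeric(hr_bpm) || length(hr_bpm) != 1L ||
      hr_bpm < hr_range_supported[1] || hr_bpm > hr_range_supported[2])
    stop(sprintf("hr_bpm %.3g outside supported range [%g, %g]", hr_bpm,
                 hr_range_supported[1], hr_range_supported[2]))
  stopifnot(fs > 0)
  rr_ms <- 1000 * 60 / hr_bpm
  rr_samples <- fs * 60 / hr_bpm
  pre_window_ms <- model$pr_slope * hr_bpm + model$pr_intercept +
    model$qrs_pre_ms
  d_ponset <- (pre_window_ms / rr_ms) * rr_samples
  d_qrspre <- model$qrs_pre_ms * fs / 1000
  d_qrspost <- model$qrs_post_ms * fs / 1000
  rt_ms <- model$qt_intercept + model$qt_rr_coeff * (60 / hr_bpm) -
    model$qrs_pre_ms
  d_toffset <- (rt_ms / rr_ms) * rr_samples
  if (d_ponset <= d_qrspre)
    stop(sprintf("hr %.3g bpm unsupported for hrc: P-onset (%.1f samples) not before QRS onset (%.1f)",
                 hr_bpm, d_ponset, d_qrspre))
  if (d_toffset <= d_qrspost)
    stop(sprintf("hr %.3g bpm unsupported for hrc: T-offset (%.1f samples) not after QRS offset (%.1f)",
                 hr_bpm, d_toffset, d_qrspost))
  list(d_ponset = d_ponset, d_qrspre = d_qrspre, d_qrspost = d_qrspost,
       d_toffset = d_toffset, rr_samples = rr_samples)
}

round_half_up <- function(x) floor(x + 0.5)

#' Build an alignment template
#'
#' The template is the standardized target grid: it fixes where R-peaks
#' sit after alignment. It is defined by the recording duration, sampling
#' frequency, target heart rate, and an initial offset giving the
#' position of the first R-peak slot. Slot `k` sits at
#' `round(offset_s*fs + k*rr_samples)` with `rr_samples = fs*60/target_bpm`;
#' all slots below `duration_s*fs` are kept. Duration and sampling rate
#' must match the records transformed with the template.
#'
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param target_bpm Target heart rate in bpm, within `[30, 220]`.
#' @param offset_s Position of the first R-peak slot in seconds
#'   (`0 <= offset_s < duration_s`).
#' @return Object of class `ecg_template` with derived fields
#'   `rr_samples`, `rpeak_slots` (0-based), `n_beats`.
#' @export
build_template <- function(duration_s, fs, target_bpm = 60,
                           offset_s = 0.25) {
  stopifnot(duration_s > 0, fs > 0)
  if (target_bpm < hr_range_supported[1] || target_bpm > hr_range_supported[2])
    stop(sprintf("target_bpm %.3g outside supported range [%g, %g]",
                 target_bpm, hr_range_supported[1], hr_range_supported[2]))
  if (offset_s < 0 || offset_s >= duration_s)
    stop("offset_s must satisfy 0 <= offset_s < duration_s")
  n <- round(duration_s * fs)
  rr_samples <- fs * 60 / target_bpm
  k_max <- floor((n - 1 - offset_s * fs) / rr_samples)
  if (is.na(k_max) || k_max < 0)
    stop("no template beat fits the record; increase duration or offset")
  slots <- round_half_up(offset_s * fs + (0:k_max) * rr_samples)
  slots <- slots[slots < n]
  if (!length(slots)) stop("no template beat fits the record")
  structure(list(duration_s = duration_s, fs = fs, target_bpm = target_bpm,
                 offset_s = offset_s, rr_samples = rr_samples,
                 rpeak_slots = as.integer(slots),
                 n_beats = length(slots)),
            class = "ecg_template")
}

#' @export
print.ecg_template <- function(x, ...) {
  cat(sprintf("<ecg_template> %g s @ %g Hz, %g bpm, offset %g s: %d slots (rr = %g samples)\n",
              x$duration_s, x$fs, x$target_bpm, x$offset_s, x$n_beats,
              x$rr_samples))
  invisible(x)
}
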