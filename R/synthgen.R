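#' Beat morphology parameters
#'
#' The synthetic beat is a sum of five Gaussian bumps (P, Q, R, S, T),
#' each with an amplitude in millivolts, a centre offset from the R-peak
#' in milliseconds, and a width (Gaussian sigma) in milliseconds, plus a
#' per-lead amplitude scaling vector projecting the common waveform onto
#' the 12 leads.
#'
#' With `hr_coupling = TRUE` (the default) the P and T waves follow the
#' heart-rate-dependent interval model of [hrc_model()]: the P wave is
#' centred mid-way between the P-onset and QRS-onset landmarks and the
#' T wave mid-way between the QRS-offset and T-offset landmarks at the
#' record's heart rate, with widths proportional to the respective
#' segment lengths. This makes the hrc alignment exact on synthetic
#' ground truth: the same morphology generated at any two heart rates
#' maps onto the same template beat. With coupling off, the P/T
#' placement is frozen at its 60 bpm geometry regardless of the record's
#' rate.
#'
#' @param p_amp,q_amp,r_amp,s_amp,t_amp Wave amplitudes in mV.
#' @param q_center_ms,s_center_ms Q/S centre offsets from the R-peak, ms.
#' @param q_width_ms,r_width_ms,s_width_ms QRS wave sigmas, ms (kept
#'   narrow enough that the QRS stays inside the fixed 35/55 ms window).
#' @param p_frac,t_frac Relative position of the P/T centre within its
#'   landmark segment (0 = segment start, 1 = segment end).
#' @param p_width_frac,t_width_frac Wave sigma as a fraction of the
#'   landmark segment length.
#' @param lead_scale Numeric vector of per-lead amplitude factors.
#' @param hr_coupling Couple P/T placement to heart rate (default TRUE).
#' @param model The [hrc_model()] supplying the landmark geometry.
#' @return Object of class `beat_params`.
#' @export
beat_params <- function(p_amp = 0.15, q_amp = -0.1, r_amp = 1.0,
                        s_amp = -0.25, t_amp = 0.35,
                        q_center_ms = -22, s_center_ms = 28,
                        q_width_ms = 4, r_width_ms = 8, s_width_ms = 4,
                        p_frac = 0.5, t_frac = 0.5,
                        p_width_frac = 0.16, t_width_frac = 0.14,
                        lead_scale = c(0.6, 1.0, 0.5, -0.75, 0.2, 0.75,
                                       -0.4, 0.8, 1.1, 1.2, 1.0, 0.8),
                        hr_coupling = TRUE, model = hrc_model()) {
  stopifnot(q_width_ms > 0, r_width_ms > 0, s_width_ms > 0,
            p_width_frac > 0, t_width_frac > 0, r_amp != 0)
  if (abs(r_amp) <= max(abs(q_amp), abs(s_amp)))
    stop("R amplitude must dominate Q and S for detectability")
  structure(list(p_amp = p_amp, q_amp = q_amp, r_amp = r_amp,
                 s_amp = s_amp, t_amp = t_amp,
                 q_center_ms = q_center_ms, s_center_ms = s_center_ms,
                 q_width_ms = q_width_ms, r_width_ms = r_width_ms,
                 s_width_ms = s_width_ms,
                 p_frac = p_frac, t_frac = t_frac,
                 p_width_frac = p_width_frac, t_width_frac = t_width_frac,
                 lead_scale = lead_scale, hr_coupling = isTRUE(hr_coupling),
                 model = model),
            class = "beat_params")
}

#' Noise parameters
#'
#' Additive noise model: sinusoidal baseline wander, sinusoidal powerline
#' interference (random phases), and white Gaussian noise.
#'
#' @param baseline_mV Baseline wander amplitude in mV (default 0.05).
#' @param baseline_hz Baseline wander frequency in Hz (default 0.2).
#' @param powerline_mV Powerline amplitude in mV (default 0.02).
#' @param powerline_hz Powerline frequency in Hz (default 50).
#' @param white_mV White-noise standard deviation in mV (default 0.02).
#' @return Object of class `noise_params`.
#' @export
noise_params <- function(baseline_mV = 0.05, baseline_hz = 0.2,
                         powerline_mV = 0.02, powerline_hz = 50,
                         white_mV = 0.02) {
  amps <- c(baseline_mV, powerline_mV, white_mV)
  if (any(amps < 0)) stop("noise amplitudes must be >= 0")
  structure(list(baseline_mV = baseline_mV, baseline_hz = baseline_hz,
                 powerline_mV = powerline_mV, powerline_hz = powerline_hz,
                 white_mV = white_mV),
            class = "noise_params")
}

#' Silence
#' @return A [noise_params()] with all amplitudes zero.
#' @export
no_noise <- function() noise_params(0, 0.2, 0, 50, 0)

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# per-wave (amplitude mV, centre ms from R, sigma ms) table at a given hr
wave_table <- function(params, hr_bpm) {
  hr_eff <- if (params$hr_coupling) hr_bpm else 60
  lm_ms <- {
    m <- params$model
    pre <- m$pr_slope * hr_eff + m$pr_intercept + m$qrs_pre_ms
    list(ponset = pre, qrspre = m$qrs_pre_ms, qrspost = m$qrs_post_ms,
         toffset = m$qt_intercept + m$qt_rr_coeff * (60 / hr_eff) -
           m$qrs_pre_ms)
  }
  p_len <- lm_ms$ponset - lm_ms$qrspre
  t_len <- lm_ms$toffset - lm_ms$qrspost
  rbind(
    P = c(params$p_amp, -(lm_ms$qrspre + (1 - params$p_frac) * p_len),
          params$p_width_frac * p_len),
    Q = c(params$q_amp, params$q_center_ms, params$q_width_ms),
    R = c(params$r_amp, 0, params$r_width_ms),
    S = c(params$s_amp, params$s_center_ms, params$s_width_ms),
    T = c(params$t_amp, lm_ms$qrspost + params$t_frac * t_len,
          params$t_width_frac * t_len))
}

#' Generate one synthetic 12-lead ECG record
#'
#' Sums per-beat Gaussian bumps on every lead at R-peak times spaced
#' `60/hr_bpm` seconds apart (optionally jittered multiplicatively),
#' projects the common waveform through the per-lead scaling vector, adds
#' noise, and records the exact ground-truth R-peak sample indices in
#' `truth_rpeaks`. Fully deterministic for a fixed seed.
#'
#' @param hr_bpm Heart rate in bpm, within `[30, 220]`.
#' @param duration_s Record duration in seconds (default 10).
#' @param fs Sampling rate in Hz (default 500).
#' @param params A [beat_params()].
#' @param noise A [noise_params()]; default [no_noise()].
#' @param rr_jitter_frac Multiplicative RR jitter in `[0, 0.2)`
#'   (default 0).
#' @param first_r_s Time of the first R-peak in seconds (default 0.3).
#' @param seed Optional integer seed (local to this call).
#' @return An [ecg_record()] with `truth_rpeaks` set.
#' @export
generate_record <- function(hr_bpm, duration_s = 10, fs = 500,
                            params = beat_params(), noise = no_noise(),
                            rr_jitter_frac = 0, first_r_s = 0.3,
                            seed = NULL) {
  if (hr_bpm < 30 || hr_bpm > 220)
    stop("hr_bpm must lie in [30, 220]")
  if (rr_jitter_frac < 0 || rr_jitter_frac >= 0.2)
    stop("rr_jitter_frac must lie in [0, 0.2)")
  stopifnot(inherits(params, "beat_params"), inherits(noise, "noise_params"))
  with_seed(seed, {
    n <- round(duration_s * fs)
    rr_s <- 60 / hr_bpm
    r_times <- first_r_s
    while (TRUE) {
      jit <- if (rr_jitter_frac > 0) 1 + rr_jitter_frac * stats::runif(1, -1, 1) else 1
      nxt <- r_times[length(r_times)] + rr_s * jit
      if (nxt >= duration_s - 0.02) break
      r_times <- c(r_times, nxt)
    }
    truth <- round(r_times * fs)          # 0-based sample indices
    truth <- truth[truth < n]
    r_grid <- truth / fs                  # snap centres to the sample grid
    waves <- wave_table(params, hr_bpm)
    t <- (0:(n - 1)) / fs
    base <- numeric(n)
    for (k in seq_along(r_grid)) {
      for (w in seq_len(nrow(waves))) {
        amp <- waves[w, 1]; c_ms <- waves[w, 2]; s_ms <- waves[w, 3]
        if (amp == 0) next
        mu <- r_grid[k] + c_ms / 1000
        sd_s <- s_ms / 1000
        lo <- max(1L, floor((mu - 5 * sd_s) * fs) + 1L)
        hi <- min(n, ceiling((mu + 5 * sd_s) * fs) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        base[idx] <- base[idx] + amp * exp(-((t[idx] - mu)^2) / (2 * sd_s^2))
      }
    }
    sig <- outer(base, params$lead_scale)
    if (noise$baseline_mV > 0)
      sig <- sig + noise$baseline_mV *
        sin(2 * pi * noise$baseline_hz * t + stats::runif(1, 0, 2 * pi))
    if (noise$powerline_mV > 0)
      sig <- sig + noise$powerline_mV *
        sin(2 * pi * noise$powerline_hz * t + stats::runif(1, 0, 2 * pi))
    if (noise$white_mV > 0)
      sig <- sig + matrix(stats::rnorm(length(sig), sd = noise$white_mV),
                          nrow = n)
    leads <- if (length(params$lead_scale) == 12L) standard_leads()
             else paste0("ch", seq_along(params$lead_scale))
    ecg_record(sig, fs = fs, lead_names = leads,
               meta = list(generator = "gaussian-pqrst", hr_bpm = hr_bpm,
                           rr_jitter_frac = rr_jitter_frac, seed = seed),
               truth_rpeaks = truth)
  })
}

#' White-noise sigma for a target SNR
#'
#' Convenience helper: the white-noise standard deviation that yields the
#' requested signal-to-noise ratio against the RMS of a clean record's
#' reference lead.
#'
#' @param record A clean (noise-free) [ecg_record()].
#' @param snr_db Target SNR in decibels.
#' @param lead Reference lead (default `"II"`).
#' @return Standard deviation in mV.
#' @export
white_sigma_for_snr <- function(record, snr_db, lead = "II") {
  s <- slice_lead(record, lead)
  sqrt(mean(s^2)) / 10^(snr_db / 20)
}

#' Generate a labelled multi-class synthetic dataset
#'
#' Emulates three diagnostic groups: `NORM` (baseline morphology),
#' `T_PERTURBED` (only T-wave parameters altered — an ST/T-change-like
#' contrast), and `QRS_PERTURBED` (only Q/R/S parameters altered — an
#' infarction-like contrast). Heart rate is drawn uniformly from
#' `hr_range` per record, and a lognormal per-record amplitude factor
#' (sd `amp_jitter_sd` on the log scale) plus additive noise provide
#' within-class variability. Deterministic for a fixed seed.
#'
#' @param n_per_class Records per class (>= 1).
#' @param classes Subset of `c("NORM", "T_PERTURBED", "QRS_PERTURBED")`.
#' @param hr_range Two-element bpm range (default `c(50, 150)`).
#' @param effect_size Perturbation strength (>= 0; 0 makes the classes
#'   statistically indistinguishable). Default 1: the T-perturbed class
#'   scales the T amplitude by `1 + 0.5 * effect_size`; the QRS-perturbed
#'   class scales Q by `1 + effect_size` and R by
#'   `1 - 0.25 * effect_size`.
#' @param duration_s,fs Record geometry (defaults 10 s, 500 Hz).
#' @param noise A [noise_params()]; default light realistic noise.
#' @param rr_jitter_frac Multiplicative RR jitter (default 0.03).
#' @param amp_jitter_sd Per-record lognormal amplitude sd (default 0.1).
#' @param seed Integer seed.
#' @return List with `records` (list of [ecg_record()]), `labels`
#'   (character vector), `hr` (numeric vector).
#' @export
generate_class_dataset <- function(n_per_class,
                                   classes = c("NORM", "T_PERTURBED",
                                               "QRS_PERTURBED"),
                                   hr_range = c(50, 150), effect_size = 1,
                                   duration_s = 10, fs = 500,
                                   noise = noise_params(),
                                   rr_jitter_frac = 0.03,
                                   amp_jitter_sd = 0.1, seed = 1L) {
  stopifnot(n_per_class >= 1, effect_size >= 0)
  known <- c("NORM", "T_PERTURBED", "QRS_PERTURBED")
  if (!all(classes %in% known))
    stop("unknown class name(s): ",
         paste(setdiff(classes, known), collapse = ", "))
  with_seed(seed, {
    n_total <- n_per_class * length(classes)
    labels <- rep(classes, each = n_per_class)
    hrs <- stats::runif(n_total, hr_range[1], hr_range[2])
    seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    records <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      scale <- exp(stats::rnorm(1, 0, amp_jitter_sd))
      bp <- switch(labels[i],
        NORM = beat_params(),
        T_PERTURBED = beat_params(t_amp = 0.35 * (1 + 0.5 * effect_size)),
        QRS_PERTURBED = beat_params(q_amp = -0.1 * (1 + effect_size),
                                    r_amp = 1.0 * (1 - 0.25 * effect_size)))
      bp$p_amp <- bp$p_amp * scale; bp$q_amp <- bp$q_amp * scale
      bp$r_amp <- bp$r_amp * scale; bp$s_amp <- bp$s_amp * scale
      bp$t_amp <- bp$t_amp * scale
      records[[i]] <- generate_record(hrs[i], duration_s = duration_s,
                                      fs = fs, params = bp, noise = noise,
                                      rr_jitter_frac = rr_jitter_frac,
                                      seed = seeds[i])
      records[[i]]$meta$label <- labels[i]
    }
    list(records = records, labels = labels, hr = hrs)
  })
}
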