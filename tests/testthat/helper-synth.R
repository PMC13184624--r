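# Shared fixtures, built in code. Heavy synthetic datasets are cached per
# test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_template <- function(offset_s = 0.25) {
  build_template(10, 500, 60, offset_s)
}

# noisy record at a given SNR (white noise sigma derived from the clean
# signal's lead-II RMS), with mild RR jitter
noisy_record <- function(hr, snr_db, seed, jitter = 0.05) {
  clean <- generate_record(hr, seed = seed)
  sg <- white_sigma_for_snr(clean, snr_db)
  generate_record(hr, noise = noise_params(white_mV = sg),
                  rr_jitter_frac = jitter, seed = seed)
}

# truth peaks far enough from the record edges that the detector's edge
# policy (drop QRS regions touching the first/last 100 ms) cannot apply
interior_truth <- function(record, margin_s = 0.2) {
  t <- record$truth_rpeaks
  t[t >= margin_s * record$fs & t < n_samples(record) - margin_s * record$fs]
}

# lead-II hrc median beats of a class dataset, one row per record
median_beat_matrix <- function(dataset, config, lead = 2L) {
  batch <- transform_batch(dataset$records, config)
  stopifnot(length(batch$failures) == 0L)
  t(vapply(batch$results, function(r) r$aligned[, lead],
           numeric(nrow(batch$results[[1]]$aligned))))
}

# brute-force one-vs-rest AUC by explicit pair counting (ties count 1/2)
pair_count_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

brute_macro_auc <- function(scores, labels) {
  classes <- sort(unique(labels))
  mean(vapply(classes, function(cl)
    pair_count_auc(scores[, cl], labels == cl), numeric(1)))
}

# |H(f)| of a digital filter, evaluated directly from its coefficients
filter_gain <- function(b, a, f_hz, fs) {
  z <- exp(-1i * 2 * pi * f_hz / fs * (0:(max(length(b), length(a)) - 1)))
  Mod(sum(b * z[seq_along(b)]) / sum(a * z[seq_along(a)]))
}

std_centroid_dist <- function(a, b) {
  abs(mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
}
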