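#' Standard 12-lead names
#'
#' Default lead ordering for a 12-lead resting ECG: the limb leads I, II,
#' III, the augmented leads aVR, aVL, aVF, and the precordial leads V1-V6.
#'
#' @return Character vector of length 12.
#' @export
standard_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Construct an ECG record
#'
#' An `ecg_record` holds one multichannel ECG: a sample matrix in
#' millivolts (rows = samples, columns = leads), the sampling rate, lead
#' labels, and optional ground-truth R-peak positions (synthetic data
#' only). All sample indices in this package are 0-based and all index
#' intervals are half-open `[start, stop)`.
#'
#' @param signal Numeric matrix `[n_samples x n_leads]` in millivolts.
#'   A plain vector is treated as a single lead.
#' @param fs Sampling rate in Hz (> 0).
#' @param lead_names Optional character vector of lead labels. Defaults to
#'   the standard 12-lead ordering when `n_leads == 12`, otherwise
#'   `"ch1", "ch2", ...`.
#' @param meta Free-form named list of provenance information.
#' @param truth_rpeaks Optional 0-based sample indices of true R-peaks
#'   (strictly increasing, each in `[0, n_samples)`).
#' @return Object of class `ecg_record` with fields `signal`, `fs`,
#'   `lead_names`, `duration_s`, `meta`, `truth_rpeaks`.
#' @export
ecg_record <- function(signal, fs, lead_names = NULL, meta = list(),
                       truth_rpeaks = NULL) {
  if (is.vector(signal) && is.numeric(signal)) signal <- matrix(signal, ncol = 1)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix [n_samples x n_leads]")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (ncol(signal) < 1L) stop("at least one lead is required")
  bad <- which(!is.finite(signal))
  if (length(bad)) {
    idx0 <- bad[1L] - 1L
    stop(sprintf("non-finite sample at flat 0-based index %d (sample %d, lead %d)",
                 idx0, (bad[1L] - 1L) %% nrow(signal),
                 (bad[1L] - 1L) %/% nrow(signal) + 1L))
  }
  if (is.null(lead_names)) {
    lead_names <- if (ncol(signal) == 12L) standard_leads()
                  else paste0("ch", seq_len(ncol(signal)))
  }
  if (length(lead_names) != ncol(signal))
    stop("`lead_names` length must equal the number of leads")
  if (!is.null(truth_rpeaks)) {
    truth_rpeaks <- as.integer(round(truth_rpeaks))
    if (any(diff(truth_rpeaks) <= 0))
      stop("`truth_rpeaks` must be strictly increasing")
    if (any(truth_rpeaks < 0L) || any(truth_rpeaks >= nrow(signal)))
      stop("`truth_rpeaks` must lie in [0, n_samples)")
  }
  colnames(signal) <- lead_names
  structure(
    list(signal = signal, fs = fs, lead_names = lead_names,
         duration_s = nrow(signal) / fs, meta = meta,
         truth_rpeaks = truth_rpeaks),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples x %d leads, %g Hz, %.3f s\n",
              nrow(x$signal), ncol(x$signal), x$fs, x$duration_s))
  cat("  leads:", paste(x$lead_names, collapse = ", "), "\n")
  if (!is.null(x$truth_rpeaks))
    cat(sprintf("  truth_rpeaks: %d fiducials\n", length(x$truth_rpeaks)))
  invisible(x)
}

#' Number of samples in a record
#' @param record An `ecg_record`.
#' @return Integer sample count.
#' @export
n_samples <- function(record) nrow(record$signal)

resolve_lead <- function(record, lead) {
  if (is.numeric(lead)) {
    j <- as.integer(lead) + 1L  # 0-based index in, 1-based column out
    if (j < 1L || j > ncol(record$signal))
      stop(sprintf("lead index %d out of range [0, %d)", lead,
                   ncol(record$signal)))
    return(j)
  }
  j <- match(tolower(lead), tolower(record$lead_names))
  if (is.na(j))
    stop(sprintf("unknown lead '%s'; available: %s", lead,
                 paste(record$lead_names, collapse = ", ")))
  j
}

#' Extract a single lead
#'
#' Returns one column of the record as a numeric vector with the sampling
#' rate attached as attribute `fs`. Lead names are matched
#' case-insensitively; a numeric argument is interpreted as a 0-based
#' column index. The conventional detection lead is `"II"`.
#'
#' @param record An `ecg_record`.
#' @param lead Lead name (case-insensitive) or 0-based column index.
#'   Default `"II"`.
#' @return Numeric vector with attribute `fs`.
#' @export
slice_lead <- function(record, lead = "II") {
  j <- resolve_lead(record, lead)
  out <- record$signal[, j]
  attr(out, "fs") <- record$fs
  out
}

#' Construct an importance map
#'
#' Per-sample (optionally per-lead) importance values paired with an ECG
#' record, either in the record's original sample space or in aligned
#' template-beat space.
#'
#' @param values Numeric matrix `[n_samples x n_leads]` (a vector is one
#'   lead) of finite importance values.
#' @param space `"original"` or `"aligned"`.
#' @param record_id Identifier linking the map to its source record.
#' @return Object of class `importance_map`.
#' @export
importance_map <- function(values, space = c("original", "aligned"),
                           record_id = NULL) {
  space <- match.arg(space)
  if (is.vector(values) && is.numeric(values)) values <- matrix(values, ncol = 1)
  if (!is.matrix(values) || !is.numeric(values) || any(!is.finite(values)))
    stop("`values` must be a finite numeric matrix")
  structure(list(values = values, space = space, record_id = record_id),
            class = "importance_map")
}
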