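#' Alignment configuration
#'
#' Bundles every choice the transform needs: the resampling strategy
#' (`"linear"` stretches each full R-to-R cycle onto the template grid;
#' `"hrc"` rescales only the rate-dependent P and ST/T regions while
#' copying a fixed 35/55 ms QRS window unchanged), the output format, the
#' detection lead, and the detector/template/interval-model settings.
#'
#' @param template An [build_template()] result; its `fs` and
#'   `duration_s` must match every input record.
#' @param strategy `"hrc"` (default) or `"linear"`.
#' @param output `"full_signal"`, `"median_beat"` (default), or
#'   `"beat_list"`.
#' @param lead Detection lead (name or 0-based index), default `"II"`.
#' @param detector A [detector_config()].
#' @param hrc An [hrc_model()].
#' @param beat_list_processed If `TRUE` (default) `beat_list` output
#'   returns template-length resampled beats; if `FALSE`, raw
#'   variable-length source cycles with their local landmarks.
#' @return Object of class `alignment_config`.
#' @export
alignment_config <- function(template, strategy = c("hrc", "linear"),
                             output = c("median_beat", "full_signal",
                                        "beat_list"),
                             lead = "II", detector = detector_config(),
                             hrc = hrc_model(), beat_list_processed = TRUE) {
  stopifnot(inherits(template, "ecg_template"))
  structure(list(template = template, strategy = match.arg(strategy),
                 output = match.arg(output), lead = lead,
                 detector = detector, hrc = hrc,
                 beat_list_processed = isTRUE(beat_list_processed)),
            class = "alignment_config")
}

## ---- segment plans ----------------------------------------------------------

# Landmark boundaries of one cycle [r0, r1) at heart rate hr. Returns the
# six 0-based boundary positions (half-open between consecutive ones) or
# NULL when the geometry is unusable. When T-offset and the next P-onset
# cross (T-P fusion at high rates), both are clipped to their midpoint so
# the TP filler collapses to zero length instead of the cycle being lost.
cycle_boundaries <- function(r0, r1, hr, fs, model) {
  lm <- tryCatch(hrc_landmarks(hr, fs, model), error = function(e) NULL)
  if (is.null(lm)) return(NULL)
  s1 <- r0 + round_half_up(lm$d_qrspost)
  s2 <- r0 + round_half_up(lm$d_toffset)
  s3 <- r1 - round_half_up(lm$d_ponset)
  s4 <- r1 - round_half_up(lm$d_qrspre)
  if (s4 <= s1) return(NULL)  # QRS windows of adjacent beats collide
  if (s2 > s3) {
    mid <- min(max(round_half_up((s2 + s3) / 2), s1), s4)
    s2 <- mid; s3 <- mid
  }
  s2 <- min(max(s2, s1), s4)
  s3 <- min(max(s3, s2), s4)
  c(r0, s1, s2, s3, s4, r1)
}

#' Plan the per-cycle segment mapping
#'
#' Computes, for each detected cardiac cycle, the half-open source
#' intervals and the half-open target intervals they map onto — the
#' sample mapping later applied identically to every lead (and reusable
#' for realigning importance maps). Under the linear strategy each cycle
#' `[R_k, R_k+1)` maps as one segment onto `[slot_k, slot_k+1)`. Under
#' hrc each cycle splits at the landmark boundaries evaluated at the
#' cycle's own local heart rate (from its own RR interval) into five
#' segments: the post-R half of the fixed QRS window (copied), the ST/T
#' region, the TP filler, the P region (each Fourier-resampled), and the
#' pre-R half of the next QRS window (copied). The first
#' `min(n_cycles, n_slots - 1)` cycles are mapped in order; surplus
#' cycles are dropped with a warning. Cycles whose landmark ordering is
#' unusable are dropped with a warning.
#'
#' @param record An [ecg_record()].
#' @param rpeaks An [rpeak_set()] for the record.
#' @param strategy `"hrc"` or `"linear"`.
#' @param hrc An [hrc_model()].
#' @param template An [build_template()] result.
#' @return Object of class `sample_mapping`: a data frame of segments
#'   (`cycle`, `kind`, `src_start`, `src_stop`, `dst_start`, `dst_stop`;
#'   0-based half-open) with attributes `n` (record length), `slots_used`
#'   (0-based template slots that received a cycle boundary), and
#'   `dropped` (source cycle indices dropped).
#' @export
segment_cycles <- function(record, rpeaks, strategy = c("hrc", "linear"),
                           hrc = hrc_model(), template) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(rpeaks, "rpeak_set"), inherits(template, "ecg_template"))
  peaks <- rpeaks$indices
  if (length(peaks) < 2L)
    stop("alignment infeasible: need >= 2 detected R-peaks")
  fs <- template$fs
  n <- n_samples(record)
  slots <- template$rpeak_slots
  n_cycles_src <- length(peaks) - 1L
  n_cycles_dst <- length(slots) - 1L
  m <- min(n_cycles_src, n_cycles_dst)
  if (m < 1L)
    stop("alignment infeasible: template holds fewer than 2 R-peak slots")
  if (n_cycles_src > m)
    warning(sprintf("%d surplus cycle(s) beyond the %d template slots dropped",
                    n_cycles_src - m, length(slots)))
  segs <- list()
  dropped <- integer(0)
  if (strategy == "linear") {
    for (k in seq_len(m)) {
      segs[[length(segs) + 1L]] <- data.frame(
        cycle = k, kind = "resample",
        src_start = peaks[k], src_stop = peaks[k + 1L],
        dst_start = slots[k], dst_stop = slots[k + 1L])
    }
  } else {
    tb_land <- hrc_landmarks(template$target_bpm, fs, hrc)
    for (k in seq_len(m)) {
      rr_src <- peaks[k + 1L] - peaks[k]
      hr_local <- 60 * fs / rr_src
      sb <- cycle_boundaries(peaks[k], peaks[k + 1L], hr_local, fs, hrc)
      tb <- cycle_boundaries(slots[k], slots[k + 1L], template$target_bpm,
                             fs, hrc)
      if (is.null(sb) || is.null(tb)) {
        dropped <- c(dropped, k)
        next
      }
      kind <- c("copy", "resample", "resample", "resample", "copy")
      for (j in 1:5) {
        segs[[length(segs) + 1L]] <- data.frame(
          cycle = k, kind = kind[j],
          src_start = sb[j], src_stop = sb[j + 1L],
          dst_start = tb[j], dst_stop = tb[j + 1L])
      }
    }
    if (length(dropped))
      warning(sprintf("cycle(s) %s dropped: unusable landmark geometry",
                      paste(dropped, collapse = ", ")))
    if (length(dropped) == m)
      stop("alignment infeasible: all cycles dropped")
  }
  plan <- do.call(rbind, segs)
  plan <- plan[plan$dst_stop > plan$dst_start | plan$src_stop > plan$src_start, ]
  rownames(plan) <- NULL
  mapped_cycles <- setdiff(unique(plan$cycle), dropped)
  structure(plan,
            class = c("sample_mapping", "data.frame"),
            n = n, fs = fs,
            slots_used = slots[intersect(seq_len(length(slots)),
                                         sort(unique(c(mapped_cycles,
                                                       mapped_cycles + 1L))))],
            mapped_cycles = sort(mapped_cycles),
            dropped = dropped)
}

# Apply a sample mapping to a [n x L] matrix, producing the aligned
# full-length matrix (unmapped spans zero-filled) and a coverage mask.
apply_mapping <- function(sig, mapping) {
  n <- attr(mapping, "n")
  out <- matrix(0, nrow = n, ncol = ncol(sig))
  covered <- logical(n)
  for (i in seq_len(nrow(mapping))) {
    s0 <- mapping$src_start[i]; s1 <- mapping$src_stop[i]
    t0 <- mapping$dst_start[i]; t1 <- mapping$dst_stop[i]
    mlen <- t1 - t0
    if (mlen <= 0L) next
    src <- sig[seq.int(s0 + 1L, length.out = s1 - s0), , drop = FALSE]
    if (mapping$kind[i] == "copy") {
      stopifnot(nrow(src) == mlen)
      res <- src
    } else {
      boundary <- sig[min(s0 + 1L, nrow(sig)), ]
      res <- resample_flexible(src, mlen, boundary_row = boundary)
    }
    out[seq.int(t0 + 1L, length.out = mlen), ] <- res
    covered[seq.int(t0 + 1L, length.out = mlen)] <- TRUE
  }
  list(aligned = out, covered = covered)
}

## ---- beat extraction and aggregation ---------------------------------------

# 0-based start of the template beat window for a slot: the beat spans
# one full template cycle starting at the P-onset landmark, so the
# R-peak sits at a fixed internal offset d_ponset(target_bpm).
beat_geometry <- function(template, hrc) {
  lm <- hrc_landmarks(template$target_bpm, template$fs, hrc)
  list(beat_len = as.integer(round_half_up(template$rr_samples)),
       r_offset = as.integer(round_half_up(lm$d_ponset)))
}

extract_beats <- function(aligned, covered, template, hrc) {
  geom <- beat_geometry(template, hrc)
  n <- nrow(aligned)
  beats <- list(); slots_kept <- integer(0)
  for (slot in template$rpeak_slots) {
    st <- slot - geom$r_offset
    en <- st + geom$beat_len
    if (st < 0L || en > n) next
    idx <- seq.int(st + 1L, en)
    if (!all(covered[idx])) next
    beats[[length(beats) + 1L]] <- aligned[idx, , drop = FALSE]
    slots_kept <- c(slots_kept, slot)
  }
  list(beats = beats, slots = slots_kept, beat_len = geom$beat_len,
       r_offset = geom$r_offset)
}

#' Pointwise median beat
#'
#' Aggregates equal-length processed cycles into one representative beat
#' by taking the elementwise median across cycles, per lead (midpoint
#' convention for even counts).
#'
#' @param beat_list Non-empty list of numeric matrices of identical
#'   dimensions `[beat_len x n_leads]`.
#' @return One matrix `[beat_len x n_leads]`.
#' @export
median_beat <- function(beat_list) {
  if (!length(beat_list)) stop("median_beat needs at least one cycle")
  dims <- vapply(beat_list, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ragged cycle lengths: only processed (equal-length) cycles can be aggregated")
  if (length(beat_list) == 1L) return(beat_list[[1L]])
  arr <- array(unlist(beat_list, use.names = FALSE),
               dim = c(dims[1, 1], dims[2, 1], length(beat_list)))
  apply(arr, c(1, 2), stats::median)
}

## ---- transform --------------------------------------------------------------

#' Align one ECG record to the template
#'
#' Runs R-peak detection on the configured lead, plans the per-cycle
#' segment mapping (see [segment_cycles()]), and applies it identically
#' to every lead. After the transform, every retained reference-lead
#' R-peak sits exactly on its template slot.
#'
#' @param record An [ecg_record()]; its `fs` and `duration_s` must match
#'   the template.
#' @param config An [alignment_config()].
#' @return Object of class `alignment_result` with fields:
#'   \describe{
#'     \item{`aligned`}{Full-length aligned matrix (`full_signal`), the
#'       median beat matrix (`median_beat`), or a list of per-cycle
#'       matrices (`beat_list`).}
#'     \item{`mapping`}{The [segment_cycles()] plan.}
#'     \item{`rpeaks_detected`}{The [rpeak_set()] used.}
#'     \item{`template`, `output`, `strategy`}{Echoes of the
#'       configuration.}
#'     \item{`beat_len`, `r_offset`}{Beat geometry: beats span one
#'       template cycle starting at the P-onset landmark, with the R-peak
#'       at index `r_offset` (0-based).}
#'     \item{`covered`}{Logical mask of template samples written by a
#'       mapped segment (zero-filled elsewhere).}
#'   }
#' @export
transform <- function(record, config) {
  stopifnot(inherits(record, "ecg_record"),
            inherits(config, "alignment_config"))
  tpl <- config$template
  if (abs(record$fs - tpl$fs) > 1e-9 ||
      abs(record$duration_s - tpl$duration_s) > 1e-9)
    stop(sprintf("record (%g Hz, %g s) does not match template (%g Hz, %g s)",
                 record$fs, record$duration_s, tpl$fs, tpl$duration_s))
  rp <- detect_rpeaks(record, lead = config$lead, config = config$detector)
  mapping <- segment_cycles(record, rp, strategy = config$strategy,
                            hrc = config$hrc, template = tpl)
  full <- apply_mapping(record$signal, mapping)
  res <- list(mapping = mapping, rpeaks_detected = rp, template = tpl,
              output = config$output, strategy = config$strategy,
              covered = full$covered)
  geom <- beat_geometry(tpl, config$hrc)
  res$beat_len <- geom$beat_len
  res$r_offset <- geom$r_offset
  if (config$output == "full_signal") {
    colnames(full$aligned) <- record$lead_names
    res$aligned <- full$aligned
  } else if (config$output == "beat_list" && !config$beat_list_processed) {
    peaks <- rp$indices
    cyc <- lapply(seq_len(length(peaks) - 1L), function(k) {
      idx <- seq.int(peaks[k] + 1L, peaks[k + 1L])
      record$signal[idx, , drop = FALSE]
    })
    res$aligned <- cyc
  } else {
    eb <- extract_beats(full$aligned, full$covered, tpl, config$hrc)
    if (!length(eb$beats))
      stop("alignment infeasible: no complete template beat covered")
    res$beat_slots <- eb$slots
    res$aligned <- if (config$output == "beat_list") eb$beats
                   else median_beat(eb$beats)
    if (config$output == "median_beat")
      colnames(res$aligned) <- record$lead_names
  }
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> strategy=%s output=%s, %d peaks detected, %d segment(s)\n",
              x$strategy, x$output, length(x$rpeaks_detected$indices),
              nrow(x$mapping)))
  invisible(x)
}

#' Align a batch of records
#'
#' Applies [transform()] to each record, optionally across worker
#' processes. Output order matches input order and results are
#' bit-identical for any worker count (the transform is deterministic and
#' uses no random numbers). In lenient mode (default) per-record failures
#' are recorded by index without aborting the batch; in strict mode any
#' failure raises an error naming the failing indices.
#'
#' @param records List of [ecg_record()] objects.
#' @param config An [alignment_config()].
#' @param n_workers Number of worker processes (default 1).
#' @param strict Abort on any per-record failure? Default `FALSE`.
#' @return List with `results` (same length/order as `records`; `NULL`
#'   where a record failed) and `failures` (named character vector of
#'   error messages keyed by record index).
#' @export
transform_batch <- function(records, config, n_workers = 1L,
                            strict = FALSE) {
  stopifnot(n_workers >= 1L)
  if (!length(records)) return(list(results = list(), failures = character(0)))
  worker <- function(rec) {
    tryCatch(list(ok = TRUE, value = suppressWarnings(transform(rec, config))),
             error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  }
  raw <- if (n_workers == 1L || .Platform$OS.type != "unix") {
    lapply(records, worker)
  } else {
    parallel::mclapply(records, worker, mc.cores = n_workers)
  }
  ok <- vapply(raw, function(r) isTRUE(r$ok), logical(1))
  failures <- stats::setNames(
    vapply(raw[!ok], function(r) as.character(r$value), character(1)),
    which(!ok))
  if (strict && any(!ok))
    stop("transform_batch failed for record(s): ",
         paste(which(!ok), collapse = ", "))
  results <- vector("list", length(records))
  results[ok] <- lapply(raw[ok], `[[`, "value")
  list(results = results, failures = failures)
}
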