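#' Interval schemes over the aligned beat axis
#'
#' `interval_scheme_fixed()` tiles the beat axis with consecutive
#' intervals of a fixed width (default 25 samples), dropping the trailing
#' remainder — a 475-sample beat yields 19 intervals.
#' `interval_scheme_landmarks()` derives the named intervals `P`, `QRS`,
#' `T` (the ST/T region), and `TP` from the template's hrc landmarks at
#' the target heart rate, in beat coordinates (the beat starts at the
#' P-onset landmark with the R-peak at the internal offset
#' `d_ponset(target_bpm)`).
#'
#' @param beat_len Beat length in samples.
#' @param width Interval width in samples (default 25).
#' @return Object of class `interval_scheme`: a list of half-open 0-based
#'   `c(start, stop)` index ranges (named for the landmark variant).
#' @export
interval_scheme_fixed <- function(beat_len, width = 25L) {
  width <- as.integer(width)
  stopifnot(width >= 1L, beat_len >= width)
  k <- beat_len %/% width
  iv <- lapply(seq_len(k) - 1L, function(i) c(i * width, (i + 1L) * width))
  structure(iv, class = "interval_scheme", beat_len = as.integer(beat_len),
            width = width)
}

#' @rdname interval_scheme_fixed
#' @param template An [build_template()] result.
#' @param hrc An [hrc_model()].
#' @export
interval_scheme_landmarks <- function(template, hrc = hrc_model()) {
  stopifnot(inherits(template, "ecg_template"))
  lm <- hrc_landmarks(template$target_bpm, template$fs, hrc)
  beat_len <- as.integer(round_half_up(template$rr_samples))
  r0 <- round_half_up(lm$d_ponset)
  qrs_pre <- round_half_up(lm$d_qrspre)
  qrs_post <- round_half_up(lm$d_qrspost)
  t_off <- min(round_half_up(lm$d_toffset), beat_len - r0)
  iv <- list(P = c(0, r0 - qrs_pre),
             QRS = c(r0 - qrs_pre, r0 + qrs_post),
             T = c(r0 + qrs_post, r0 + t_off),
             TP = c(r0 + t_off, beat_len))
  iv <- iv[vapply(iv, function(v) v[2] > v[1], logical(1))]
  structure(iv, class = "interval_scheme", beat_len = beat_len,
            r_offset = as.integer(r0))
}

beats_as_matrix <- function(X) {
  # [n, beat_len] matrix or [n, beat_len, n_leads] array -> list with the
  # flat matrix and the mapping from beat-axis interval to flat columns
  if (length(dim(X)) == 3L) {
    d <- dim(X)
    flat <- matrix(X, nrow = d[1])        # column order: (sample, lead)
    cols_for <- function(iv) {
      base <- seq.int(iv[1] + 1L, iv[2])
      as.vector(outer(base, (seq_len(d[3]) - 1L) * d[2], `+`))
    }
    list(flat = flat, beat_len = d[2], cols_for = cols_for)
  } else {
    X <- as.matrix(X)
    list(flat = X, beat_len = ncol(X),
         cols_for = function(iv) seq.int(iv[1] + 1L, iv[2]))
  }
}

## ---- metrics ----------------------------------------------------------------

# one-vs-rest AUC by the midrank (Wilcoxon) formula
auc_binary <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro-averaged AUC
#'
#' Unweighted mean of per-class one-vs-rest areas under the ROC curve,
#' computed by the midrank (Wilcoxon) formula so ties contribute 1/2.
#'
#' @param scores Numeric matrix `[n x n_classes]`, one score column per
#'   class, with `colnames` matching the class labels (columns are
#'   matched to `sort(unique(labels))` when unnamed). A vector is
#'   accepted for a binary problem as the score of the second sorted
#'   class.
#' @param labels Vector of class labels, each class present at least
#'   once.
#' @return Macro AUC in `[0, 1]`.
#' @export
macro_auc <- function(scores, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes present")
  if (is.null(dim(scores))) {
    if (length(classes) != 2L)
      stop("a score vector is only valid for a binary problem")
    scores <- cbind(-scores, scores)
    colnames(scores) <- classes
  }
  scores <- as.matrix(scores)
  if (nrow(scores) != length(labels))
    stop("scores and labels disagree in length")
  cn <- colnames(scores)
  if (is.null(cn)) {
    if (ncol(scores) != length(classes))
      stop("unnamed score columns must match the number of classes")
    cn <- classes
  }
  missing_cls <- setdiff(classes, cn)
  if (length(missing_cls))
    stop("no score column for class(es): ",
         paste(missing_cls, collapse = ", "))
  aucs <- vapply(classes, function(cl)
    auc_binary(scores[, cl == cn, drop = TRUE][seq_len(nrow(scores))],
               labels == cl), numeric(1))
  mean(aucs)
}

#' Expected calibration error
#'
#' Standard confidence-binned ECE: predictions are assigned to
#' equal-width bins on the top-label confidence, and the result is the
#' occupancy-weighted mean absolute gap between each bin's accuracy and
#' its mean confidence. Bounded in `[0, 1]`; invariant under class
#' relabelling.
#'
#' @param probabilities Matrix `[n x n_classes]` of predicted class
#'   probabilities (rows summing to 1; `colnames` matched against
#'   `labels`, positional otherwise).
#' @param labels True class labels.
#' @param n_bins Number of equal-width confidence bins (default 10).
#' @return ECE value `>= 0`.
#' @export
expected_calibration_error <- function(probabilities, labels, n_bins = 10L) {
  probabilities <- as.matrix(probabilities)
  n <- nrow(probabilities)
  if (n == 0L) stop("empty input")
  if (n != length(labels)) stop("probabilities and labels disagree in length")
  if (any(abs(rowSums(probabilities) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  top <- max.col(probabilities, ties.method = "first")
  conf <- probabilities[cbind(seq_len(n), top)]
  cn <- colnames(probabilities)
  pred_lab <- if (!is.null(cn)) cn[top] else as.character(top)
  correct <- pred_lab == as.character(labels)
  bin <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  ece <- 0
  for (b in seq_len(n_bins)) {
    in_b <- bin == b
    if (!any(in_b)) next
    ece <- ece + sum(in_b) / n * abs(mean(correct[in_b]) - mean(conf[in_b]))
  }
  ece
}

## ---- grouped permutation importance -----------------------------------------

#' Grouped permutation importance over beat intervals
#'
#' Measures, for each interval of the aligned beat axis, how much the
#' test metric drops when all features of that interval (all leads of its
#' samples, jointly — one shared row permutation per repetition) are
#' shuffled across observations. The baseline metric is computed once;
#' each of `n_repeats` repetitions per interval draws a fresh permutation
#' and records `baseline - permuted_metric`. Fully determined by `seed`.
#'
#' @param X Beats: matrix `[n x beat_len]` or array
#'   `[n x beat_len x n_leads]`.
#' @param y True labels (length `n`).
#' @param predictor Function mapping an `X`-shaped input to class scores
#'   accepted by `metric`.
#' @param scheme An interval scheme (see [interval_scheme_fixed()]).
#' @param n_repeats Permutations per interval (default 20).
#' @param seed Integer seed (default 1).
#' @param metric Function `(scores, labels) -> numeric`; default
#'   [macro_auc()].
#' @return Object of class `importance_profile`: data frame with one row
#'   per interval (`interval`, `start`, `stop`, `mean_drop`, `sd_drop`),
#'   attributes `baseline`, `n_repeats`, `metric`.
#' @export
grouped_permutation_importance <- function(X, y, predictor, scheme,
                                           n_repeats = 20L, seed = 1L,
                                           metric = macro_auc) {
  stopifnot(inherits(scheme, "interval_scheme"), n_repeats >= 1L)
  bm <- beats_as_matrix(X)
  if (attr(scheme, "beat_len") > bm$beat_len)
    stop("interval scheme exceeds the beat axis of X")
  n <- nrow(bm$flat)
  baseline <- metric(predictor(X), y)
  drops <- matrix(NA_real_, nrow = length(scheme), ncol = n_repeats)
  with_seed(seed, {
    for (i in seq_along(scheme)) {
      cols <- bm$cols_for(scheme[[i]])
      for (r in seq_len(n_repeats)) {
        perm <- sample.int(n)
        Xp <- X
        if (length(dim(X)) == 3L) {
          iv <- scheme[[i]]
          Xp[, seq.int(iv[1] + 1L, iv[2]), ] <-
            X[perm, seq.int(iv[1] + 1L, iv[2]), , drop = FALSE]
        } else {
          Xp[, cols] <- X[perm, cols, drop = FALSE]
        }
        drops[i, r] <- baseline - metric(predictor(Xp), y)
      }
    }
  })
  out <- data.frame(
    interval = if (!is.null(names(scheme))) names(scheme)
               else seq_along(scheme),
    start = vapply(scheme, `[`, numeric(1), 1),
    stop = vapply(scheme, `[`, numeric(1), 2),
    mean_drop = rowMeans(drops),
    sd_drop = apply(drops, 1L, stats::sd))
  structure(out, class = c("importance_profile", "data.frame"),
            baseline = baseline, n_repeats = as.integer(n_repeats),
            metric = deparse(substitute(metric)), drops = drops)
}

#' Deterministic interval-mean predictor
#'
#' Builds the simplest localized classifier over aligned beats: its score
#' for the positive class is the mean of the beat samples inside one
#' interval, with the sign chosen so the positive-class training centroid
#' scores higher. Because the score depends on nothing outside the
#' interval, permuting any other interval provably leaves it unchanged —
#' which makes this the reference predictor for localization checks of
#' [grouped_permutation_importance()].
#'
#' @param X Training beats, matrix `[n x beat_len]` or array
#'   `[n x beat_len x n_leads]`.
#' @param labels Two-class training labels.
#' @param interval Half-open 0-based `c(start, stop)` over the beat axis.
#' @param positive The positive class (default: second sorted label).
#' @return Function mapping beats to a two-column score matrix.
#' @export
make_interval_mean_predictor <- function(X, labels, interval,
                                         positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("interval-mean predictor is two-class")
  if (is.null(positive)) positive <- classes[2L]
  negative <- setdiff(classes, positive)
  bm <- beats_as_matrix(X)
  cols <- bm$cols_for(interval)
  score_of <- function(newX) {
    nb <- beats_as_matrix(newX)
    rowMeans(nb$flat[, cols, drop = FALSE])
  }
  s <- score_of(X)
  direction <- sign(mean(s[labels == positive]) - mean(s[labels == negative]))
  if (direction == 0) direction <- 1
  function(newX) {
    m <- direction * score_of(newX)
    sc <- cbind(-m, m)
    colnames(sc) <- c(negative, positive)
    sc
  }
}

## ---- importance map realignment ---------------------------------------------

#' Realign an importance map into template beat space
#'
#' Transforms a per-sample importance map from its record's original
#' sample space to the aligned median-beat space, by applying the same
#' per-segment Fourier resampling operator as the signal transform and
#' then reducing the per-template-cycle maps to one beat (pointwise mean
#' across cycles by default; median available).
#'
#' @param map An [importance_map()] in `"original"` space whose row count
#'   matches the mapped record.
#' @param mapping A `sample_mapping` from [segment_cycles()], or an
#'   `alignment_result` from [transform()] (in which case `template` and
#'   `hrc` are taken from it).
#' @param template The [build_template()] used (ignored when `mapping` is
#'   an `alignment_result`).
#' @param hrc The [hrc_model()] used (ditto).
#' @param reducer `"mean"` (default) or `"median"` across cycles.
#' @return An [importance_map()] in `"aligned"` space whose values are
#'   one beat `[beat_len x n_leads]`.
#' @export
realign_map <- function(map, mapping, template = NULL, hrc = hrc_model(),
                        reducer = c("mean", "median")) {
  stopifnot(inherits(map, "importance_map"))
  reducer <- match.arg(reducer)
  if (map$space != "original")
    stop("map must be in 'original' space")
  if (inherits(mapping, "alignment_result")) {
    template <- mapping$template
    mapping <- mapping$mapping
  }
  stopifnot(inherits(mapping, "sample_mapping"),
            inherits(template, "ecg_template"))
  if (nrow(map$values) != attr(mapping, "n"))
    stop(sprintf("map length (%d) does not match the mapped record (%d)",
                 nrow(map$values), attr(mapping, "n")))
  full <- apply_mapping(map$values, mapping)
  eb <- extract_beats(full$aligned, full$covered, template, hrc)
  if (!length(eb$beats))
    stop("no complete template beat covered by the mapping")
  beat <- if (reducer == "mean") {
    Reduce(`+`, eb$beats) / length(eb$beats)
  } else {
    median_beat(eb$beats)
  }
  importance_map(beat, space = "aligned", record_id = map$record_id)
}

#' Aggregate aligned importance maps
#'
#' Pointwise mean of a set of equal-shape aligned maps — the dataset-wide
#' aggregation that alignment makes meaningful.
#'
#' @param aligned_maps Non-empty list of [importance_map()] objects in
#'   `"aligned"` space with identical dimensions.
#' @return An [importance_map()] (aligned) with attribute `n_maps`.
#' @export
aggregate_maps <- function(aligned_maps) {
  if (!length(aligned_maps)) stop("empty input: no maps to aggregate")
  if (!all(vapply(aligned_maps, function(m)
    inherits(m, "importance_map") && m$space == "aligned", logical(1))))
    stop("all maps must be importance_map objects in 'aligned' space")
  dims <- vapply(aligned_maps, function(m) dim(m$values), integer(2))
  if (any(dims != dims[, 1]))
    stop("maps disagree in shape")
  mv <- Reduce(`+`, lapply(aligned_maps, `[[`, "values")) /
    length(aligned_maps)
  out <- importance_map(mv, space = "aligned")
  attr(out, "n_maps") <- length(aligned_maps)
  out
}

#' Pearson correlation matrix of importance vectors
#'
#' @param profiles List of equal-length numeric vectors (or a matrix with
#'   one vector per column). Zero-variance vectors yield `NA` entries
#'   with a warning rather than a silent 0.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
importance_correlation <- function(profiles) {
  m <- if (is.list(profiles)) do.call(cbind, lapply(profiles, as.numeric))
       else as.matrix(profiles)
  if (ncol(m) < 2L) stop("need at least 2 vectors")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance vector(s): correlation undefined (NA) for column(s) ",
            paste(which(sds == 0), collapse = ", "))
  out <- suppressWarnings(stats::cor(m))
  diag(out) <- 1
  out
}

## ---- interval PCA ------------------------------------------------------------

#' Interval-wise two-block PCA of aligned beats
#'
#' Performs two separate PCAs — one on the QRS-complex interval, one on
#' the T-wave interval of the aligned beat (endpoints from the template
#' landmarks) — and projects each beat onto the first principal component
#' of each block, yielding an explainable two-dimensional feature vector
#' per beat. The sign convention fixes each loading vector so its
#' largest-magnitude element is positive.
#'
#' @param beats Matrix `[n x beat_len]` or array
#'   `[n x beat_len x n_leads]` of aligned, equal-length beats.
#' @param scheme An interval scheme containing named `QRS` and `T`
#'   intervals (see [interval_scheme_landmarks()]).
#' @return List with `scores` (`[n x 2]`, columns `QRS`, `T`) and
#'   `loadings` (list of the two unit loading vectors).
#' @export
interval_pca <- function(beats, scheme) {
  stopifnot(inherits(scheme, "interval_scheme"))
  if (!all(c("QRS", "T") %in% names(scheme)))
    stop("scheme must contain named QRS and T intervals")
  bm <- beats_as_matrix(beats)
  if (attr(scheme, "beat_len") > bm$beat_len)
    stop("interval scheme exceeds the beat axis")
  one_block <- function(iv) {
    cols <- bm$cols_for(iv)
    blk <- bm$flat[, cols, drop = FALSE]
    if (all(apply(blk, 2L, stats::sd) == 0))
      stop("zero variance in interval; PCA undefined")
    pc <- stats::prcomp(blk, center = TRUE, scale. = FALSE, rank. = 1L)
    load <- pc$rotation[, 1L]
    if (load[which.max(abs(load))] < 0) load <- -load
    list(scores = as.numeric(scale(blk, center = TRUE, scale = FALSE) %*% load),
         loading = load)
  }
  q <- one_block(scheme$QRS)
  tt <- one_block(scheme$T)
  list(scores = cbind(QRS = q$scores, T = tt$scores),
       loadings = list(QRS = q$loading, T = tt$loading))
}
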