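#' Fourier-domain segment resampling
#'
#' Resamples a segment to `target_len` samples by truncating or
#' zero-padding its discrete Fourier spectrum (the classical FFT
#' resampling scheme, equivalent to `scipy.signal.resample`). Applied
#' column-wise, so all leads of a multichannel segment are transformed
#' identically. A length-preserving call returns the input unchanged;
#' DC segments are preserved exactly and in-band sinusoids are
#' reconstructed to machine precision.
#'
#' @param segment Numeric vector or matrix (rows = samples,
#'   columns = leads).
#' @param target_len Desired number of output rows (>= 2).
#' @return Vector or matrix with `target_len` rows.
#' @export
resample_segment <- function(segment, target_len) {
  vec <- is.null(dim(segment))
  x <- if (vec) matrix(segment, ncol = 1) else segment
  n <- nrow(x)
  m <- as.integer(target_len)
  if (n < 2L || m < 2L)
    stop(sprintf("degenerate resampling lengths (source %d, target %d); both must be >= 2",
                 n, m))
  if (m == n) return(segment)
  out <- apply(x, 2L, fourier_resample_vec, m = m)
  if (vec) as.numeric(out) else out
}

fourier_resample_vec <- function(x, m) {
  n <- length(x)
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  nh <- min(n, m)
  keep <- nh %/% 2L
  Y[1:(keep + 1L)] <- X[1:(keep + 1L)]
  if (keep >= 1L) Y[(m - keep + 1L):m] <- X[(n - keep + 1L):n]
  if (nh %% 2L == 0L) {
    if (m < n) {
      # fold the part of the spectrum beyond the new Nyquist bin
      Y[keep + 1L] <- Y[keep + 1L] + X[n - keep + 1L]
    } else if (m > n) {
      # split the old Nyquist bin symmetrically
      Y[keep + 1L] <- Y[keep + 1L] / 2
      Y[m - keep + 1L] <- Y[keep + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Resampling that tolerates degenerate spans: empty or single-sample
# sources are replicated, single-sample targets take the first source
# sample. Used for cycle segments whose landmark geometry collapses
# (e.g. an empty TP filler at high heart rate).
resample_flexible <- function(x_mat, m, boundary_row = NULL) {
  if (m <= 0L) return(x_mat[0, , drop = FALSE])
  n <- nrow(x_mat)
  if (n == 0L) {
    if (is.null(boundary_row)) stop("cannot resample an empty segment")
    return(matrix(rep(boundary_row, each = m), nrow = m))
  }
  if (n == 1L || m == 1L) {
    if (m == 1L) return(x_mat[1L, , drop = FALSE])
    return(matrix(rep(x_mat[1L, ], each = m), nrow = m))
  }
  resample_segment(x_mat, m)
}
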