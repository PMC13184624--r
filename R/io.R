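#' Read an ECG record from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`csv`}{One column per lead, values in millivolts. The first
#'     line is a comment of the form `# fs=500`, the second line holds the
#'     lead names, data rows follow.}
#'   \item{`wfdb`}{A WFDB header/signal pair (`<record>.hea` +
#'     `<record>.dat`, signal format 16, little-endian 16-bit integers,
#'     interleaved). ADC gain and baseline from the header are applied so
#'     samples come back in the units the header declares (millivolts by
#'     convention). `path` may point at the `.hea` file or at the bare
#'     record name.}
#'   \item{`array`}{A matrix container: a TSV of raw values plus a JSON
#'     sidecar `<path>.json` holding `fs`, `lead_names` and `units`.}
#' }
#'
#' @param path File path (see format notes above).
#' @param format One of `"csv"`, `"wfdb"`, `"array"`. Default guesses from
#'   the file extension.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb", "array")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", hea = "wfdb", dat = "wfdb",
                     tsv = "array",
                     stop("cannot guess format from extension of ", path))
  }
  switch(format,
         csv = read_record_csv(path),
         wfdb = read_record_wfdb(path),
         array = read_record_array(path))
}

#' Write an ECG record to disk
#'
#' Inverse of [read_record()]: `read_record(write_record(x))` reproduces
#' `x` field-for-field up to the declared precision of the container
#' (exact for `csv`/`array`, quantized by the ADC gain for `wfdb`).
#'
#' @param record An [ecg_record()].
#' @param path Output path (for `wfdb`, the `.hea` path or bare record
#'   name; the `.dat` file is placed alongside).
#' @param format One of `"csv"`, `"wfdb"`, `"array"`.
#' @param wfdb_gain ADC gain in adu/mV used when writing WFDB (default
#'   1000, i.e. 1 uV resolution).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path,
                         format = c("auto", "csv", "wfdb", "array"),
                         wfdb_gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", hea = "wfdb", tsv = "array",
                     stop("cannot guess format from extension of ", path))
  }
  switch(format,
         csv = write_record_csv(record, path),
         wfdb = write_record_wfdb(record, path, gain = wfdb_gain),
         array = write_record_array(record, path))
  invisible(path)
}

## ---- CSV ------------------------------------------------------------------

read_record_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*fs\\s*=\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2L)
    stop("missing sampling rate: expected a '# fs=<Hz>' first line in ", path)
  fs <- as.numeric(m[2])
  dat <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  sig <- as.matrix(dat)
  storage.mode(sig) <- "double"
  ecg_record(sig, fs = fs, lead_names = colnames(dat),
             meta = list(source = path, format = "csv"))
}

write_record_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", record$fs), con)
  utils::write.csv(as.data.frame(record$signal), con, row.names = FALSE,
                   quote = FALSE)
}

## ---- array container (TSV + JSON sidecar) ---------------------------------

read_record_array <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar lacks required field 'fs': ", sidecar)
  sig <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(sig) <- NULL
  scale <- switch(tolower(meta$units %||% "mV"),
                  mv = 1, uv = 1e-3, v = 1e3,
                  stop("unknown units in sidecar: ", meta$units))
  ecg_record(sig * scale, fs = meta$fs, lead_names = meta$lead_names,
             meta = list(source = path, format = "array"))
}

write_record_array <- function(record, path) {
  utils::write.table(record$signal, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(fs = record$fs, lead_names = record$lead_names, units = "mV"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

## ---- WFDB (format 16) -----------------------------------------------------

# Minimal WFDB support: single-segment records, signal format 16
# (little-endian two's-complement 16-bit), one .dat holding all signals
# interleaved. Gain string follows the "gain(baseline)/units" convention.

wfdb_paths <- function(path) {
  base <- sub("\\.hea$", "", path)
  list(hea = paste0(base, ".hea"), base = base,
       name = basename(base), dir = dirname(base))
}

read_record_wfdb <- function(path) {
  p <- wfdb_paths(path)
  if (!file.exists(p$hea)) stop("file not found: ", p$hea)
  lines <- readLines(p$hea)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 4L)
    stop("WFDB header lacks sampling rate or sample count: ", p$hea)
  n_sig <- as.integer(rec[2])
  fs <- as.numeric(rec[3])
  n_samp <- as.integer(rec[4])
  if (!is.finite(fs) || fs <= 0) stop("missing sampling rate in ", p$hea)
  sig_lines <- lines[2:(1 + n_sig)]
  leads <- character(n_sig); gains <- numeric(n_sig)
  baselines <- numeric(n_sig); units <- character(n_sig)
  dat_file <- NULL
  for (i in seq_len(n_sig)) {
    f <- strsplit(trimws(sig_lines[i]), "\\s+")[[1]]
    if (f[2] != "16")
      stop("unsupported WFDB signal format '", f[2], "' (only 16)")
    dat_file <- f[1]
    gm <- regmatches(f[3],
            regexec("^([0-9.eE+-]+)(\\(([0-9+-]+)\\))?(/(.*))?$", f[3]))[[1]]
    gains[i] <- as.numeric(gm[2])
    baselines[i] <- if (nzchar(gm[4])) as.numeric(gm[4]) else 0
    units[i] <- if (length(gm) >= 6 && nzchar(gm[6])) gm[6] else "mV"
    # description = everything after the 9th standard field, else a default
    leads[i] <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
                else paste0("ch", i)
  }
  dat_path <- file.path(p$dir, dat_file)
  if (!file.exists(dat_path)) stop("file not found: ", dat_path)
  raw <- readBin(dat_path, "integer", n = n_sig * n_samp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_sig * n_samp)
    stop("WFDB .dat shorter than header declares: ", dat_path)
  adc <- matrix(raw, ncol = n_sig, byrow = TRUE)
  sig <- sweep(adc, 2L, baselines, `-`)
  sig <- sweep(sig, 2L, gains, `/`)
  uscale <- vapply(units, function(u) switch(tolower(u),
                   mv = 1, uv = 1e-3, v = 1e3, 1), numeric(1))
  sig <- sweep(sig, 2L, uscale, `*`)
  ecg_record(sig, fs = fs, lead_names = leads,
             meta = list(source = p$hea, format = "wfdb"))
}

write_record_wfdb <- function(record, path, gain = 1000) {
  p <- wfdb_paths(path)
  sig <- record$signal
  adc <- round(sig * gain)
  if (any(abs(adc) > 32767))
    stop("signal exceeds 16-bit WFDB range at gain ", gain,
         "; reduce wfdb_gain")
  storage.mode(adc) <- "integer"
  inter <- as.integer(t(adc))
  writeBin(inter, file.path(p$dir, paste0(p$name, ".dat")),
           size = 2L, endian = "little")
  # 16-bit signed checksum per signal
  csum <- vapply(seq_len(ncol(adc)), function(j) {
    s <- sum(as.numeric(adc[, j])) %% 65536
    if (s > 32767) s <- s - 65536
    as.integer(s)
  }, integer(1))
  hdr <- c(sprintf("%s %d %.10g %d", p$name, ncol(sig), record$fs, nrow(sig)),
           sprintf("%s.dat 16 %.10g(0)/mV 16 0 %d %d 0 %s",
                   p$name, gain, adc[1, ], csum, record$lead_names))
  writeLines(hdr, p$hea)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
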