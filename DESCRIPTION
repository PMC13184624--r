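Package: ecgalign
Title: Template-Based R-Peak Alignment and Heart-Rate-Corrected
    Resampling of Electrocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aligns multichannel resting electrocardiograms (ECGs) to a
    standardized beat template. R-peaks are detected on a reference lead
    by the steepness of the smoothed absolute gradient, and each cardiac
    cycle is resampled onto the template with Fourier-domain resampling,
    either linearly or with a heart-rate-corrected (hrc) strategy that
    rescales the PQ and ST/T regions to a target heart rate while copying
    a fixed window around the R-peak unchanged. Outputs include the
    full-length aligned signal, a per-record median beat, and per-cycle
    beat lists. Alignment-enabled analyses are provided: grouped
    permutation importance over beat intervals, realignment and
    aggregation of per-sample importance maps, interval-wise principal
    component analysis of the QRS complex and T-wave, macro-averaged AUC,
    and expected calibration error. A parametric 12-lead synthetic ECG
    generator with ground-truth fiducials supports validation. Readers
    and writers cover WFDB, CSV, and a matrix-plus-JSON array container.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    parallel,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
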