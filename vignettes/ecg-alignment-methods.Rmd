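---
title: "Heart-rate-corrected ECG alignment: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate-corrected ECG alignment: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgalign)
```

## The model

A resting ECG is a quasi-periodic multichannel signal whose period (the
RR interval) and whose internal interval structure both vary with heart
rate: as the rate rises, the PQ interval (P-onset to QRS-onset) and the
QT interval (QRS-onset to T-offset) shorten, while the QRS complex
itself — ventricular depolarization — keeps an essentially fixed
duration. Any scheme that compares ECGs sample-by-sample must therefore
solve two problems at once: put every R-peak at the same sample index in
every record, and undo the rate-dependence of the surrounding intervals
without distorting the rate-independent QRS.

`ecgalign` does this with a fixed *template* (duration, sampling rate
`fs`, target rate `bpm`, initial offset) that prescribes R-peak slot
positions, and two per-cycle resampling strategies:

* **linear** — the whole R-to-R cycle is Fourier-resampled onto one
  template cycle. Simple, but it over-corrects: at high source rates the
  P and T waves end up proportionally *further* from the R-peak than at
  low rates, so median beats of different rate groups do not
  superimpose.
* **hrc** — each cycle is split at four landmarks and only the
  rate-dependent segments are rescaled. The landmark distances from the
  R-peak are linear interval models evaluated at the cycle's heart rate
  (all in milliseconds):

  * pre-window (P-onset to R): $(-0.351\,hr + 176.7) + 35$
  * fixed QRS window: $35$ before to $55$ after the R-peak, never
    rescaled
  * R to T-offset: $(230 + 170 \cdot 60/hr) - 35$

  The first form is a linear PR–rate relation; the second is a standard
  linear QT–RR estimate measured from QRS onset ($230 + 170\,RR_s$ ms
  with $RR_s$ in seconds), shifted to R-peak coordinates by the fixed
  35 ms QRS-onset offset. Both are implemented as *relative scale
  factors* of the RR interval — the fraction
  $(\text{interval ms} / \text{RR ms}) \cdot \text{RR samples}$ — which
  algebraically reduces to $\text{interval ms} \cdot fs / 1000$ but
  makes explicit that the segments are defined as fractions of the
  cycle.

Each cycle thus yields five segments — post-R QRS half (copied), ST/T
region, TP filler, P region (each Fourier-resampled), pre-R QRS half of
the next beat (copied) — whose target intervals tile the template span
gap-free. The same mapping is applied to every lead, and can be replayed
on any per-sample quantity, which is what makes attribution-map
realignment exact rather than approximate.

### Degenerate landmark geometry at high rates

The two interval models cross at high rates: for $hr \gtrsim 139$ bpm
the predicted T-offset of one beat falls *after* the predicted P-onset
of the next (T–P fusion, a real physiological phenomenon). Dropping all
such cycles would make tachycardic records unalignable, so instead the
two landmarks are clipped to their midpoint: the TP filler collapses to
zero length, the ST/T and P segments absorb the overlap symmetrically,
and the tiling stays monotone. The landmark evaluation itself
(`hrc_landmarks()`) still refuses genuinely unusable geometries
(P-onset not before QRS-onset, T-offset not after QRS-offset), and
`segment_cycles()` drops individual cycles whose local geometry cannot
be repaired, with a warning.

## R-peak detection

Detection runs on a single configurable reference lead (default II,
the convention for rhythm analysis). Preprocessing is a 5th-order
0.5 Hz high-pass Butterworth filter followed by a ±1 Hz second-order
Butterworth band-stop at the powerline frequency (default 50 Hz,
settable to 60). Both are applied forward-backward (zero-phase) so that
fiducial positions are not lagged; the implementation pads with odd
extensions and starts each pass from the steady state of a constant
input, without which a 5th-order high-pass at a normalized cutoff of
0.002 leaves edge transients that would dominate a 10 s record.

QRS complexes are localized by the steepness of the absolute gradient:
the cleaned signal is mildly smoothed (10 ms), differentiated, rectified
and smoothed again (100 ms boxcar), and regions are gated where this
envelope exceeds its running mean plus a fraction (default 0.1) of the
running envelope amplitude, both over a 1.5 s window — long enough to
contain at least one beat down to 40 bpm, short enough to track
amplitude drift. Candidate regions closer than the refractory period
(200 ms) keep only the steepest member, which suppresses T-waves that
graze the threshold. The R-peak is the largest-magnitude extremum of
the cleaned signal inside each region — magnitude, not maximum, so
inverted QRS polarity costs nothing — refined to the raw-signal
extremum within ±20 ms because filtering can shift extrema slightly.
Regions touching the first or last 100 ms are dropped: their cycles are
incomplete and cannot be resampled reliably.

All thresholds are relative, so detection is exactly invariant under
amplitude scaling, and all windows are translation-covariant, so
interior peaks are shift-equivariant.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `highpass_cutoff_hz` | 0.5 | Hz | removes baseline wander below the slowest physiologic component |
| `highpass_order` | 5 | — | steep roll-off without numerical fragility under zero-phase use |
| `powerline_hz` | 50 | Hz | mains interference; 60 for North American data |
| `min_rr_ms` | 200 | ms | refractory period; 300 bpm upper bound on detectable rate |
| `gradient_smooth_ms` | 100 | ms | QRS-scale envelope; merges Q/R/S steepness into one region |
| `qrs_threshold_frac` | 0.1 | — | gate level as a fraction of running envelope amplitude |
| `target_bpm` | 60 | bpm | reference rate; 1 s cycles at 500 Hz give round 500-sample beats |
| `offset_s` | 0.25 | s | leaves room for the P region of the first slot |
| hrc constants | −0.351, 176.7, 35, 55, 230, 170 | ms-scale | the two linear interval models and the fixed QRS window |

The hrc constants are exposed through `hrc_model()` so alternative
interval models can be substituted; the supported heart-rate range is
[30, 220] bpm, outside which the landmark orderings are not guaranteed.

## Analyses enabled by alignment

**Grouped permutation importance** shuffles, per repetition, all
features of one beat interval jointly across observations — one shared
row permutation for all leads of the interval's samples, preserving
inter-lead structure — and reports the drop in macro AUC against an
unpermuted baseline computed once. Default 20 repetitions per interval;
the canonical layout tiles the beat into 25-sample intervals (a
475-sample span yields 19). A deterministic predictor that provably
ignores an interval has exactly zero drop there in every repetition,
which the tests exploit.

**Attribution-map realignment** replays the signal's sample mapping on a
per-sample importance map (same Fourier operator), then reduces the
per-cycle maps to one beat (mean by default, median for robustness).
Because the pipeline is linear, realigning then averaging equals
averaging then realigning, and dataset-level aggregation of per-record
maps becomes meaningful.

**Interval-wise PCA** fits two separate PCAs — QRS interval and T
interval, endpoints from the template landmarks — and keeps each first
principal component score, giving every beat an explainable 2-D
embedding (QRS axis, T axis). Loading signs are fixed by making the
largest-magnitude element positive, so score axes are reproducible
across runs.

**Macro AUC** is the unweighted mean of one-vs-rest midrank AUCs;
**expected calibration error** is the canonical top-label,
10-equal-width-bin variant (occupancy-weighted mean absolute gap
between bin accuracy and bin confidence). Both have brute-force oracles
in the test suite.

## The synthetic generator, and what it does not emulate

`generate_record()` builds each beat as five Gaussian bumps (P, Q, R, S,
T) on a common waveform projected through a per-lead scaling vector,
with exact ground-truth R-peak indices. With `hr_coupling = TRUE` the P
and T waves sit at fixed *fractions* of the hrc landmark segments, with
widths proportional to segment length — so the generator and the hrc
transform share one interval model, and the rate-invariance of hrc
median beats has an exact synthetic ground truth. Noise is additive
baseline wander, powerline, and white Gaussian noise;
`generate_class_dataset()` adds class contrasts that touch only the
T-wave (`T_PERTURBED`, scaling the T amplitude by $1 + 0.5\,e$) or only
the QRS (`QRS_PERTURBED`, scaling Q by $1+e$ and R by $1-0.25e$), with
per-record lognormal amplitude jitter (sd 0.1), uniform heart rates, and
mild RR jitter as within-class variability. Default effect size
$e = 1$ was chosen once to represent a clearly pathological but
realistic morphology change (a ~50% T-amplitude increase).

Passing tests on this generator show that the *mechanics* are right —
detection, landmark geometry, resampling, mapping replay, and the
statistical procedures. They do not show robustness to what the
generator omits: ectopic beats and arrhythmia (no PVC handling beyond
landmark-ordering rejection), beat-to-beat morphology variation, muscle
artifact and electrode noise with realistic spectra, conduction
abnormalities that widen the QRS beyond the fixed 35/55 ms window
(bundle branch block, paediatric ECGs), or atrial activity decoupled
from the ventricular rate. On such data the fixed QRS window and the
single-lead detector are known limitations.

## Numerical choices

* **Coordinates**: sample indices are 0-based and all intervals
  half-open `[start, stop)`, everywhere — this removes every off-by-one
  ambiguity between detection, mapping, and beat extraction.
* **Units**: millivolts internally; WFDB gain/baseline and sidecar units
  are applied on read. Non-finite input samples are rejected, never
  imputed — silent imputation would bias median beats.
* **Rounding**: landmark distances are kept real-valued and rounded
  half-up only at segment-boundary extraction, avoiding cumulative
  drift; template slots round half-up for determinism.
* **Fourier resampling**: spectrum truncation/zero-padding with the
  even-length Nyquist bin split (or folded) symmetrically; a
  length-preserving call returns its input verbatim; empty or
  single-sample source segments (possible for a collapsed TP filler)
  are replicated from the boundary sample instead of erroring.
* **Median beats**: beats span exactly one template cycle starting at
  the P-onset landmark, so the R-peak sits at the fixed internal offset
  `round(d_ponset(target_bpm))` and every named interval has a
  reproducible position; only slots whose full window is covered by
  mapped segments contribute.
* **Surplus cycles** beyond the template's slots are dropped in order
  with a warning; leading/trailing unmapped spans are zero-filled and
  flagged in a coverage mask rather than interpolated.
* **Determinism**: the transform uses no random numbers, so batch
  results are bit-identical for any worker count; all stochastic
  operations (generator, permutation importance) are fully determined
  by an explicit seed.

## Problem sizes used in the tests

The property suites run on synthetic records of the standard resting
geometry (10 s, 500 Hz, 12 leads): 50 records across 45–160 bpm at
15 dB SNR for detection/exactness, 25 records per class for the
permutation-importance and PCA datasets, and 3-record rate groups
(50/75/140 bpm) for the rate-invariance checks. These sizes give the
statistics comfortable margins (e.g. standardized centroid separations
of 3–4 against a threshold of 2) while keeping the full suite fast.

## Known limitations

Beyond the generator's omissions listed above: the linear strategy's
cycle unit is R-to-R (onset-to-onset mapping is not offered); template
estimation from data is out of scope (the template is always
prescribed); and median-beat representations intentionally suppress
beat-to-beat information — rhythm analysis should use the unprocessed
beat list instead.
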