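---
title: "Monitoring, triage, and normalization assessment for quantitative LC-MS QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring, triage, and normalization assessment for quantitative LC-MS QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcsentinel)
```

`qcsentinel` implements a three-tier quality-control model for
quantitative bottom-up proteomics: longitudinal system-suitability
monitoring, per-run internal-QC triage, and external-QC-driven assessment
of the normalization/batch-correction ladder. This vignette is the
package's account of the statistics it computes, the parameters that
matter, what the simulator does and does not emulate, and the design
decisions taken where the problem left them open.

## The measurement model

The unit of exchange is a long-format measurement table: one row per
(run, precursor) carrying precursor and summed-transition areas, retention
time (minutes), average mass error (ppm), and the areas of the first three
isotope peaks (M0, M+1, M+2). Such tables come from chromatogram
integration software; raw-file parsing and peak integration are
deliberately out of scope. A companion run log assigns each run a type —
system suitability, sample, or external QC (inter-batch /
inter-experiment) — a batch, an optional preparation arm, and free-text
annotations. Run order is acquisition time, with ties broken by run id, so
every chart is deterministic.

Analytes carry one of four roles. *Suitability peptides* are the fixed
standard injected between samples. The *protein internal QC* (we simulate
yeast enolase 1 peptides) is spiked before digestion and therefore reports
on the entire preparation; the *peptide internal QC* (a heavy-labeled
synthetic mixture) is spiked after digestion, just before injection, and
reports only on the LC-MS. The contrast between the two is what lets a
single bad run be attributed to preparation rather than instrument.
*Endogenous* peptides are the quantities of scientific interest.

## Control charts

All charts share a guide-set baseline: the arithmetic mean and sample SD
(n − 1) of an initial run window, by default the first 10 runs of matching
type. Explicit guide run lists override `first_k`; at least 5 guide points
are required. The guide count is configuration: a longitudinal series with
a long stable history detects steps more reliably when the whole stable
period is the guide, because the 3-sigma decision is sensitive to the
sampling noise of the estimated SD.

* **Levey-Jennings**: per-run `z`-scores with a small Westgard-style rule
  set — FAIL when |z| > 3 (`1_3s`), WARN when this and the previous point
  sit on the same side with |z| > 2 (`2_2s`). With a zero-SD baseline the
  chart degenerates to "any deviation FAILs", which is the only consistent
  reading of exact guide data. The false-FAIL rate on in-control Gaussian
  data is the 3-sigma tail, 0.27%; the acceptance script re-measures it on
  10,000 simulated points.
* **CUSUM**: the two-sided tabular recurrence with slack `k = 0.5` and
  decision interval `h = 5` (standardized units), the standard choice
  tuned for sustained ~1 SD drifts; its textbook average run length under
  a 1-sigma shift is about 10.4 runs, which the simulation reproduces.
* **Moving range**: |x_i − x_{i−1}| against the individuals-chart limit
  `3.267 x mean(MR)`; when a baseline is supplied the mean MR comes from
  the guide region only, so a later variance change cannot inflate its own
  limit.
* **Trailing mean / trailing CV**: over a window of 5 runs ending at the
  current run, `CV% = 100 s / mean` with the sample SD — the same
  convention as the baseline. Worked through: the series
  (10, 10, 10, 10, 10, 20) ends with the window (10, 10, 10, 10, 20),
  mean 12, SD `sqrt(20) = 4.4721`, trailing CV 37.27%, a FAIL at the
  default 20% threshold. The threshold is configuration, not science: it
  encodes how much short-term scatter an operator tolerates.

## Isotope envelopes and the isotope dot product

A peptide's elemental composition is the residue sum plus one water;
carbamidomethylation adds C2H3NO per cysteine. The theoretical envelope is
computed by iterated truncated convolution of per-element isotope
distributions, using a natural-abundance table (C, H, N, O, S) frozen in
the code for reproducibility. Truncation to `n_peaks` (default 3) is
followed by renormalization, with the captured mass fraction recorded. A
brute-force check — exhaustive enumeration of isotopologues with
multinomial weights — agrees with the convolution to total-variation
distance below 1e-9 on random small compositions; the suite runs that
comparison every time. Heavy labels (13C6/15N2 on C-terminal K, 13C6/15N4
on C-terminal R) pin atoms to their heavy isotope: pinned atoms shift
every peak by the same nucleon count and so are excluded from the
envelope-shape convolution while still contributing to the monoisotopic
mass.

The isotope dot product (idotp) is defined here as the plain cosine
similarity between the expected envelope and the observed three peak
areas: 1 iff proportional, invariant to positive rescaling of either side,
symmetric, and strictly decreasing as M+1/M+2 are attenuated with M0
fixed. Integration software sometimes applies a square-root weighting
before the cosine; an `idotp_transform = "sqrt"` switch reproduces that
convention, but the untransformed cosine is the default because it is the
simplest scale-invariant choice and no published formula fixes the
weighting. Exact numerical agreement with any particular vendor's printed
idotp is therefore not claimed. An all-zero observation raises a distinct
undefined-score error rather than returning a low score: "no signal" and
"wrong envelope" are different failures.

## Triage rules

Each sample run is summarized by medians across the analytes of each IQC
class — medians, not means, so one misbehaving peptide cannot dominate —
yielding `eno_ratio` and `prtc_ratio` (transition area relative to the
per-analyte baseline mean), `eno_z` / `prtc_z`, the median RT deviation,
and the minimum idotp across IQC analytes. The suitability context
`ss_status` is DEGRADED when any of the last 3 suitability runs FAILed
Levey-Jennings on transition area for at least half the suitability
analytes, OK when none did, UNKNOWN when there is no suitability run yet.

Classification applies ordered rules; the first match wins, and `NA`
fields skip the rules that need them:

| rule | call | signature |
|------|------|-----------|
| R1 | ISOTOPE_ENVELOPE_LOSS | min idotp < 0.90 while both IQC ratios are normal |
| R2 | SAMPLE_PREP_FAILURE | protein IQC reduced, peptide IQC consistent (abs(z) <= 2) |
| R3 | INJECTION_LC_EVENT | both IQCs reduced, abs(RT shift) > 2 min, neighbors normal |
| R4 | MS_SENSITIVITY_LOSS | peptide IQC reduced or in sustained decline, suitability DEGRADED |
| R5 | SYSTEM_CHECK_NEEDED | same intensity evidence, suitability OK/UNKNOWN |

Envelope loss is evaluated first because it is the one failure that leaves
total areas intact — intensity rules would never reach it. R5 exists
because a sensitivity claim should be confirmed by suitability runs before
blaming the instrument; it mirrors the operator practice of queueing
suitability injections when sample IQCs start declining. "Reduced" means
a ratio below `low_ratio = 0.5`; a *decline* is `decline_runs = 3`
consecutive strictly decreasing peptide-IQC ratios ending below
`decline_ratio = 0.7`. The RT tolerance is 2 minutes. All of these are
configuration with documented defaults; the underlying observations are
qualitative, so the numbers are engineering choices, and raising
`low_ratio` monotonically increases the number of non-PASS calls (a
property the suite tests).

## The normalization ladder

Level 1 is the raw linear-area matrix of the selected runs (zero areas are
recorded as missing, because integration software emits zero for "nothing
integrated"). Level 2 is `log2` followed by per-run median centering onto
the grand median of run medians — re-centering on the grand median rather
than zero keeps values in the original intensity register. Level 3
subtracts, per analyte, the batch mean and restores the analyte grand
mean: a transparent location-only batch adjustment. Empirical-Bayes
shrinkage of batch effects is deliberately not implemented: the location
estimator is exact, testable (within-batch variances are preserved to
machine precision, injected offsets are recovered at the analytic
`SE = sd/sqrt(n)` rate), and sufficient for location batch effects; a
`scale_adjust` option additionally equalizes batch SDs when needed.
Analytes with fewer than 2 observations in an occupied batch pass through
unadjusted and are listed. No imputation is performed anywhere; CVs simply
require a minimum number of observations.

CVs are computed on the linear scale — log2-level matrices are
back-transformed first — matching clinical-laboratory convention; a
`cv_method = "geometric"` switch offers the log-normal closed form
`100 sqrt(exp((s ln 2)^2) − 1)` on the log2 SD. The ladder summary
statistic eta is the median CV% across analytes with at least `min_obs = 3`
observations. Protein rollup is the mean of peptide log2 values (sum of
linear areas at level 1); rollup choice changes protein CVs, so the method
is recorded in the matrix provenance and results are comparable only
within one scheme. The CV-versus-abundance relationship is smoothed by
locally weighted linear regression (tricube weights, span 0.5, one
robustness iteration) evaluated on a 100-point grid; local-linear
smoothing reproduces constant and linear relationships exactly, which the
suite asserts to 1e-6.

## The simulator

Areas are log-normal: `log2(area) = base + batch offset + run scale +
noise`, with the log2 noise SD derived from the target CV through
`sigma_ln = sqrt(log(1 + cv^2))`. Retention times get Gaussian jitter
(0.05 min SD), mass errors are Gaussian (2 ppm SD), and isotope areas are
the precursor area times the theoretical envelope times elementwise
log-normal noise (5% CV), so simulated in-control idotp sits near 1 and
reacts to envelope events exactly as the detector assumes. Six event
types reproduce the canonical failures: a step change in all areas;
sporadic attenuation of M+1/M+2 (x0.05); an arm-wise digestion failure
(protein IQC and endogenous x0.01, peptide IQC untouched); a single bad
injection (all areas x0.3, RT +4 min); progressive decay
(`rate^injections`, reset by maintenance); and per-(batch, analyte)
offsets ~ N(0, 0.5^2 log2). Ground-truth labels are written into the run
log; for decay, runs are labeled once the cumulative attenuation reaches
50%, the point at which the loss has materially manifested.

Default conditions: 10% area CV, suitability runs interleaved one per 8
samples (cadence in runs, since wall-clock scheduling is not simulable),
17 suitability peptides, 6 protein-IQC and 15 peptide-IQC peptides, run
scale off except where a scenario requires it. The 8-batch external-QC
scenario uses 12 QC runs and 10 samples per batch, 60 endogenous
peptides, batch offsets of 0.5 log2, and a per-run scale SD of 0.5 log2
(~41% CV): raw, un-normalized loading variation of that order is typical
of clinical-matrix studies and is the first-order effect median
normalization exists to remove. The simulator panels keep each peptide in
a single QC role (the suitability panel is simulated as carrier-protein
peptides, the peptide IQC as the heavy mixture) so that every analyte has
one unambiguous baseline; real suitability standards often contain the
IQC peptides too.

What the simulator does *not* emulate: chromatographic peak shape (a
"poor chromatography" event appears only as area loss and RT shift),
m/z-resolved spectra, missingness mechanisms of data-dependent
acquisition, autocorrelated drift, and interference between co-eluting
analytes. Passing tests therefore demonstrate that the detectors recover
the failure modes as modeled, not that the thresholds are optimal for any
particular instrument; on real data the thresholds are the tunable
surface.

## Validation scenarios and problem sizes

The mixed-failure benchmark (`simulate_failure_mixture()`) embeds all four
triage-relevant events in one experiment per seed: 22 suitability cycles
of [SS, sample, sample], a clean 10-sample guide period, three
isotope-loss runs, five digestion-failure runs, one bad injection (kept
non-adjacent to other events so it is genuinely isolated), and a decay
episode (rate 0.6 per injection) opening at a suitability-cycle boundary
and running to the end. Event positions are randomized per seed within
the post-guide region. Decay episodes open at cycle boundaries so that a
failing suitability run precedes the first materially degraded sample —
matching how decays surface in practice, where suitability injections
bracket sample blocks. Precision and recall are pooled over 200 seeds.

Other sizes used by the suite and the acceptance script: 10,000 points
for chart calibration (guide 5,000), 2,000 series for the CUSUM run
length, 1,000 seeds for step-detection power (21-run series, step at run
21, 20-run guide), 200 seeds for the ladder ordering, and 20 random
compositions for the envelope oracle. These sizes put every Monte-Carlo
margin several standard errors from its threshold while keeping the whole
suite within a few minutes on one CPU.

## Known limitations

Thresholds are engineering defaults, not fitted constants; a laboratory
should calibrate `low_ratio`, `rt_tol`, `idotp_min`, and the trailing-CV
threshold against its own history. The triage rules are per-run and
first-match; simultaneous failures collapse to the first matching class.
Batch adjustment is location(-scale) only and assumes exchangeable runs
within batch. The idotp is computed on three peaks; very large peptides
whose envelope mass extends beyond M+2 lose some discrimination.
Suitability status looks back a fixed window of suitability runs, not
wall-clock time.
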