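---
title: "Multiplex functional muscle networks: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex functional muscle networks: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model behind `musclenet`, the
tunable parameters and the reasoning behind every place where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

Six surface-EMG channels (RTEMP, LTEMP, RMAS, LMAS, RABD, LABD; 2,000
Hz) recorded during sentence reading are turned into one 48-dimensional
feature vector per sentence.

**Preprocessing** runs crosstalk suppression, a 60 Hz notch, a 20 Hz
high-pass and DC removal, in that order. The crosstalk stage is a
temporal-decorrelation source separation: channels are whitened, rotated
by a Jacobi joint diagonalization of pooled time-lagged covariance
matrices *and* time-windowed covariance matrices, and each electrode is
reconstructed from its single dominant source (sources are assigned
greedily so two electrodes can never collapse onto the same source).
The windowed covariances matter: burst-structured EMG is nonstationary,
and sources with independent activation envelopes are far better
separated by their time-varying power than by their (similar) spectra.
Filter realizations are a second-order IIR notch (quality factor 30) and
a fourth-order Butterworth high-pass, both run forward-backward (zero
phase) over 1 s reflect-padded signals; cutoffs follow the acquisition
protocol, realizations are standard practice.

**Nodal features.** Each channel is reduced to a local standard
deviation series with non-overlapping windows of `L = 100` samples
(50 ms at 2,000 Hz; the trailing remainder is dropped — the window
index arithmetic implies disjoint blocks), then to a natural visibility
graph with the *strict* inequality, so a collinear intermediate point
blocks visibility. Density lives in (0, 1]; the spectral radius ratio
(principal adjacency eigenvalue over mean degree) is >= 1, with equality
for regular graphs. The principal eigenvalue comes from LAPACK
(`eigen(symmetric = TRUE)`) rather than a hand-rolled power iteration;
it is the standard tool and at least as accurate.

**Edgewise features.** Rectified channel pairs are reduced to jointly
selected 1 s epochs around activity bursts. Burst detection is not
specified by the protocol; we use the smoothed RMS envelope (50 ms
window) against a `median + 1.5 MAD` threshold, held for at least
100 ms on both channels jointly (identical windows for the pair, since
the coherence estimator requires simultaneous segments). Three
robustness refinements are part of the design:

* supra-threshold runs separated by dips shorter than 0.5 s are merged
  (bursts of one phrase belong together), and a merged run qualifies on
  its supra-threshold *content*, so chained noise blips cannot pass;
* when the primary threshold finds nothing, detection retries at 1.0
  and 0.5 MAD before declaring the pair unusable;
* a lone epoch is widened to two adjacent epochs centred on the burst,
  because a single epoch leaves the significance threshold undefined.

Welch magnitude-squared coherence uses a 1,024-point Hamming window at
75% overlap with a 4,096-point FFT (frequency grid fs/4096). Two
estimator details are deliberate. Each segment is linearly detrended,
and each windowed segment is normalized to unit power. The
normalization cancels slow *common gain* exactly: speech loudness rises
and falls for all muscles together, and a shared multiplicative gain
otherwise inflates the coherence estimate by a kurtosis factor that
scales like the significance threshold itself, so no amount of data
washes it out. Sliding windows never span the junction between
non-adjacent epochs (junction discontinuities occur at identical sample
positions in both channels and would masquerade as broadband
coherence); epochs that were adjacent in the recording remain one
contiguous block.

The effective segment count uses the disjoint-block convention,
refined to count blocks *within* contiguous segments:
`L_hat = sum_blocks floor(block_length / 1024)`. A disjoint block cannot
span a discontinuity, so this count is honestly conservative exactly
when the epoch set is fragmented — which is what makes the significance
gate `S = 1 - 0.05^(1/(L_hat - 1))` hold its nominal level on short
recordings. "A peak above significance" is read literally: any single
bin in the band above `S` opens the gate; the band weight is then
`atanh(sqrt(mean msc))` over **all** bins of the band (the printed rule
averages the band, not only supra-threshold bins). Band membership is
half-open `[low, high)` with the gamma upper edge inclusive at 60 Hz, so
4–60 Hz is partitioned without double counting. The Fisher transform is
applied to the coherency magnitude `sqrt(msc)`, the convention of the
coherence literature.

**Graph descriptors** (per band layer): mean nodal strength
`2 sum(w) / 6`; strength assortativity as the edge-weight-weighted
Pearson correlation of endpoint strengths (the formulation that honors
"(weighted) degrees" for weighted graphs; undefined and reported as
missing when fewer than two positive edges exist or strengths have zero
variance); global efficiency with edge lengths `1/w` (the dominant
convention for coherence-weighted networks; disconnected pairs
contribute zero); Onnela-type geometric-mean clustering on weights
normalized by the layer maximum (bounded [0, 1]; nodes with fewer than
two positive neighbours get 0); laterality as right-minus-left
homologous edge weight normalized by the **same band layer's** 15-weight
sum (keeping each band's index self-contained; the cross-layer
normalization is the obvious alternative and would only rescale all
three bands by a common factor). Missing edges propagate to missing
band features, never silently to zero.

**Kinematics.** Jaw traces are low-pass filtered (second-order
Butterworth, 15 Hz, zero lag), reduced to the Euclidean distance to the
lower-incisor reference, and segmented at velocity zero crossings
(central differences; crossings and peak speeds are interpolated to
sub-sample accuracy, which is what lets quarter-period identities hold
to 2% at 100 Hz). Half-cycles below 5% of the global excursion are
discarded as noise. Mean acceleration over the accelerating phase is
computed as peak speed over acceleration time — identical to the mean
absolute second derivative for a monotone velocity rise, and exact
rather than quadrature-limited. Stiffness is global (max speed over max
excursion) per sentence rather than per cycle, following the "maximum
speed to maximum distance" phrasing; a per-cycle variant would average
ratios instead and is a one-line change.

## Factor reduction

Features are standardized implicitly (correlation-matrix ML factor
analysis via `factanal`), since the 48 features mix units. The factor
count comes from parallel analysis — observed correlation eigenvalues
against the 95th percentile of 100 random-normal datasets of the same
shape; the retained count is the number of *leading* eigenvalues above
their simulated quantile. The rotation is oblimin (quartimin, gamma =
0, the conventional default) by the oblique gradient-projection
algorithm, implemented in the package because no installed package
provides it; likewise tenBerge factor scores
(`W = R^{-1/2} C (C'C)^{-1/2} Phi^{1/2}`, `C = R^{-1/2} Lambda Phi^{1/2}`),
which preserve the inter-factor correlations exactly on the fitting
sample. Heywood cases are reported with a warning, not clipped;
non-positive-definite correlation matrices are ridge-regularized with a
message. Cumulative variance is the sum of squared structure loadings
over the feature count. Primary components use the absolute-loading
threshold 0.3. Sentences are treated as independent rows for the
factorization, as the sentence-level record count implies.

## Inference

Disease-effect models are `feature ~ group * node + (1 | subject)` (six
muscles) or `group * band` (three bands), with Satterthwaite F tests and
estimated-marginal-mean ALS-vs-control contrasts Bonferroni-adjusted
within one model's family (6 nodes or 3 bands). Marginal and conditional
R² follow the Nakagawa–Schielzeth variance partition. The stepwise
kinematic models start from `group + all factor scores`, drop fixed
effects backward on AIC under ML with the random intercept kept
throughout, and refit the final model with REML.

Classification uses RF (500 trees), radial SVM (kernel width from the
median-distance heuristic, unit cost) and KNN (k = 5, standardized
inputs) under stratified five-fold cross-validation repeated ten times.
Folds are grouped by subject by default — sentences of one subject never
span train and test, avoiding the leakage that record-wise folds invite
with 19 near-replicate sentences per subject; record-wise folds remain
available (`grouping = "record"`). Out-of-fold probabilities are pooled
per repeat; precision, recall and AUC are averaged over repeats, and the
report-level F1 is the harmonic mean of the report's precision and
recall, so the F1 identity holds for every report.

## The synthetic cohort: what it emulates, and what it does not

The generator exists so every stage is testable without human
recordings. Per channel the model is an envelope-driven broadband
carrier plus structured nuisance:

* **Phrase gate** (shared): breath-group-scale loudness alternation,
  logistic-squashed so phrases are plateaus separated by near-silent
  pauses, with an activity hump anchored to the sentence interior. Its
  spectral content stays below the 4 Hz edge of the lowest analysis
  band, so it creates the joint activity stretches the epoch selector
  needs without masquerading as coupling.
* **Burst train** (per channel): half-sine bursts at Gamma-distributed
  inter-burst intervals (mean 200 ms), log-normal amplitudes of unit
  mean whose CV is scaled by the profile's `envelope_cv_scale`.
* **Shared band drives**: unit-SD Gaussian processes band-passed to
  4–12, 12–30 and 30–60 Hz, *amplitude-modulating* the carrier (riding
  on the slow gate only). A purely additive low-frequency drive would
  be annihilated by the 20 Hz high-pass before rectification; amplitude
  modulation is how common drive actually survives rectified-signal
  coherence, and gating the drives by the slow envelope only keeps
  their band content from smearing across bands.
* **Nuisance**: distinct per-muscle carrier bands (which is also what
  makes the sources identifiable for the separation stage), a common
  60 Hz line component, per-channel DC offsets, sensor noise, and a
  fixed nearest-neighbour crosstalk mixture (leakage 0.1).

Disease profiles scale this model. `amplitude_scale` (symptomatic 0.7,
prodromal 0.85) lowers the envelope-driven gain; `coupling_scale`
(0.6 / 0.8) weakens the shared drives; `envelope_cv_scale` (1.5 / 1.25)
disperses burst amplitudes, makes burst timing more erratic, drops
occasional bursts, and — through the same knob — *fragments the phrase
gate*: effortful speech concentrates myoelectric output in fewer,
relatively larger excursions. That last mechanism is what produces the
nodal visibility-graph signature of disease (density down, spectral
radius ratio up): regular alternating phrases give a dense, homogeneous
visibility graph, while a single dominant excursion creates hub
structure. `right_left_asymmetry` (healthy default 0.15, reduced toward
0 with disease) lateralizes the drive injection; `kinematic_slowing`
divides the jaw cycle rate. ALS subjects draw their profiles around
stage means with 5% multiplicative jitter; controls are the identity
profile exactly.

A feature-level companion generator draws 48-feature records directly
from a ten-factor oblique latent model whose factor-to-feature pattern
mirrors the reported primary components (primary loadings 0.8, with
0.85 for factors carried by three or fewer features — few-indicator
factors need stronger markers to be identifiable, a standard
psychometric design rule; inter-factor correlation 0.15). Group effects
shift the nodal and band-connectivity factors by 1.8 within-record SD
for symptomatic subjects (prodromal 60%), the clustering and
antagonist-laterality factors by a third of that and the remaining
factors by a fifth, mirroring the reported gradient of effects across
feature families; subjects carry factor intercepts with SD 0.4.

The generator does **not** emulate: hum harmonics beyond 60 Hz,
electrode failures or motion artifacts, real inter-muscle coupling
magnitudes (stipulated, not fitted), articulatory or acoustic structure,
or longitudinal change. Passing tests therefore demonstrate internal
consistency, directional fidelity and statistical calibration of the
pipeline — not clinical performance on human data.

## Problem sizes used by the test suite

The suite exercises the full study design (25 subjects × 19 sentences
− 2 dropped recordings = 473 records of 5 s) once, for the structural
count. Simulation-based calibration uses scaled designs chosen to keep
each property measurable at desk scale: mixed-model power and null runs
use 5 + 5 subjects × 5 sentences × 5 s over 30 seeded cohorts;
classifier properties use the feature-level generator at the full
473-record design over 10 (power) and 20 (null) seeds; gating
properties use 5–12 s recordings over 20 seeds. All seeds are fixed in
the tests.

## Known limitations

* With 1 s epochs and a 1,024-sample window, isolated epochs carry
  barely two effective Welch segments; the per-block `L_hat` keeps the
  gate conservative there, at some cost in detection power on very
  short or fragmented recordings.
* The band-level false-positive rate of the "any bin above S" gate is
  bin-max dependent; under independence it is held well below 25% by
  the conservative `L_hat`, but it is not a calibrated 5% band-level
  test.
* Assortativity is frequently undefined on sparse gated layers (fewer
  than two positive edges); it is reported as missing, and imputation
  is left to the factor-analysis screening.
* The oblimin implementation uses the standard gradient-projection
  scheme with random-free initialization at the identity; pathological
  loading patterns could converge to local optima, which the recovery
  tests bound but do not exclude.
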