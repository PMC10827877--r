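---
title: "Methods: resting-state fNIRS connectivity and graph topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state fNIRS connectivity and graph topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nirsgraph` analyses resting-state continuous-wave NIRS recordings:
multichannel optical intensity at two wavelengths (760/850 nm, 7.81 Hz,
64 source–detector channels at 3 cm separation), converted to oxy- and
deoxyhemoglobin concentration changes, summarized as functional
connectivity between 14 cortical regions of interest, characterized with
weighted graph metrics, and compared between a previously malnourished
(PEM) and a control (CON) arm with a childhood-SES covariate. This
vignette documents the model, the numerical choices, and what the
synthetic cohort generator does and does not emulate.

## Preprocessing model and assumptions

**Channel quality.** A channel that optically couples to the scalp
carries the cardiac pulsation coherently at both wavelengths. We band-pass
both wavelength series to the cardiac band (default 0.5–2.0 Hz — wide
enough for resting adult heart rates; the exact band is configurable),
take instantaneous phases from the analytic signal, and score the channel
with the phase-locking value |⟨e^{i(φ₇₆₀−φ₈₅₀)}⟩| over valid samples.
Channels scoring strictly below 0.85 are rejected. Phase locking of two
independent noise series concentrates near 1/√N, so the statistic cleanly
separates coupled from dead channels.

**Motion artifacts.** Samples where the 1-s moving standard deviation of
the log-intensity exceeds 3× its median (either wavelength) are flagged
and dilated by half a window. This replaces interactive inspection with a
deterministic, reproducible rule; both parameters are configurable.
Channels with strictly more than 25% flagged samples are rejected;
participants with strictly more than 50% rejected channels are excluded.
All cut-offs are strict inequalities, following the study's wording.

**Filtering.** A Butterworth band-pass of order 4 to 0.01–0.08 Hz,
applied with zero phase. Numerically we multiply the FFT of the
reflection-padded signal by the squared magnitude response of the
`signal::butter` design — identical in response to a forward–backward
(filtfilt) pass and exact for arbitrarily narrow bands, where recursive
filtering with short padding is unreliable (the 0.01 Hz edge at 7.81 Hz
corresponds to an impulse response of roughly a thousand samples). The
filter is applied to the intensity fluctuation around each valid
segment's mean, preserving positivity, which equals band-passing the
optical density to first order.

**Optical density and hemoglobin.** Per good segment,
ΔOD = −log₁₀(I/Ī). The modified Beer–Lambert law
ΔOD(λ) = Σ_c ε_c(λ)·Δc·d·DPF(λ) is inverted per sample as a 2×2 system,
with base-10 extinction coefficients shipped as data (units 1/(µM·cm),
replaceable by the user) and the differential pathlength factor from the
published general age/wavelength equation
DPF = 223.3 + 0.05624·A^0.8493 − 5.723·10⁻⁷λ³ + 0.001245λ² − 0.9025λ.
The equation was fitted over roughly 690–832 nm; following common
practice for 850 nm hardware we accept wavelengths up to 860 nm as a mild
extrapolation (the accepted range is an argument; outside it the function
errors).

**PCA confound filter.** Per chromophore, the time × channel matrix is
decomposed by SVD and recomposed without its first component. At rest the
dominant cross-channel covariance is systemic physiology (scalp blood
flow and blood-pressure waves inside the spontaneous band), so removing
one spatial component removes most of it. Two consequences matter for
interpretation. First, because the systemic gain vector and the global
cerebral mode are both near-uniform positive channel vectors, the filter
removes each participant's *global* covariance level along with the
systemic signal: connectivity after the filter is measured relative to
the participant's own global mode, and diffuse (matrix-wide) group
differences are attenuated while block-localized differences survive.
Second, the filter can make weakly coupled channel pairs slightly
anti-correlated; downstream graph analysis takes absolute weights.

**Prewhitening.** An AR model per channel (Yule–Walker, AIC order
selection up to 20) yields innovation series for statistics that assume
serial independence. Prewhitening a signal confined to a 0.07 Hz band
flattens its spectrum across the full Nyquist range and thereby
re-weights variance toward residual broadband noise; empirically this
collapses band-limited cross-channel correlation. Connectivity is
therefore computed on the PCA-filtered (not prewhitened) concentration
signal by default (`use_prewhitened = FALSE`), matching the description
of the correlation analysis as operating on the PCA-filtered signal;
prewhitening remains available and fully tested.

## Connectivity

Two hundred 60-s segments are drawn uniformly with replacement (200
non-overlapping minutes cannot fit a 12-minute recording, so overlap is
implied), retained if at least 90% of their samples are valid (inclusive
bound), correlated per channel pair over the segment's complete valid
rows, and averaged across segments. The mean matrix is Fisher-transformed
(z = atanh r, clipping |r| ≥ 1 with a warning) and averaged into ROI
blocks; within-ROI diagonal entries are computed but group tests use the
91 distinct ROI pairs. An effective-sample-size subtlety: a 60-s segment
of a 0.01–0.08 Hz band-limited signal contains only ≈2·B·T ≈ 8
independent samples, so single-segment correlations are noisy and the
segment averaging is what stabilizes the estimate.

## Graph topology

Channel-level mean Pearson matrices (the un-averaged, channel-wise
matrices of the same PCA-filtered signal) are absolutized — negative
channel correlations have no agreed interpretation — and thresholded at
0.01…0.85 in steps of 0.01, keeping superthreshold weights (strict
inequality). Metrics: degree; global efficiency (mean inverse shortest
distance, edge length 1/w, 1/∞ = 0); local efficiency (global efficiency
of each node's neighbour subgraph, nodes with <2 neighbours scoring 0);
characteristic path length (mean distance over connected pairs,
disconnection flagged); weighted clustering (Onnela geometric-mean
triangle intensity over weights normalized by the maximum, with a binary
mode for cross-checks). The 1/w length convention and the Onnela
formulation follow the standard brain-connectivity toolbox; kernels are
compiled (Floyd–Warshall all-pairs distances — exact and cache-friendly
at 64 nodes) and verified in the test suite against brute-force R
implementations and igraph.

**Null networks.** Each thresholded graph is randomized by
degree-preserving edge swaps (10 attempts per edge) followed by random
reassignment of the original weight multiset onto the rewired edges, so
every null conserves node count, edge count, degree sequence and weight
multiset; graphs admitting no swap (complete or single-edge) keep their
topology with shuffled weights. Real metric curves are normalized by the
mean of all participants' null metrics at each threshold (the grand-mean
reading; per-participant normalization is available via
`normalization = "participant"` — note it answers a different question,
"how far is this individual network from its own rewired ensemble", and
inverts the group contrasts of raw metrics in our simulations). The
small-world index is SW = NormCC/NormLL.

**Threshold range and AUC.** The analysis range is the maximal contiguous
run of thresholds where the cohort-average matrix is fully connected
(Kmin ≥ 1 and CCmin ≥ 0 — the latter vacuous for nonnegative weights, a
stricter cut-off is available) and small-world (SW ≥ 1, with SW computed
from the average matrix's own nulls); ties resolve toward lower
thresholds. Normalized metrics are summarized by the composite trapezoid
over the range (grid spacing is part of the measure). Because the null
metric means vary smoothly with threshold, `null_subgrid = k` evaluates
them on every k-th in-range threshold with linear interpolation — with
k = 8 the AUCs change by well under 10% (asserted in the tests) at an
eight-fold reduction of null-network computation.

## Group statistics

For each outcome (ROI-pair z, metric AUC), F for the group term of
y ~ intercept + group + SES via extra sums of squares, df = (1, n−3); the
p-value comes from 2,000 random permutations of the cases with the
add-one convention p = (1 + #{F* ≥ F})/(1 + n_perm), computed in a single
matrix pass per outcome. Benjamini–Hochberg correction is applied across
the ROI-pair family. Demographics follow the study's reporting: pooled
two-sample t from group summaries (CON − PEM orientation), 1-df Pearson
chi-square without continuity correction for sex, two-sided Fisher exact
for handedness. The "mixed" aspect of the original analysis names no
within-subject factor; the default model is a one-way ANCOVA per outcome
and per chromophore (HbO by default — the reporting chromophore is not
stated in the source).

## The synthetic cohort generator

The generator defines the conditions under which the pipeline is
validated. Each participant's two-wavelength intensity is built from:

* a **cerebral component**: band-limited (0.01–0.08 Hz) Gaussian process
  with channel correlation given by a latent matrix (below), amplitude
  1 µM HbO with HbR = −0.5·HbO, projected onto wavelengths by the forward
  Beer–Lambert model with the participant's age-specific DPF;
* a **systemic low-frequency oscillation**: one shared band-limited time
  course, channel-specific gain U(0.5, 1.5), amplitude 1.5 µM
  HbO-equivalent — deliberately larger than the cerebral signal, which is
  what makes the PCA filter's first component well-defined;
* **cardiac (≈1.1 Hz), respiratory (0.2 Hz) and Mayer-wave (0.1 Hz)**
  sinusoids with channel-specific amplitude and phase (cardiac amplitude
  0.015 OD units, calibrated so live channels score ≈0.97 phase coherence
  and channels drawn "dead" — cardiac amplitude ≈0 — score near zero);
* **white measurement noise** (0.003 OD) and **Poisson motion artifacts**
  (2/min): decaying spikes and 1–3 s baseline shifts of random sign;
* intensity I = I₀·10^(−ΔOD) with a positive channel baseline.

The latent correlation matrix has within-ROI coupling 0.6, between-ROI
baseline 0.15, a frontal coupling block (prefrontal and Broca) at 0.45,
and a long-range integration backbone at 0.7 — the homotopic left/right
blocks of the non-frontal ROIs plus parietal-association blocks
(premotor/motor/lateral-temporal to inferior parietal). Group effects in
the PEM arm: the frontal block is deepened by +0.3 (hyperconnectivity on
existing strong edges); lattice-ward rewiring scales with
`clustering_boost` (0.6), weakening the backbone to the between-ROI
baseline while reinforcing within-ROI coupling by +0.15 — raising
clustering and local efficiency while removing the interhemispheric
highways that carry global efficiency. The arms' mean latent correlation
is explicitly matched (`match_baseline`), because the PCA filter removes
each participant's global covariance mode and an unmatched baseline
would re-emerge inverted rather than as a group difference. Between-
subject variability is Fisher-z jitter (SD 0.045) on all latent
correlations, calibrated to put cohort-level effects in the moderate-F
regime typical of resting-state group studies; matrices are projected to
the nearest positive-semidefinite correlation (Higham's algorithm —
one-shot eigenvalue clipping measurably distorts block structure).

What the generator does **not** emulate: real optode-distance-dependent
coupling geometry, heterogeneous hemodynamic response shapes, slow
drifts outside the analysis band, non-Gaussian physiology, or any
spatial autocorrelation beyond the ROI blocks. Passing recovery tests
therefore demonstrates that the pipeline detects the *kind* of effects
it targets under realistic noise, masking and confound conditions — not
that it would behave identically on any particular real dataset.

## Problem sizes used by the validation suite

The generator's scientific defaults are the study conditions (720-s
recordings, 200 segments, 100 nulls, 2,000 permutations, 25 + 28
participants). The automated validation suite exercises the full pipeline
at reduced sizes chosen once: 300-s recordings, 50 segments, 25 null
networks, 500 permutations, null means on every 8th in-range threshold,
across 20 independently seeded cohorts at the full 25/28 size and the
full 64-channel montage. Smaller unit fixtures use a 16-channel montage
and 120-s recordings. The end-to-end criterion — every boosted frontal
pair recovered with PEM > CON among the top of the positive-direction
p-ranking, and AUC directions CC: PEM > CON, LE: PEM > CON,
GE: CON > PEM — is required in at least 90% of the 20 seeds.

## Known limitations

* The PCA filter's global-mode removal means diffuse hyper- or
  hypo-connectivity is structurally hard to detect; group differences
  must be spatially structured to survive. This is a property of the
  method, not of the implementation.
* Prewhitening, while implemented faithfully, is unsuitable as an input
  to band-limited correlation analysis (see above); the robust
  AR-IRLS variant of the original toolbox is out of scope.
* "Manual inspection" of artifacts is replaced by the deterministic
  moving-std detector; with confound-free, high-amplitude slow waves its
  median-scaled threshold can flag legitimate signal epochs (raise
  `artifact_z_thresh` in such regimes).
* Threshold-range selection on near-complete graphs is degenerate
  (rewiring cannot alter a complete topology, so SW ≡ 1); this arises
  only if confound removal is skipped.
* Recordings are read from a plain-text container (or built in memory);
  vendor formats and HDF5-based containers are not parsed.
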