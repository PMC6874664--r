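---
title: "Normative atlas z-scoring of phase-amplitude coupling: models and methods"
author: "pacAtlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative atlas z-scoring of phase-amplitude coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intracranial EEG biomarkers of the epileptogenic zone — here the coupling
between high-frequency activity (HFA, > 150 Hz) and the phase of the local
slow wave (3–4 Hz) during slow-wave sleep — vary systematically across the
cortex even in healthy tissue: occipital cortex couples more than
superior-temporal or superior-frontal cortex. A raw coupling value at an
electrode is therefore hard to interpret. The idea implemented by this
package is the intracranial analogue of statistical parametric mapping:
standardise each electrode's coupling against an anatomically matched
*normative* distribution estimated from non-epileptic recording sites of
other patients, and work with the resulting z-score.

The pipeline has four stages, each a package module:

1. **Signal → MI.** Per channel, the mean-vector-length modulation index
   over ten 30-second slow-wave-sleep epochs on a common average reference.
2. **MI → atlas.** At every vertex of an average-brain surface mesh, the
   mean and SD of MI over the *k* closest non-epileptic sites
   (default *k* = 30) pooled across an atlas cohort.
3. **Atlas → z-scores.** `z = (MI − mean_v) / sd_v` at each electrode's
   vertex; per-patient summaries: the SOZ / non-SOZ medians and the
   *subtraction MI z-score* (mean z over resected minus mean z over
   preserved electrodes).
4. **z-scores → inference.** Wilcoxon signed-rank on paired medians;
   multivariate logistic models of surgical success with ROC/AUC,
   fixed-sensitivity operating points, and leave-one-out cross-validation.

## The modulation index

For a phase series $\varphi(t)$ (analytic phase of the 3–4 Hz component)
and an amplitude envelope $A(t)$ (analytic envelope of the 150–300 Hz
component),

$$\mathrm{MI} = \left| \frac{1}{N} \sum_t A(t)\, e^{i\varphi(t)} \right|.$$

This is the classical mean-vector-length definition. It is non-negative,
bounded by $\overline{A}$, invariant under a global phase rotation, and
linear in envelope gain. For the envelope family
$A(t) = 1 + c\cos\varphi(t)$ with uniform phase coverage, MI equals $c/2$
exactly — the package's primary analytic oracle. An envelope-normalised
variant $\mathrm{MI}/\overline{A}$ is available via `normalize = TRUE`;
the unnormalised form is the default because downstream z-scoring absorbs
amplitude scale anyway, and because the choice then only matters for the
raw MI maps. Recording units are passed through unchanged: they rescale
raw MI but cancel in every z-score.

Chance level: under independence of $A$ and $\varphi$ the complex mean has
modulus of order $\sqrt{E[A^2]/(2N)}$. The familiar
$3\,\mathrm{sd}(A)/\sqrt{N}$ bound is a genuine 3-sigma bound only when the
envelope's variability dominates its mean (for an exponential envelope it
is exact); for a high-mean envelope it understates the chance level. Tests
of the chance-level property therefore use exponential envelopes, and the
data-driven null uses block permutation (`miPermutationNull()`), which
preserves envelope autocorrelation while destroying the phase-envelope
alignment.

## Signal processing choices

* **Common average reference.** Each included channel has the
  instantaneous mean over included channels subtracted; artifact channels
  are excluded from the reference and dropped, never interpolated.
* **Filters.** Zero-phase (forward-backward) Hamming-window FIR band-pass.
  The order spans three cycles of the band's low edge — 1000 taps for the
  3–4 Hz band at 1000 Hz, 20 taps for 150–300 Hz. Measured on sinusoids,
  this passes 3.5 Hz at unit gain and leaves < 10⁻⁶ residual at 10 Hz.
  Zero-phase application matters: phase distortion would bias the coupling
  phase directly.
* **Edge handling.** One second is trimmed from each end of every epoch
  after filtering and the Hilbert transform, suppressing filter and
  analytic-signal transients before MI is computed (`edgeTrim`, default
  1 s of a 30 s epoch).
* **Analytic signal.** FFT-based Hilbert transform; phase is zero at the
  band-passed signal's positive peak and lies in $(-\pi, \pi]$.
* **Epochs.** Ten 30-second epochs by default (`EpochSpec`); epoch
  selection (sleep staging) is upstream of this package and
  caller-supplied.

## The normative atlas

* **Distance.** "Closest" is 3-D Euclidean distance in average-brain
  millimetre coordinates. Geodesic surface distance would be a defensible
  variant but is not implemented: at typical inter-electrode spacings the
  ranking of near neighbours rarely differs, and Euclidean distance is
  deterministic and fast.
* **Neighbourhood.** At each mesh vertex the *k* = 30 closest pool sites
  (ties broken by pool row order, documented for reproducibility); mean
  and *sample* SD (denominator *k* − 1, so *k* ≥ 2 is enforced).
* **Degenerate SD.** A zero normative SD (possible with duplicated MI
  values in tiny pools) yields an undefined z (`NA` with a warning), never
  ±∞, and such electrodes are excluded from summaries.
* **Vertex indexing.** Vertex and face indices are 1-based everywhere in
  the package and in its file formats, matching both R convention and the
  OBJ format; any 0-based convention is converted at the format boundary.
* **Self-normalisation.** When the scored patient contributed to the pool,
  the atlas is rebuilt without that patient's sites (`loo = TRUE` scores a
  whole cohort that way; `excludePatient` does one patient). Cross-cohort
  scoring — patients disjoint from the pool — uses the full pool. Both
  modes are exposed because published usage does not pin down which was
  applied within the atlas cohort.

With *k* equal to the pool size the procedure degenerates to global
standardisation — a useful exact identity used in the tests.

## Outcome statistics

* **Wilcoxon signed-rank** (`wilcoxonSignedRank()`): zero differences
  dropped, midranks for ties, exact two-sided p by dynamic programming
  over the rank-sum distribution (identical to full sign enumeration) for
  n ≤ 25, tie-corrected normal approximation beyond; the signed z is
  always reported.
* **Logistic models** (`fitLogistic()`): maximum likelihood via IRLS
  (`stats::glm`, convergence 10⁻¹², ≤ 100 iterations); Wald 95% CIs
  `exp(β ± 1.96 se)` and Wald p-values; Nagelkerke R² (with Cox–Snell also
  emitted) as the conventional SPSS-style pseudo-R²; likelihood-ratio
  model p. Collinear designs are refused; quasi-separation (|β| > 15 on a
  standardised predictor, or non-convergence) is flagged with a warning.
  The three model variants: *full* (11 predictors), *no-mi* (drops the
  subtraction MI z-score), *no-soz* (drops the two SOZ-dependent
  variables, keeps the MI score).
* **ROC/AUC** (`rocAuc()`): AUC as the normalised Mann–Whitney U with
  half credit for ties; p-value against AUC = 0.5 from the tie-corrected
  normal approximation of U (the choice of AUC test is the package's own;
  published usage does not state one). The operating point rule
  (`specificityAtSensitivity()`): maximum specificity among thresholds
  reaching the target sensitivity (default 0.86), with the achieved
  sensitivity reported alongside.
* **Cross-validation** (`leaveOneOutProbs()`): n refits, each predicting
  the held-out patient; non-estimable folds yield `NA` with a message.
  Agreement between full-fit and cross-validated probabilities is
  summarised by Pearson correlation (`pearsonCorrelation()`, t-based p).
* Significance is two-sided at 0.05 throughout; no multiple-testing
  correction is applied, matching the analysis the battery reproduces.

## The synthetic-data generator

The generator exists so that every stage is testable without clinical
recordings, which are not publicly available for this kind of data.

**Signals** (`simulatePacSignal()`):
$x(t) = a_s \sin(2\pi f t) + (1 + c\cos\varphi(t))\, a_h g(t) + \varepsilon(t)$
with $g$ band-limited unit-variance noise in the amplitude band and
$\varepsilon$ white. Defaults emulate clinical slow-wave sleep ECoG at
1000 Hz: slow wave 150 µV at 3.5 Hz, HFA 10 µV in 150–300 Hz, 5 µV noise.
The coupling depth $c \in [0,1]$ is the ground truth; the normalised MI of
such a signal converges to $c/2$.

**Cohorts** (`simulateCohort()`): per patient, electrodes sampled without
replacement on a mesh (a deterministic sphere at 70 mm radius stands in
for the cortical surface); MI = smooth spatial field + i.i.d. site noise
(SD 0.08 around a baseline 0.5, the minimal structure under which k-NN
pooling is meaningful, with an optional posterior hotspot emulating
elevated occipital coupling); a spatially contiguous SOZ (15% of sites)
elevated by δ site-noise SDs (default δ = 1, consistent with the
magnitude of reported SOZ/non-SOZ contrasts); a spike halo; a resection
mask covering the halo and all or 60% of the SOZ depending on the
patient's incomplete-resection status. Covariates follow documented
distributions (age uniform 4–44 years; binary rates as in
`cohortParams()`; AED count 1 + Poisson(1.5); resection size derived from
the resected fraction, clamped to 0.6–91.6% of hemisphere). Outcome is
Bernoulli with logit equal to the generating coefficient vector — by
default the full-model odds ratios of the outcome battery — applied to
mean-centred predictors around a 73% marginal success rate. The
generating δ and β are returned for recovery tests.

What the generator does **not** emulate: seizure dynamics, spike
morphology, volume conduction, non-stationary sleep architecture,
inter-electrode correlation of MI noise, and real cortical geometry.
Passing tests therefore demonstrate the pipeline's correctness and its
statistical behaviour under the stated assumptions — not clinical
performance on real recordings.

## Experiment sizes and fixed conditions

The package's property experiments use: calibration of leave-one-patient-
out z-scores on 47 patients × 70 electrodes (≈ 2400 held-out
non-epileptic sites); group-contrast power and type-I runs of 100
replicates at 50 patients × 100 electrodes; model-contrast runs of 100
cohorts of n = 123; and the neighbourhood sweep k ∈ {10, …, 60} on a
123-patient cohort. The sphere mesh for atlas work has 410 vertices. For
the model-contrast experiment the outcome's dependence on the subtraction
MI z-score is set to 4 log-odds per z unit — about one logit per cohort-SD
of the score, i.e. a deliberately strong dependence; the generator default
stays at the reported-odds-ratio scale (log 1.45), under which the MI
term's incremental contribution is small because the subtraction score
partly overlaps with resection-completeness information.

## Known limitations

* Euclidean (not geodesic) neighbourhoods; hemispheres are treated exactly
  as the supplied mesh/coordinates encode them.
* No spatial smoothing or age stratification of the atlas.
* MI is the mean-vector-length variant only; Kullback–Leibler (Tort) MI
  and comodulograms are out of scope.
* Epoch selection, electrode localisation, and spatial normalisation all
  happen upstream; the package consumes their outputs.
* The EDF reader is deliberately minimal (single common sampling rate,
  annotation channels skipped); EDF writing is not supported.
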