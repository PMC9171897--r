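---
title: "Quantifying in vivo methionine oxidation stoichiometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in vivo methionine oxidation stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosquant)
```

# The measurement model

mosquant quantifies the fraction of a methionine site that is oxidized in
vivo, from samples in which every remaining unoxidized methionine was
force-oxidized ("blocked") with ¹⁸O-labeled peroxide at lysis. After
blocking, each peptide exists as two chemically identical species differing
only in the isotope of the sulfoxide oxygen: light (¹⁶O, oxidized in vivo)
and heavy (¹⁸O, blocked in vitro). The methionine oxidation stoichiometry
is the light fraction, MOS = L/(L + H).

Three layered models take the raw spectra to that number.

## 1. Envelope overlap and its correction

The ¹⁸O–¹⁶O offset is 2.004246 Da, while two ¹³C isotopologue spacings are
2.0067 Da. At a resolution of 120,000 (at m/z 200) these 2.5 mDa are not
resolved for tryptic peptides, so heavy isotopologue *k* and light
isotopologue *k+2* appear as a single centroid. We therefore model the
heavy species' envelope as the light envelope shifted by exactly two
aggregated (unit-mass) isotopologue positions, and work with aggregated
envelopes rather than fine structure, matching what centroided MS1 peak
picking yields.

Observed channel intensities then mix the true species signals linearly:

$$\begin{pmatrix} y_\text{light} \\ y_\text{heavy} \end{pmatrix} =
\begin{pmatrix} w_{LL} & w_{LH} \\ w_{HL} & w_{HH} \end{pmatrix}
\begin{pmatrix} L \\ H \end{pmatrix},$$

with weights that are sums of theoretical envelope abundances over the
channel index sets. With the default channels — light = light
isotopologues {0, 1}, heavy = heavy isotopologues {0..K} — the light
channel is spillover-free ($w_{LH} = 0$) and only the heavy channel is
contaminated ($w_{HL} = \sum_{k \ge 2} a_k$). The observed regression
slope $b$ of light on heavy then inverts in closed form to the true ratio
$\rho = (b\,w_{HH} - w_{LH}) / (w_{LL} - b\,w_{HL})$. The inversion is
exact against a forward simulation to below $10^{-9}$ across
$\rho \in [0.01, 10]$.

Envelopes are computed by truncated convolution of per-element natural
isotope distributions (binary exponentiation per element), against a pinned
abundance table shipped as a plain-text resource. The default K = 6
isotopologues per species cover >99.9% of the envelope mass for tryptic
peptides. An exhaustive one-atom-at-a-time polynomial expansion serves as
the independent oracle in the tests (total variation < $10^{-8}$).

## 2. Per-run ratio estimation

For each peptide × charge × run target, traces are extracted per
isotopologue (default 10 ppm tolerance, ±1.0 min window around the
evidence retention time; the most intense in-tolerance peak per scan,
deterministic). A Gaussian or Gaussian-mixture model (1–3 components,
BIC-selected) is fit to the summed raw trace in the retention-time
dimension; the component nearest the predicted retention time delineates
the elution peak (±3σ). Fitting only delineates the peak — quantification
keeps the raw intensities inside the bounds, because the downstream slope
regression is defined on summed observed intensities. Consecutive
isotopologues are linked into a cluster only if adjacent traces share a
cosine similarity ≥ 0.6 (inclusive); traces after the first failing link
are discarded.

The light/heavy ratio is the OLS slope of the summed light channel on the
summed heavy channel across scans, with a free intercept absorbing any
constant baseline. The coefficient of determination of that same
regression is the quality score; a pair is valid only when R² ≥ 0.8. Two
degenerate cases are defined explicitly: a light channel that is
identically zero is a *confident pure-heavy* measurement (slope 0, R² 1),
and heavy identically zero with a real light peak is *pure light*
(MOS = 1). At least 5 scans with heavy signal are required otherwise.

## 3. Titration extrapolation

Each run mixes the sample with a fully light carrier proteome at a known
fraction *t* (0.10 or 0.25). Under carrier mixing the measured value for
peptide *j* in run *i* is

$$\mathrm{MOS}_{ij} = t_i + (1 - t_i)\,\mathrm{MOS}_{\text{invivo},j},$$

the unique linear mixing form consistent with the variable definitions: a
fully blocked peptide (no in vivo oxidation) reads back exactly the
carrier fraction, and a fully oxidized peptide reads 1 at any *t*. The
parameter is estimated by bounded nonlinear least squares on [0, 1]
(`nls` with the port algorithm), with SEM from the fit's parameter
covariance. We clip the *parameter*, not the data: measured values
slightly outside [0, 1] carry information about the noise and are kept
(a `clip_measurements` flag provides the alternative behavior).

Fit quality is the normalized RMSE — residual RMSE divided by the mean of
the observed values (range normalization is available) — gated at ≤ 0.2.
Inclusion requires ≥ 7 valid values out of 12 per age group, and
cysteine-containing peptides are removed throughout: cysteine is also
modified by the labeling chemistry but its oxidation is reversible in
lysates, so the blocking logic does not apply to it.

# Statistical inference

**Oxidation-prone methionines** (one-sample analysis): interage estimates
are reformatted as distances from the global median of the filtered set,
and an adaptive-shrinkage model with a *half-uniform, positive-effects*
prior $\pi_0\delta_0 + \sum_m \pi_m U(0, b_m)$ is fit by EM over a
geometric grid ($b_m$ from $\min(\mathrm{SE})/10$ to $2\max|\hat\beta|$,
ratio $\sqrt2$). A Dirichlet pseudo-count of 10 on the null component is
included, following the convention of adaptive-shrinkage implementations:
uniform components much narrower than the noise SD are
likelihood-indistinguishable from the point mass, and without the penalty
$\pi_0$ is not identifiable on null data. Each record's local false-sign
rate is its posterior null weight (all non-null prior mass is positive),
and q-values are running means of the sorted local false-sign rates.
Significance is q ≤ 0.01. One consequence of the one-sided prior worth
knowing: for observations very close to zero the posterior mean can
slightly *exceed* the observation, so "shrinkage toward zero" holds in
aggregate and for well-resolved effects, not record-by-record.

**Age contrasts** (two-sample analysis): the effect is the difference of
the two age groups' titration estimates; the pooled SE combines their
SEMs; the t statistic uses Welch–Satterthwaite degrees of freedom derived
from per-group measurement counts (n − 1 per group, floored at 3 — the
counts the titration fit actually used). Family-wise error is controlled
with Holm–Bonferroni. The package applies one significance convention
across both analyses, 0.01, so the two procedures are comparable; it is
configurable (`q_threshold`).

# The synthetic-data generator

`simulation_truth()` / `simulate_ms1_run()` / `simulate_experiment()`
emulate the assay's study design end to end: tryptic-like single-Met,
Cys-free peptides; both species' theoretical envelopes placed at their
exact m/z; Gaussian elution (σ = 0.05 min) on a 1 s scan cycle; the
carrier-mixing split $f = t + (1-t)\,\mathrm{MOS}$ of species intensities;
optional reagent isotopic impurity (a heavy reagent of purity *p* puts
$1-p$ of the blocked signal at the light positions — the forward model
behind the assay's stated 10% impurity ceiling); multiplicative lognormal
and additive Gaussian peak noise; and centroid merging of peaks closer
than 4 mDa, which is precisely what creates the envelope overlap the
correction must undo. The default in vivo stoichiometry draw has a median
near 0.045 with a ~10% oxidation-prone upper tail, emulating the low-MOS
regime the assay operates in.

Defaults represent the reference design: 2 titration points (0.10, 0.25) ×
2 technical × 3 biological replicates × 2 age groups = 24 runs. Simulated
runs use a 2 min retention window rather than a full 90 min gradient —
the window length only sets how many runs fit in a test session, not the
physics of any single peak.

What the simulator does *not* emulate — and hence what passing tests do
not establish about real data: chimeric/overlapping features from other
peptides beyond chance m/z collisions, retention-time drift across runs,
detector saturation and dynamic-range compression, missing-value structure
from data-dependent acquisition, and search-engine identification errors.
Real noise magnitudes are also unknown; the lognormal σ = 0.01 used in
calibration tests is a low-noise regime in which estimator *bias* and SEM
*calibration* can be checked cleanly.

# Numerical choices and degenerate inputs

- Elution fitting uses Levenberg–Marquardt with box constraints
  (`minpack.lm`), means seeded at the top local maxima, widths bounded
  below by half the scan interval; non-convergence yields an invalid fit
  with a reason, never an exception.
- BIC (with 3k parameters per k-component model) selects the mixture size;
  at most 3 components.
- Ambiguous peak matches inside the ppm window take the most intense peak.
- The slope regression requires 5 scans with heavy signal; R² is clamped
  to [0, 1].
- `correct_overlap` returns `Inf` (MOS 1) when the observed slope reaches
  the pure-light limit of the mixing model rather than failing.
- Titration fits fall back to the closed-form linear solution (clamped)
  if the bounded optimizer errors; all-identical *t* is rejected as a
  degenerate design.
- SEMs entering the shrinkage and contrast stages are floored at 1e-8 so
  numerically perfect fits (synthetic noiseless data) remain usable.
- All randomness in the generator is seeded per run (derived
  deterministically from the experiment seed), making every simulated
  experiment byte-reproducible.

# Problem sizes used in the shipped tests

The test suite validates the pipeline at sizes chosen to exercise every
code path while staying desk-scale: the titration self-validation uses 50
peptides in one run; full-pipeline recovery uses 48 peptides (8 per true
stoichiometry in {0, 0.02, 0.05, 0.1, 0.3, 0.5}) across the 24-run
reference design; shrinkage calibration uses 2000 records (90% null);
null-contrast behavior uses 20 seeded repetitions of 60 peptides. These
are the package's own validation conditions, reported here so their scope
is explicit.

# Known limitations

- The overlap correction assumes the heavy envelope is exactly the light
  envelope shifted +2 positions; the 2.5 mDa residual offset is ignored,
  which is appropriate at ~120k resolution but not for very high
  resolution data where the doublet partially resolves.
- Quantification requires an evidence table; there is no de novo feature
  detection, MS2 processing, or cross-run retention-time alignment.
- The shrinkage model is a pinned in-package variant (grid, EM, penalty as
  described); q-values from other adaptive-shrinkage implementations may
  differ in detail.
- Reagent isotopic impurity is annotated, not corrected, by default — the
  simulator can generate it and the forward model can account for it, but
  the default analysis mirrors the assay convention of reporting it as a
  ceiling on interpretation.
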