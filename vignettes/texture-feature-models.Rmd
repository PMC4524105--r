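---
title: "Texture feature models for multi-parametric prostate MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture feature models for multi-parametric prostate MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmrad)
```

## The problem

Prostate tumours alter tissue in ways that several MR contrasts see
partially: a mild signal drop on T2-weighted images, and restricted
water diffusion on diffusion-weighted imaging (DWI). A voxel-level
classifier that pools texture information from many modalities at once
can separate cancerous from healthy tissue better than any single
contrast. `mpmrad` implements that pipeline end to end: derived
diffusion modalities, a 96-feature texture vector per modality,
criterion-driven feature selection, combined texture feature models
(TFM1..TFM6), and leave-one-patient-out evaluation — plus a synthetic
phantom cohort so every stage is testable without clinical data.

## Signal model and derived modalities

DWI signal at diffusion weighting $b$ follows the mono-exponential
decay

$$S(b) = S_0\, e^{-b D},$$

with $D$ the apparent diffusion coefficient (mm²/s) and $S_0$ the
unweighted signal. Tumours restrict diffusion: $D_\text{tumour} <
D_\text{healthy}$, so tumours are dark on ADC maps and relatively
bright at high $b$.

* **ADC** (`fitADC`): per-voxel ordinary least squares of $\log S$
  against $b$; slope $=-D$, intercept $=\log S_0$. OLS (rather than
  maximum likelihood) is chosen for determinism and exactness on
  noiseless data; signals are clamped to $\varepsilon = 10^{-6}$
  before the log, and negative fitted $D$ is clamped to 0.
* **CHB-DWI** (`computeCHBDWI`): a computed high-b image
  $S_0 e^{-b_t D}$ at $b_t = 2000$ s/mm² — strictly an extrapolation
  beyond the largest acquired $b$. The tumour/healthy mean ratio grows
  as $e^{b_t\,\Delta D}$, so the synthetic $b=2000$ image separates
  the classes far more than the acquired $b=1000$ image
  ($e^{2000 \cdot 0.0012} \approx 11$ versus
  $e^{1000 \cdot 0.0012} \approx 3.3$ for typical coefficients).
* **CDI** (`computeCDI`): correlated diffusion imaging mixes the
  signal across *all* acquired b-values inside a local subvolume
  $V(x)$. The mixing integral involves an unspecified conditional
  joint signal density; we use the empirical (delta-mass) estimator,
  which reduces it to the local mean of the cross-b product
  $\prod_i S_i(y)$ over $y \in V(x)$. The estimator sits behind a
  single function so a different density model can be swapped in. The
  default subvolume is $3\times3\times1$ voxels (in-plane radius 1):
  slices are 3 mm thick against ~1.6 mm in-plane spacing, so
  through-plane mixing is off by default. Subvolumes are clipped at
  image borders rather than padded — padding would invent signal. The
  $b=0$ image is included in the product (the mixing is defined across
  all acquired b-values). Because the product compounds the per-b
  attenuation, the tumour/healthy ratio is
  $e^{(\sum_i b_i)\,\Delta D} \approx 6$ — larger than any single-b
  ratio — and tumours appear as bright nodules.

## The 96-feature texture vector

For each modality, features are computed for a sliding window (default
$3\times3$ pixels, 2-D because of the slice anisotropy) centred on
every gland voxel:

| family | count | notes |
|---|---|---|
| first-order | 4 | mean, population SD, skewness, excess kurtosis of raw intensities |
| GLCM (Haralick) | 18 × 4 | directions 0°/45°/90°/135°, offset distance 1, symmetrized and normalized |
| Gabor | 3 × 4 | frequencies 0.1/0.25/0.4 cycles/px, orientations 0°/45°/90°/135° |
| Kirsch | 8 | maximum absolute compass-kernel response over the window |

Totalling $4 + 72 + 12 + 8 = 96$ per modality. Design notes:

* **Quantization** for the GLCMs uses 16 grey levels, min–max scaled
  per modality *over the gland*, not per window — per-window scaling
  would erase inter-window contrast, which is precisely the signal.
* The 18 GLCM statistics follow the standard co-occurrence
  definitions; the information measure of correlation is the IMC1
  variant (the feature name records this). Degenerate (constant)
  windows get entropy/correlation-type features 0, energy 1,
  contrast 0; skewness and kurtosis of constant windows are defined
  as 0 rather than NaN.
* **Gabor** filters are applied to the whole slice (FFT convolution)
  and the response magnitude is mean-pooled per window; image-level
  filtering avoids window-edge artefacts. The frequency triple spans
  coarse-to-fine texture at the window scale; published Gabor feature
  sets in this literature typically state only the counts (3 scales,
  4 orientations), so the exact parameterization is the package's
  choice.
* **Kirsch** kernels are the classic ±5/±3 compass masks; zero-sum, so
  features are invariant to intensity offsets.

A window inherits the label of its centre voxel (pixel-based ground
truth). Feature names carry provenance
(`modality/family/name/detail`), which the model-building stage uses.

## Feature selection and the texture feature models

Features are ranked by greedy maximum-relevance minimum-redundancy
(mRMR), difference form: the next feature maximizes
$\mathrm{MI}(f;c) - \tfrac{1}{|S|}\sum_{g\in S}\mathrm{MI}(f;g)$.
Mutual information is the histogram plug-in estimator (16 equal-width
bins, matching the GLCM level count; both configurable), reported in
bits. Ties break lexicographically so rankings are deterministic.

The subset *size* is chosen by sweeping a grid of sizes along the
ranking and scoring each prefix with a patient-grouped cross-validated
SVM (`selectBestM`). The exhaustive search is over subset size, not
over all $2^{96}$ subsets. Scores within `scoreTol = 0.01` (about the
cross-validation noise scale) of the best are treated as tied and the
smallest size wins — a one-standard-error-style parsimony rule;
without it a stochastic score curve almost never ties exactly and the
largest subsets win on noise.

Models combine modalities two-stage (`buildTFM`): select per modality,
pool the winners, select again on the pool. The published
compositions are TFM1 = T2w+ADC through TFM6 = all eight modalities
(T2w, ADC, CHB-DWI, CDI, and the four individual b-value images).
Selection runs under one *criterion* (sensitivity, specificity or
AUC); the final subset size may instead maximize a separate *target*
(e.g. specificity-driven selection targeting AUC), mirroring how
different clinical scenarios weight the two error types.

## Classification and evaluation

The classifier is an RBF SVM (LIBSVM via `e1071`) with class weights
inversely proportional to class frequency — cancerous windows are
~1–2% of the gland, and unweighted training collapses to the majority
class. Features are standardized with training-fold statistics only.
The operating threshold is chosen on training scores: Youden's J for
AUC-driven runs, or a criterion-specific policy (maximize the
prioritized rate subject to the complementary rate ≥ 0.6 — the
"moderate" level of the screening / surgical-planning scenarios).
Candidate thresholds are midpoints between adjacent distinct scores,
so the operating point sits centred in the decision gap and transfers
to held-out patients.

Evaluation is leave-one-patient-out: train on all other patients
(healthy samples capped at 3000 per fold for tractability; all
cancerous samples kept), score the held-out patient. Sensitivity,
specificity and accuracy pool the per-fold confusion counts; AUC is
trapezoidal over all pooled held-out scores (ties count ½, equal to
the Mann–Whitney statistic); 95% confidence intervals come from a
percentile bootstrap over patients — patient-level resampling respects
the clustering of windows within patients. Per-patient metrics feed
two-sided Wilcoxon signed-rank model comparisons — exact for ≤ 12
informative pairs without ties, normal approximation with continuity
correction otherwise; all-zero difference vectors are degenerate and
reported as p = 1 with a flag.

## The phantom

`phantomConfig()` / `generateCohort()` emulate a 20-patient MP-MRI
study: a DWI grid of 64×64×16 voxels at 1.56×1.56×3 mm (the T2w
volume can be super-sampled to a finer in-plane grid and is resampled
back for analysis), b-values 0/100/400/1000 s/mm², an ellipsoidal
gland of roughly 25–30 cm³, 0–2 ellipsoidal lesions sized to make
~1.5% of gland voxels cancerous, a 15% chance of a lesion-free patient
(so a 20-patient cohort typically contains a few cancer-free
patients), per-patient diffusion
coefficients drawn uniformly from 1.4–2.0×10⁻³ (healthy) and
0.5–0.9×10⁻³ mm²/s (tumour, i.e. restricted), a T2w signal drop of
25% in lesions, a smooth multiplicative bias field (±10%), and Rician
magnitude noise (default scale 10 on a baseline near 1000; acquisition
noise varies by scanner and protocol, so the scale is a free
parameter). Everything is a deterministic function of (seed, patient
index).

What the phantom does *not* emulate — and hence what passing tests do
not show about clinical data: zonal anatomy (peripheral vs transition
zone), benign confounders (BPH, prostatitis) that mimic tumour
signal, motion and distortion between b-value acquisitions,
non-mono-exponential diffusion (IVIM, kurtosis), and radiologist
ground-truth uncertainty. Two consequences are worth naming. First,
class separation is strong, so phantom AUCs (~1.0) sit far above
clinically reported values; phantom results validate the machinery
and the *direction* of claims (combined models not worse, computed
modalities amplifying contrast), not clinical accuracy. Second,
because the phantom signal is exactly mono-exponential with
piecewise-constant D, the ADC map is an almost noise-free estimate of
D — a standardized-effect-size comparison against ADC is therefore
stacked in ADC's favour in a way it would not be on real data, and
the package's contrast comparisons use ratio-of-means contrast
instead.

## Numerical choices and degenerate inputs

* ADC: signals clamped to ≥ 10⁻⁶ before the log; all-zero masked
  voxels yield D = S0 = 0 and a counted warning; negative D clamps
  to 0.
* CHB-DWI refuses `bTarget` at or below the largest acquired b-value
  (it is an extrapolator, not an interpolator).
* GLCM of a window with no co-occurring pairs returns zeros
  defensively; constant windows follow the conventions above.
* Integer-valued patches passed to `glcmFeatures` are treated as
  already-quantized grey levels; continuous patches are min–max
  binned.
* ROC with a single class present is an error; per-patient AUC for
  lesion-free patients is NA and drops out of paired comparisons.
* Bootstrap CIs are NA when the metric is undefined in more than half
  the resamples.
* Grids with any axis under 8 voxels are rejected as degenerate.

## Problem sizes

The shipped configuration keeps a full run desk-sized: default phantom
grid with in-plane extraction stride 2 (~1000 windows per patient,
~20k per cohort with ~1.5% positives — the scale and class balance
typical of voxel-level clinical studies of this kind),
4 patient groups for selection CV, stage-1 size grid {10, 20, 40, 96}
and a coarse stage-3 grid, 3000-negative training cap, and 500
bootstrap replicates in the acceptance script. A complete
TFM1-vs-TFM6 build and LOPO evaluation on 20 patients runs in a few
minutes on one CPU.

## Known limitations

"Bayesian" CHB-DWI formulations in the imaging literature are
typically underspecified; the package implements the deterministic
mono-exponential extrapolation consistent with the ADC least-squares
fit. The CDI density model is the
empirical estimator described above. Clinical performance numbers are
out of scope by design: no clinical data ships with the package, and
the phantom's separability is not calibrated to patient data.
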