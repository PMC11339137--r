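---
title: "Peritumoral zonation and diffusion microstructure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peritumoral zonation and diffusion microstructure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(perizone)
```

## The scientific question

Glioblastoma (GBM) infiltrates the T2-hyperintense tissue surrounding its
contrast-enhancing core, whereas brain metastases are typically surrounded
by purely vasogenic edema. If infiltration is real and graded, diffusion
MRI metrics should change *gradually* with distance from the enhancing
tumor outline, and the shape of that gradient should differ between the
two entities. `perizone` implements the full analysis chain needed to
study this question — and, because patient data of this kind are not
publicly deposited, a synthetic-phantom generator that stands in for the
cohort, with ground truth calibrated to published group values
(GBM n = 30, metastases n = 28).

The pipeline is: simulate (or load) a two-shell diffusion acquisition →
fit DTI and three-compartment microstructure per voxel → split the edema
into three equal-volume distance zones (inner IZ, middle MZ, outer OZ) →
aggregate per subject per zone → run the gated statistical battery.

## The signal model

Each voxel is modeled as three water compartments with volume fractions
summing to one:

* **intra-axonal "stick"** (fraction $V_\mathrm{intra}$): diffusion only
  along the fiber orientation $\mathbf n$, with axial diffusivity
  $D_\mathrm{ax,intra}$;
* **extra-axonal "zeppelin"** (fraction $V_\mathrm{extra}$): axially
  symmetric tensor with axial diffusivity $D_\mathrm{ax,extra}$ and
  radial diffusivity $D_\mathrm{rad}$;
* **free fluid "ball"** (fraction $V_\mathrm{CSF}$): isotropic with
  diffusivity fixed at $3\,\mu\mathrm{m^2/ms}$.

For a gradient direction $\mathbf g$ at diffusion weighting $b$ (in
ms/µm², i.e. $b = 1$ for 1000 s/mm²):

$$\frac{S(\mathbf g, b)}{S_0} = V_\mathrm{CSF} e^{-3b}
 + V_\mathrm{intra} e^{-b D_\mathrm{ax,intra} (\mathbf g\cdot\mathbf n)^2}
 + V_\mathrm{extra} e^{-b\left[D_\mathrm{rad} +
   (D_\mathrm{ax,extra}-D_\mathrm{rad})(\mathbf g\cdot\mathbf n)^2\right]}.$$

$D_\mathrm{rad}$ is not part of the reported four-parameter set; by
default it is closed by the tortuosity relation
$D_\mathrm{rad} = D_\mathrm{ax,extra}\,(1 - V_\mathrm{intra}/(V_\mathrm{intra}+V_\mathrm{extra}))$,
and it can be overridden per zone (the FA-calibration mode below uses
this freedom).

The acquisition follows the two-shell protocol: 15 b = 0 volumes and 58
directions per shell at b = 1000 and 2000 s/mm², laid out on a
hemisphere by the spherical-Fibonacci rule (the diffusion signal is even
in $\mathbf g$, so antipodal directions would be redundant). The
protocol description also mentions 65 encoding directions; the per-shell
image count (2 × 58) is what the generator reproduces, and the count is
a `make_scheme()` argument, so neither reading is hard-coded.

## DTI fitting

FA and MD come from the ordinary log-linear least-squares tensor fit of
the b = 0 and b = 1000 volumes only; the b = 2000 shell is excluded even
when present. Voxels with non-positive signals are flagged invalid
rather than aborting the fit. Negative eigenvalues are clipped to zero
for FA (with a clip count recorded) while MD reports the raw eigenvalue
mean; the clipping convention is ours, as is common.

On any mono-exponential (single-tensor) signal the log-linear fit is
exact to machine precision, which the test suite exploits as an oracle.

## Microstructure fitting

The estimator works on rotation-invariant spherical features of the
normalized signal, per shell: the spherical **mean**, **second moment**
and **fourth moment** over gradient directions. All three have closed
forms under the model (error-function integrals of
$e^{-x\cos^2\theta}$), depend only on fractions and diffusivities — not
on fiber orientation — and are computed per voxel from the 58-direction
data.

Three design points deserve explanation:

1. **Why three moments?** With two shells, the spherical mean and
   second moment alone leave a *continuous degeneracy*: parameter sets
   with free-water fractions differing by 0.3 can produce identical
   mean/second-moment features to better than 0.05 %. This is the
   well-known two-shell ambiguity of the standard model. The fourth
   moment separates these sets by tens of percent and restores
   identifiability.
2. **Branch constraint.** The remaining discrete ambiguity (swapping
   which compartment has the larger axial diffusivity) is resolved by
   the standard biophysical assumption
   $D_\mathrm{ax,intra} \ge D_\mathrm{ax,extra}$, which all published
   operating values satisfy.
3. **Magnitude-noise handling.** Magnitude (Rician) noise biases the raw
   shell mean upward by ~2 % at b = 2000 and SNR 30 — enough to corrupt
   $V_\mathrm{intra}$ by ~0.02 if ignored. The even moments admit
   *exact* debiasing ($E[M^2] = S^2 + 2\sigma^2$,
   $E[M^4] = S^4 + 8\sigma^2 S^2 + 8\sigma^4$), and the mean follows
   from the second moment minus the directional variance, with the
   exact Rician noise variance evaluated per direction via Bessel
   functions. The noise level $\sigma$ is taken from the b = 0 repeats
   (or supplied).

Estimation proceeds in two stages over a bounded uniform grid
(fractions in steps of 0.02 on the simplex; diffusivities in steps of
0.1 — "coarse", the cohort default — or 0.05 — "fine" — on
(0, 3] µm²/ms, upper bound at the free-water value):

* **Noisy voxels** get the *tempered posterior mean*: a Gaussian
  likelihood on the six features with per-voxel variances from the noise
  model, sharpened by a factor of 4 (feature SDs × 0.25). Tempering
  moves the estimate from the prior-shrunk Bayes mean toward the
  maximum-likelihood solution; at the published GBM inner-zone operating
  point it reduces the $V_\mathrm{intra}$ bias from −0.006 to −0.002
  while the extra per-voxel variance is absorbed by zone averaging.
* **Noise-free features** (used by the identifiability tests and any
  noiseless simulation) are additionally polished by bounded
  Levenberg–Marquardt refinement in coordinates that turn the simplex
  and branch constraints into box bounds. With exact features this
  recovers all four parameters to well below one grid step.

Voxels with identical features are fitted once; a windowed search on
the first-shell mean keeps the grid stage fast. $V_\mathrm{extra}$ is
always derived as $1 - V_\mathrm{intra} - V_\mathrm{CSF}$, never fitted.
One boundary case needs a convention: with no stick volume, a zeppelin
whose axial diffusivity reaches the free-water value is isotropic at
3 µm²/ms under the tortuosity closure and therefore *exactly*
indistinguishable from the ball compartment; fitted volume in that
corner ($V_\mathrm{intra} < 0.02$,
$D_\mathrm{ax,extra} > 2.9$) is reported as free water.

Known limitation: at extreme free-water fractions (≥ 0.7) the tissue
signal carries so little weight that $D_\mathrm{ax,extra}$ and
$V_\mathrm{CSF}$ estimates become noisy and cross-talk between
parameters grows; cohort-level gradient recovery is attenuated
accordingly (correlation between true and recovered per-subject
Dax-extra gradients ≈ 0.5 at SNR 30). $D_\mathrm{ax,intra}$ is the
least identified parameter throughout — its likelihood is nearly flat
over ±0.4 µm²/ms — so its absolute level carries a prior-centering
bias even where fractions are recovered well.

## Zonation

The enhancing-core outline seeds a Euclidean expansion through the
edema: each edema voxel receives the exact anisotropy-aware distance
(mm) to the nearest core voxel (a restricted exact distance transform —
for shell-like geometries this coincides with a geodesic expansion).
Before the distance computation, edema voxels within one voxel
(6-connectivity) of the core are excluded as enhancing-margin
partial-volume, and any edema voxel 6-adjacent to gray matter is
excluded; both tallies are reported.

The included voxels are sorted by (distance, array index) and cut into
three consecutive equal-count bands — IZ, MZ, OZ — with remainder voxels
assigned innermost-first. Count partition equals volume partition
because the analysis operates at uniform 1.5 mm isotropic resolution.
The deterministic tie rule makes the parcellation invariant to
traversal order, and scaling all spacings rescales distances without
changing membership.

## Zone summaries and gradients

Per subject, each metric map (FA, MD, Dax-intra, Dax-extra, V-intra,
V-CSF) is aggregated over the valid voxels of each zone; the aggregator
defaults to the mean (the median is available and tested — on these
phantoms it neither reduces the attenuation nor changes cohort medians
appreciably, because the residual error is systematic cross-talk, not
voxel outliers). Edema volume is tallied both after exclusions (used as
the ANCOVA covariate) and for the full mask. Gradients are normalized
to the inner zone: MZ − IZ and OZ − IZ per metric (IZ − IZ ≡ 0).

Because readout zones are computed on the *post-exclusion* voxel set
while the generator's ground-truth tertiles cover the whole edema, the
inner readout zone contains a small admixture of middle-zone truth;
with default geometry this attenuates recovered gradients by roughly
5–10 %, which is visible in the acceptance margins but stays within
their tolerances.

## The statistical battery

All tests gate on Shapiro–Wilk normality at α = 0.05 (constant samples
are non-normal by convention):

* within group, IZ vs OZ: paired t if the paired differences pass the
  gate, else Wilcoxon signed-rank with Pratt handling of zero
  differences (zeros rank but drop from the statistic; matches the
  library normal-approximation test when zero-free);
* between groups, OZ − IZ gradients: Welch t if both groups pass, else
  Mann–Whitney U;
* ANCOVA: `gradient ~ group + edema volume`, reporting the group
  effect; a constant covariate is dropped with a warning;
* demographics: age via gated t/U, sex via Pearson chi-square *without*
  continuity correction (the convention that reproduces the published
  demographics p-value of 0.74 from counts 18/12 vs 18/10; with Yates
  correction it would be 0.95), edema volume via Mann–Whitney U.

No multiplicity correction is applied (α = 0.05 throughout), matching
the single-test reporting convention of the emulated study design. The
type-I error of the gated between-group path is verified by simulation
(1000 null replicates) to sit at 0.05 ± 0.02.

## The phantom generator

Each synthetic subject is a spherical enhancing core (radius ~N(5, 0.5)
mm) inside an edema shell (outer radius ~N(12, 1) mm) on a 20³ grid of
1.5 mm isotropic voxels, surrounded by normal white matter; a
gray-matter half-space can be added to exercise the exclusion logic.
These lesions (edema ≈ 6–8 ml) are smaller than typical clinical edema
volumes — a deliberate reduced-scale choice that keeps a 58-subject
study tractable on one CPU while leaving every zone with hundreds of
voxels; the acceptance margins quoted below already reflect this size.

Edema microstructure is assigned per zone. Cohort subjects draw their
inner-zone level and OZ−IZ gradient for each parameter from normal
distributions whose means and SDs are calibrated to the published group
summaries (for median [IQR] values, SD ≈ IQR/1.349); the middle zone is
the midpoint, and zone values are hard constants per tertile (the
calibration targets *are* zone summaries; a smooth radial-interpolation
mode exists for monotonicity stress tests). Values without a published
counterpart (metastasis V-CSF level, MD levels, several gradient SDs)
are documented single choices in `group_profile()`. Where the published
zone medians and the published gradient for the same metric disagree
(GBM Dax-extra), the generator follows the gradient table, because the
gradients are the study's primary contrast.

Draws are *antithetically paired*: subject 2k flips the standard-normal
scores of subject 2k−1, so each profile keeps its marginal distribution
while cohort means sit exactly on their calibration targets — standard
variance reduction for simulation studies, important because several
acceptance tolerances are of the same order as the cohort-median
standard error that independent draws would produce.

FA is not a generator parameter; it emerges from the DTI fit. For
FA-calibrated cohorts the generator solves, per subject and zone, for
the zeppelin radial diffusivity that makes the *noise-free* log-linear
tensor fit hit the drawn FA target (FA is monotone in
$D_\mathrm{rad}$); when a drawn target leaves the achievable FA window,
the whole per-subject FA level is shifted into the window while the
zone *differences* — the quantity under study — are preserved exactly.

Noise is Rician (magnitude MRI) at SNR 30 at b = 0 by default, with
Gaussian and noise-free modes for analytic checks. The fiber
orientation is one random unit vector per subject (a curved tangential
field exists to stress rotation invariance; the fit uses only
rotation-invariant features, so it is insensitive to this choice by
construction).

What the phantoms deliberately do **not** emulate: real anatomy
(gyri, white-matter heterogeneity, lesion shape), acquisition-space
partial voluming and upsampling, susceptibility/eddy artifacts, and
spatial noise correlation. Passing recovery tests on these phantoms
therefore validates the *estimators and the pipeline plumbing* under
the stated noise model — not robustness to everything clinical data
can do.

## Numerical choices

* b-values are converted to ms/µm² at the I/O boundary (÷1000).
* The spherical-mean factor $\sqrt{\pi/4x}\,\mathrm{erf}(\sqrt x)$
  switches to its series below $x = 10^{-6}$.
* Feature SDs are floored at 0.2 % of the feature value, covering the
  58-direction quadrature error (≤ 0.5 % for the mean) and keeping
  noise-free posteriors proper.
* Grid ties and flat posteriors resolve to the posterior mean, which is
  continuous by construction; the refinement stage breaks exact-feature
  ties by deviance.
* Distances use exact chunked nearest-neighbor computation (no
  approximate transform), so anisotropic spacings are handled natively.
* All cohort randomness derives from one global seed via a
  deterministic per-stage, per-subject hash; reruns are bit-identical.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run, per invocation: one
28-subject metastasis-like DTI cohort (FA gradient), one 30-subject
GBM-like and one 28-subject metastasis-like DMI cohort (V-intra level
and Dax-extra gradient), a 100-point noise-free identifiability grid,
200-repetition single-voxel noise studies, and 1000-replicate null
calibrations of the statistical battery. These sizes are the package's
chosen operating point for a single-CPU run; all of them scale up by
arguments if more precision is wanted.
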