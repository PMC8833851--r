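---
title: "Adaptive principal-component template registration for amyloid PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive principal-component template registration for amyloid PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantifying amyloid-beta (A&beta;) PET requires warping each scan into a
standard template space so that a fixed volume-of-interest (VOI) atlas can be
applied, after which tracer uptake is summarized as a standardized uptake
value ratio (SUVR): the mean uptake of a cortical target region divided by
the mean of a reference region. A&beta;-negative and A&beta;-positive scans
look very different — negative scans are dominated by nonspecific white-matter
uptake, positive scans add strong cortical gray-matter signal — so registering
every scan to one fixed PET template biases the spatial normalization
systematically with amyloid status.

`pctemplate` implements a PET-only answer: a *synthetic template* whose
appearance adapts to the scan being registered. The appearance parameter is
optimized jointly with the spatial transform, so every scan is registered to
a template that looks like itself.

## The template model

Given $n$ training scans, spatially normalized and intensity-normalized by
the pons, stack their $p$ voxels into $\mathbf{X}^{p\times n}$ and centre on
the voxel-wise mean image $\mu$, $\mathbf{D} = \mathbf{X} - \mu\mathbf{1}'$.
The sample covariance is taken in its $n \times n$ Gram form

$$\mathbf{C} = \frac{\mathbf{D}'\mathbf{D}}{n-1} = \mathbf{V}\Lambda\mathbf{V}',$$

and eigenimages are obtained by projection, $I_{PCi} = \mathbf{D} q_i$ with
$q_i$ the unit-norm eigenvectors — the $p \times p$ voxel covariance is never
materialized ($p \sim 10^5$–$10^7$, $n \sim 10$–$100$). Eigenimages keep
their natural intensity-like scale, $\lVert I_{PCi}\rVert =
\sqrt{(n-1)\lambda_i}$; they are deliberately not re-normalized. All $n-1$
eigenvalues are retained even when only $k$ eigenimages are kept, so
explained-variance fractions remain well defined.

The synthetic template is the literal two-component combination

$$I_{synthetic} = I_{PC1} + w\, I_{PC2}, \qquad w \in [-1, 1],$$

with $w = -1$ the amyloid-negative end of the training appearance continuum
and $w = +1$ the positive end. In a cohort whose dominant variability is the
common (nonspecific, white-matter-type) uptake pattern, $I_{PC1}$ is a
mean-like image and $I_{PC2}$ carries the cortical amyloid axis, so this
linear family sweeps a realistic negative-to-positive appearance range. A
plausible alternative reading would add the mean image ($\mu + I_{PC1} +
w I_{PC2}$); we implement the two-component form and pin the otherwise
arbitrary eigenvector signs so that $I_{PC1}$ has positive mean over the
brain and $I_{PC2}$ has positive mean over the cortical target
(`fix_component_signs()`), which makes $w=+1$ the amyloid-positive end.

## The registration cascade

All stages minimize with Powell's direction-set method (`powell_minimize()`,
derivative-free, deterministic: Brent line searches along an evolving
direction set with the classic direction-replacement test). The appearance
weight $w$ is one extra coordinate of the parameter vector at every global
stage; the template is re-synthesized at the current $w$ for every objective
evaluation.

1. **Global affine (12 parameters + w).** Multiresolution, coarse to fine,
   over a 3-level pyramid (factor 2, pre-smoothing FWHM of 2 voxels per
   reduction), maximizing normalized mutual information (NMI) over the whole
   volume. At the coarsest level the optimizer is restarted from
   $w \in \{-0.5, 0, 0.5\}$ and the best basin kept, because the appearance
   landscape can be multimodal for atypical scans.
2. **Masked refinement (12 affine + 30 polynomial + w).** NMI restricted to
   a brain mask without ventricles (ventricle size varies across subjects
   and would otherwise bias the fit). A second-order polynomial displacement
   — ten monomials per output axis on coordinates normalized to $[-1,1]$ —
   is added to the affine-mapped coordinates, so the stage starts exactly
   where stage 1 ended. A guard keeps the stage-1 result in the unlikely
   event the refinement ends with a worse masked NMI.
3. **Rigid reference refinement (6 parameters).** The cerebellum + brain-stem
   fit is refined rigidly, driven by normalized cross-correlation over only
   the high-uptake voxels of the accepted template inside the reference
   mask — the voxels at or above the 85th percentile
   (linear-interpolation quantile, `subsample_high_uptake()`) of the
   within-mask intensity histogram. $w$ stays frozen. The resulting
   transform is blended into the global one through a Gaussian-smoothed
   ($\sigma$ = 3 mm) copy of the binary mask: the final mapping is
   $y(x) = (1-s(x))\,G(x) + s(x)\,G(R(x))$, a linear interpolation of mapped
   coordinates that leaves $s=0$ voxels untouched and keeps the displacement
   field continuous.

### Numerical choices

* **Metric.** NMI $= (H(A)+H(B))/H(A,B)$ over 64 bins. The public
  `normalized_mutual_information()` uses hard bin assignment, which makes
  NMI of an image with itself exactly 2; the registration objective uses
  linear (partial-volume) bin spreading, which varies smoothly as voxels
  cross bin edges — a hard-binned objective is noticeably bumpier in $w$.
  Histogram edges are fixed per pyramid level (the template range spans the
  whole $w$ continuum; the subject range is computed once), so the objective
  surface does not jump between Powell evaluations.
* **Initialization and scale prior.** The global stage starts from a
  moments-based estimate: intensity centroids aligned and per-axis second
  moments matched between the model mean image and the subject, with
  intensities background-thresholded first (15% of the 99.9th percentile) so
  air-region noise cannot dominate the moments. The affine
  scales additionally carry a weak quadratic prior toward that moment
  estimate (weight 0.002 per unit of (deviation / 0.05)&sup2;). The prior
  exists because information-theoretic metrics can score an
  intensity-*consistent* but geometrically wrong enlarged mapping within
  ~0.02 NMI of the true fit — for a high-burden scan whose cortical uptake
  approaches the white-matter level, mapping the template's bright core onto
  the subject's entire bright shell is nearly as "predictable" as the
  correct correspondence. Second moments are insensitive to such appearance
  ambiguity and cleanly separate the two. The prior costs ~0.002 at typical
  2–3% anchor error and only becomes decisive for ~10% scale departures.
* **Parameter scaling.** Direction-set methods need commensurate scales:
  translations step in mm, rotations in 0.01 rad, scales and shears in 0.01,
  polynomial coefficients in 0.1 voxel, $w$ in 0.1. Powell tolerances are
  `xtol` $10^{-3}$ (scaled units) and `ftol` $10^{-5}$, with per-level
  iteration caps (10/8/5 for stage 1 coarse-to-fine, 5/3 for stage 2) —
  convergence is usually reached earlier through `ftol`.
* **Sampling.** Pull-back resampling with trilinear interpolation (nearest
  for labels); out-of-field voxels are 0, which the metrics treat as
  background. Fine pyramid levels subsample the metric's voxel set (stride 8
  whole-volume, stride 4 masked), a standard cost/accuracy trade.
* **Rigid stage safeguards.** The increment is box-bounded (|t| &le; 6 mm,
  |rot| &le; 0.15 rad): the refinement is a small local correction by
  construction, and the near-cylindrical brain stem makes large rotations
  ill-determined. A plausibility guard rejects solutions whose drive voxels
  land on clearly lower subject uptake (correlation can rise while the match
  slides onto background structure); the identity is kept instead, with a
  warning.
* **Degenerate inputs.** Constant images inside a metric mask give NMI 1
  with a warning; zero-variance training stacks yield valid mean-only
  models; template weights outside $[-1,1]$ are clamped with a warning.

## Quantification

The registered scan is resampled to template space through the full chain,
intensity-normalized by the pons mean (the reference mean of the output is
exactly 1), and summarized as cortical SUVRs against five reference regions:
cerebellar gray (CG), whole cerebellum (WC), WC + brain stem, pons, and
ThPons — the pons voxels at or above the 85th percentile of the *training
mean image* within the pons, so the VOI is fixed per template rather than
varying per subject. The region statistic is the unweighted voxel mean, and
SUVR is invariant to any global intensity scaling of the input. The 0.85
ThPons fraction reuses the reference-refinement quantile and is
configurable; the pons VOI (not ThPons) drives intensity normalization.

## The digital phantom

No public amyloid-PET cohort ships with voxel-level ground truth, so the
package carries a deterministic phantom generator that plays that role.

* **Anatomy** (`make_anatomy()`): a 64 &times; 64 &times; 54 grid at 2 mm —
  desk-scale rather than the 1-mm clinical template grid — with an
  ellipsoidal cerebrum (6-mm cortical ribbon around white matter), paired
  ventricles, a brain-stem cylinder containing a pons segment, and a
  *foliated* cerebellum whose white-matter lamellae give the reference
  region internal structure, as the arbor vitae does in real scans.
* **Uptake** (`render_uptake()`): white matter 2.0, cortical gray
  0.8 + 1.6&middot;a for burden a &isin; [0,1], cerebellar gray 0.8, brain
  stem and pons 2.2, ventricles 0.1 (arbitrary fixture units), multiplied by
  a fixed smooth &plusmn;15% regional-heterogeneity field and blurred by a
  4-mm FWHM point-spread function (modern scanner resolution). The
  heterogeneity field matters: with piecewise-constant tissues, NMI is
  almost invariant to the template weight, because any weight that keeps the
  tissue clusters separated explains the joint histogram equally well.
* **Cohort appearance modes** (`generate_cohort()`): one latent burden per
  subject, stratified over [0,1], *plus* a per-subject nonspecific-binding
  level (normal, sd 0.3, truncated to [0.5, 1.5]) multiplying cerebral white
  matter and the cerebellum but not the brain stem or pons. The mode's
  support is disjoint from the cortical burden signal, so the two appearance
  axes stay separable under PCA; it spares the pons, so it survives pons
  normalization; and it dominates the burden variance, so PC1 is the common
  pattern and PC2 the amyloid axis — the configuration the adaptive template
  presumes. Scaling the brain stem itself was rejected: it creates an
  artificial pons/stem differential that corrupts the reference region.
* **Subjects** (`generate_subject()`): known affine warps (rotations up to
  10&deg;, translations up to 8 mm, scales 0.95–1.05, small shears),
  optional rigid shifts of the cerebellum/brain-stem block, and white
  Gaussian noise at a stated fraction (default 5%) of the brain mean. Every
  draw flows from explicit seeds; identical truth gives bit-identical data.

What the phantom does *not* emulate: attenuation/scatter artifacts,
reconstruction correlations (noise is white, not textured), multi-scanner
effects, real gyral anatomy, or partial-volume geometry beyond a Gaussian
blur. Passing phantom tests therefore demonstrates that the implementation
is correct and self-consistent under realistic contrast structure — not that
clinical accuracy figures transfer.

## Validation design and problem sizes

The test suite rebuilds everything from code: decomposition correctness is
checked against a dense voxel-covariance oracle at tiny size (6 images of
6&sup3; voxels); template sufficiency on the standard cohort (n = 20, 5%
noise) expects the first two components to explain at least 90% of the
variance; weight recovery registers template-synthesized subjects at
$w \in \{-1,-0.5,0,0.5,1\}$ under random small affines and expects mean
absolute error &le; 0.1 with 95% of brain voxels mapped within 2 mm;
reference rescue applies a +2-voxel brain-stem shift and expects the rigid
stage to recover it within 0.5 voxel (with the polynomial stage disabled
through the configuration, so the global stages do not absorb part of the
shift first) and the full cascade to restore the pons mean within 2%; and
the SUVR analysis registers 20 warped noisy subjects and expects
R&sup2; &ge; 0.95 between SUVRs computed through recovered and ground-truth
chains for every reference region. A 10-subject cohort run twice checks
end-to-end robustness and bit-level determinism. These sizes keep the whole
suite within a desk-scale budget while leaving each check statistically
meaningful.

## Known limitations

* The appearance family is one-dimensional at fixed $I_{PC1}$: scans whose
  non-amyloid appearance deviates strongly from the training distribution
  (e.g. extreme white-matter levels not represented in training) register
  measurably worse; the multi-start over $w$ and the rigid-stage guard
  mitigate but do not remove this.
* $w$ is an appearance coordinate, not a calibrated amyloid scale; for real
  scans only its ordering is meaningful.
* The polynomial stage has 30 coefficients and can absorb part of a genuine
  local reference-region displacement; this is by design (the rigid stage
  then corrects the remainder) but means the rigid parameters alone are not
  an estimate of the anatomical shift unless the polynomial is disabled.
* Quantile conventions (type-7, &ge; threshold) are pinned and carry a tiny
  relative tolerance so the fraction &rarr; 0 limit returns the whole mask.
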