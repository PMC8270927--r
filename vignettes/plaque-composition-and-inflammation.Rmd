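---
title: "Quantifying plaque composition and inflammation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plaque composition and inflammation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquefusion)
```

## The problem

Lipid-rich necrotic core and intraplaque hemorrhage are high-risk features
of carotid atherosclerotic plaque, and both have been linked mechanistically
to plaque inflammation. Quantitative MRI can measure the two compositional
features voxel-by-voxel — the fat fraction (FF) tracks lipid content, and
the effective transverse relaxation rate R2\* is raised by the iron products
of hemorrhage — while ^18^F-FDG PET measures inflammation as tracer uptake.
Relating the two requires a chain of image-processing steps: inversion of
the multi-echo Dixon signal model, transfer of manually drawn plaque masks
between scanner sessions by image registration, mask-restricted sampling of
the composition maps, SUV/TBR quantification of the PET data, and
correlation statistics on the resulting per-slice and per-plaque tables.
`plaquefusion` implements that chain, and pairs it with a digital phantom in
which every quantity is known exactly, so each stage can be validated
end-to-end without any patient data.

## The Dixon signal model and its inversion

The magnitude signal of a voxel with water amplitude $W$, fat amplitude $F$
(arbitrary units) and relaxation rate $R_2^*$ (s$^{-1}$) at echo time $T_e$
is modelled as

$$S(T_e) \;=\; \left|\,\bigl(W + F\cos(2\pi T_e / 2.4)\bigr)\,
e^{-R_2^* T_e}\,\right| ,$$

a single effective $R_2^*$ per voxel and a single-peak fat model. Two unit
conventions are fixed deliberately: the chemical-shift cosine takes $T_e$
in **milliseconds** with a period of 2.4 ms, so that echoes at 3.6, 7.2,
10.8 and 14.4 ms alternate out-of-phase / in-phase / out-of-phase /
in-phase; and the decay term converts $T_e$ to **seconds**, so that $R_2^*$
stays on its conventional s$^{-1}$ scale (plaque values of roughly 30–100
s$^{-1}$). This is the only assignment consistent with both the echo scheme
and that scale. Proton-density and $T_1$ differences between water and fat
are not modelled anywhere — the method quantifies signal fractions, not
tissue mass fractions.

`fit_voxel()` inverts the model in two stages:

1. **Closed form.** With times in seconds, the in-phase pair gives a decay
   estimate $r_\text{in} = \ln(S_2/S_4)/(T_4-T_2)$ and the out-of-phase
   pair $r_\text{out} = \ln(S_1/S_3)/(T_3-T_1)$; the two are averaged, and
   negative estimates (signal growing with echo time, possible only under
   noise) are clamped to zero and flagged. Decay-corrected means of the
   in-phase and out-of-phase signals estimate $W+F$ and $|W-F|$, from which
   $W$ and $F$ follow.
2. **Refinement.** Bounded nonlinear least squares (L-BFGS-B) against the
   forward model, with $W, F \in [0, 10\,\max S]$ and $R_2^* \in [0, 500]$
   s$^{-1}$ and a tight cost tolerance, polishes the closed form whenever
   the initial residual exceeds $10^{-20}$ (i.e. whenever there is noise;
   noiseless voxels are already exact).

Magnitude data cannot distinguish $(W, F)$ from $(F, W)$ — both produce
identical echoes. The package resolves every voxel **water-dominant**
($W \ge F$, FF $\le 0.5$), appropriate for vessel-wall tissue where mean FF
is far below 0.5; voxels on the FF = 0.5 boundary are flagged. Voxels with
non-finite or all-zero signals, and voxels whose fitted total signal falls
below 1% of the volume's robust (99.5th percentile) maximum, are excluded
from the valid mask: FF is numerically meaningless in air.

## The phantom: what it emulates

`make_phantom()` builds a straight carotid-like vessel along the slice axis:
a dark lumen, a vessel wall, and an eccentric wall thickening over a
configurable angular sector and slice range — the plaque, defined as wall
locally at least 1.5 mm thick (the configuration is rejected otherwise).
Inside the plaque sit a lipid-rich core (default FF 0.40) and a hemorrhagic
region (default R2\* 90 s$^{-1}$) on a plaque baseline of FF 0.10 / R2\*
45 s$^{-1}$. A second, smaller vessel stands in for the jugular vein and
provides the six venous blood-pool sample points. The carotid bifurcation
is modelled as a marked slice index used as the landmark for slice
alignment.

Default geometry and acquisition grids follow the clinical protocol the
pipeline targets: Dixon maps on 0.60 × 0.60 × 0.7 mm; stand-alone T1W on
0.50 × 0.50 × 1.75 mm; PET/MRI-session T1W on 0.31 × 0.31 × 2.5 mm; PET on
1.2 mm in-plane with 2.78 mm slices and a 3 mm Gaussian point-spread
function. Dosing is 3 MBq/kg at a default 75 kg body weight, and the
default blood activity of 3.9 kBq/mL puts the blood-pool SUV at 1.3, inside
the venous range observed in carotid FDG studies. The PET-session volumes
are misaligned from the phantom frame by a configurable similarity
transform — ground truth for the registration stage.

Noise models follow the physics of each modality: Dixon magnitudes receive
**Rician** noise (independent Gaussian noise on two quadrature channels,
then the magnitude — the signal being fitted is explicitly a magnitude),
and PET receives Gaussian noise after the point-spread convolution.

Two background-texture choices matter and are deliberate:

* the deterministic texture uses wavelengths near or above the field of
  view, because periodic texture creates false registration optima at
  translations of one period — an early design used 8–17 mm wavelengths
  and the registration occasionally locked onto them;
* a seeded smooth random field (Gaussian noise blurred to ≈1.5 mm
  correlation length) is superimposed; its autocorrelation has a unique
  peak, which anchors sub-voxel alignment, and its through-slice variation
  makes out-of-plane rotations identifiable in what is otherwise a thin,
  nearly z-invariant slab.

What the phantom does **not** emulate: k-space acquisition, $B_0$/$B_1$
inhomogeneity, flowing blood and saturation slabs, multi-peak fat spectra,
motion, PET scatter/randoms or reconstruction artifacts, and anatomical
variability beyond the configured geometry. Tests passing on the phantom
therefore validate the *computational* chain — model inversion,
registration, sampling, quantification, statistics — not robustness to
every physical confound of real acquisitions.

## Registration

`mattes_mi()` measures alignment as the mutual information of the joint
intensity histogram (32 bins per image by default) between the fixed image
and the moving image resampled through a candidate similarity transform.
Samples are spread over adjacent bins with first-order (linear) Parzen
windows; with hard binning the metric is piecewise constant in the
transform parameters and a local optimizer stalls on the plateaus. An empty
overlap scores 0 — the metric's worst value — rather than erroring.

One caveat is documented rather than engineered away: histogram MI with
equal-width bins is *not* exactly invariant to nonlinear monotone intensity
rescalings (a quadratic rescale shifts the value by roughly 10–15% here, as
it does in standard implementations), but the *optimum* over transforms is
preserved, which is what registration needs; the test suite checks exactly
that.

`register_similarity()` searches the 7-parameter space (3 translations in
mm, 3 Euler angles in degrees, log isotropic scale) with a (1+1)
evolutionary strategy: Gaussian mutations scaled per parameter, acceptance
on improvement, mutation radius × 1.05 on success and × 0.98 on failure,
stopping at the iteration budget or a radius floor of $10^{-4}$. All
hyperparameters live in `register_config()`; the defaults are the package's
own declared choices:

* **parameter scales** 0.5 mm / 3° / 0.01 log-scale per normalized unit —
  chosen so one unit of each parameter moves the metric comparably; with
  naive 1 mm / 1° scales the translation dominates every mutation and
  rotations converge poorly;
* **two resolution levels**: a smoothed, in-plane-downsampled coarse level
  for capture, then full resolution for refinement;
* **20 coarse restarts** (identity plus jittered starts spanning ±5 mm /
  ±5°), because a single evolutionary path occasionally never finds the
  true basin; the inside-optimizer score down-weights solutions covering
  less than half of the fixed image, which blocks the classic
  shrinking-overlap inflation of MI;
* **mirror probes**: thin slabs admit a near-equivalent basin with both
  out-of-plane rotations sign-flipped, so the four sign variants of the
  best coarse solutions are briefly refined at full resolution before the
  final descent.

Registration is deterministic given its seed. Degenerate (constant) images
return the identity transform with a warning flag. Masks are transferred
with nearest-neighbour interpolation only (`apply_to_mask()`), so they stay
strictly binary; the visual-inspection step of a clinical workflow is
replaced in testing by a quantitative Dice-vs-truth gate, and an initial
transform can be supplied through the configuration.

`align_slices()` implements landmark-based slice correspondence: slice
centres are expressed in millimetres relative to the bifurcation landmark
of each volume and each source slice maps to the nearest target centre,
ties broken toward the landmark; source slices beyond half a slice from the
target's outermost centre are dropped.

## Sampling rules

"Immediate neighbours" for the in-mask averaging rule is read as the
26-connected neighbourhood *including* the voxel itself: self-inclusion
guarantees a defined value for isolated voxels, and 26-connectivity matches
the isotropic intent; both are configurable (6/18/26, with or without
self), since the choice is a convention, not a derivation. The whole-mask
average is voxel-weighted (a plain mean over the mask); the slice-weighted
alternative (mean of slice means) is exposed as an option, and the two
coincide when all slices hold equal voxel counts.

For PET the order is reversed by design: the whole-plaque SUV_mean is the
**mean of the per-slice ROI means** — slices are summarized first, then
averaged — matching how TBR is computed in the vascular-PET literature; the
voxel-weighted alternative is again an option. The blood pool is the mean
of exactly six nearest-voxel point samples, with a sphere-averaging radius
deliberately *not* applied by default (points are the stated procedure).
Decay correction is assumed already applied by the scanner; uptake time is
carried as metadata only. No partial-volume correction is applied anywhere —
the 3 mm PET point spread genuinely depresses SUVs of mm-scale structures
(visible in the phantom: a 4 mm vein at true blood SUV 1.3 reads ≈1.0 at
3 mm PSF), and that bias is part of what the method reports.

## Statistics

`pearson()` returns the product-moment $r$, the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, and the
least-squares regression line; results carry `tidy()`/`glance()` and
`autoplot()` methods. `permutation_pvalue()` provides an independent
Monte-Carlo cross-check. At the pilot sample size ($n = 12$) the exact $t$
null and the conditional permutation null differ analytically by up to
about 0.02–0.03 in mid-range p-values; the calibration tests therefore
compare the two within a 0.03 absolute band, and additionally verify the
sharper property that the type-I error rate over 1000 null simulations sits
at 0.05 ± 0.02. No multiple-testing correction is applied across the
correlation family, matching the analysis the pipeline mirrors; reports
print both $r$ and $r^2$, since published per-patient thresholds are
sometimes stated ambiguously between the two.

One subtlety the synthetic cohort exposes: even when plaque uptake levels
are drawn independently of composition levels, *slice-level* FF and TBR
profiles within one plaque are not independent — both are shaped by the
same geometry (core and blur both peak mid-plaque), so per-subject slice
correlations can be large without any biological association. Independence
holds, and is tested, at the subject level across the cohort; slice-profile
machinery is validated on synthetic independent series.

## Numerical choices and degenerate inputs

* Grids are axis-aligned; world coordinates are voxel centres,
  `origin + (index − 1) · voxel`. NIfTI I/O writes that affine and refuses
  rotated affines on read.
* Resampling is trilinear for images, nearest-neighbour for masks;
  out-of-volume samples are NA (images) or 0 (masks).
* The Dixon refinement triggers only above an initial residual of
  $10^{-20}$, so noiseless fits are bit-exact closed forms.
* Empty masks, all-zero voxels, constant images and zero-extent plaques are
  flagged (degenerate attributes, warnings, invalid voxels) rather than
  raised as errors wherever an empty result is a legitimate outcome.
* Slice-correspondence ties break toward the landmark.

## Study conditions and problem sizes

The validation suite and the acceptance script run at pilot-cohort scale,
which the package adopts as its reference conditions: phantoms of 48 × 48 × 24 voxels; a 12-subject cohort with
heterogeneous plaque extent (10–15 slices), lipid FF 0.15–0.45, hemorrhage
R2\* 70–110 s$^{-1}$, body weight 65–95 kg and uptake drawn independently
of composition; 500-voxel noise studies at 2% Rician noise; 20 random
similarity misalignments within ±5 mm / ±5° / scale 0.95–1.05; $10^5$-draw
permutation oracles and 1000-run type-I calibrations at $n = 12$. The
reference uptake table of the 12-patient cohort reproduces its printed TBRs
within ±0.02 (printed values are 2-decimal rounded) and its group mean ± SD
of 1.49 ± 0.48.

## Known limitations

* Magnitude-only Dixon: FF is capped at 0.5 by the water-dominant
  convention; fat-dominant tissue (not expected in vessel wall) would be
  mirrored.
* Group FF/R2\* means of any real cohort depend on per-patient slice data;
  the package validates parameter recovery on phantoms instead of
  reproducing cohort-specific composition values it has no data for.
* The registration defaults are tuned for the thin-slab, small-FOV carotid
  geometry; other anatomies will likely need different parameter scales
  and restart budgets.
* The phantom's vessel is straight and its compartments piecewise constant;
  it is a validation instrument, not a realism benchmark.
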