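---
title: "Quantifying dopaminergic grafts from serial sections: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dopaminergic grafts from serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftquant)
```

# The measurement problem

A fetal ventral-mesencephalon graft placed in the 6-OHDA-lesioned rat
striatum is evaluated post hoc from a spaced series of stained coronal
sections: how large is the surviving graft core, how many
tyrosine-hydroxylase-positive (TH-ir) neurons survived, how far and in which
direction did their fibers reinnervate the host striatum, and did rotational
behavior normalize accordingly? Each of these is an estimate from sparse 2D
samples of a 3D object, so every estimator here is paired with a synthetic
phantom whose ground truth is known analytically or by fine-grid integration.

# Stereological model

**Volumes.** Between consecutive sections spaced h apart, the profile areas
$A_n$ and $A_{n+1}$ are treated as circles and the intervening volume as a
truncated cone:
$$V_n = \frac{h}{3}\left(A_n + \sqrt{A_n A_{n+1}} + A_{n+1}\right),$$
summed over the $N-1$ pairs (`frustumVolume`, `seriesVolume`). No end caps
are added beyond the first and last section, so convex objects are slightly
underestimated; on an analytic sphere sampled at h = r/20 the error is below
1% (tested). The spacing is always taken from the declared geometry
(thickness + gap), not hard-coded. Note that a literal 1-in-6 series of
40 um sections would imply 240 um spacing; the 40 + 120 = 160 um convention
used as the default here follows the declared metadata, and the two cannot
both be true — the pipeline trusts the metadata.

**Cell counts.** A spherical soma of diameter D intersecting a slab of
thickness T leaves a profile, so raw profile counts overestimate object
numbers by (T + D)/T. `abercrombieEstimate` applies N = n T/(T + D). The
correction is exact in expectation for spheres of fixed D; Monte-Carlo
sectioning of 500 simulated somata shows < 5% bias (tested). D is not
measurable from the package's inputs and defaults to 12 um, a typical TH-ir
soma diameter; it is a free parameter. For spaced series, `quantifyGraft`
reports both the within-series estimate and a series-extrapolated total
(times spacing/thickness) and keeps fractional values — rounding is left to
reporting.

# Densitometric model

Brightfield DAB staining is darker where more antigen is bound, so optical
density is defined ratiometrically against the TH-negative corpus callosum of
the same section: $OD(p) = \max(0, \log_{10}(I_{ref}/I(p)))$, with zero
intensities clamped to 1. Per-section (not global) referencing follows the
practice of normalizing each image individually; it also makes the measure
invariant to global illumination rescaling (tested).

Fiber segmentation takes pixels *strictly above* a threshold inside the
lesioned striatum minus graft core minus artifacts. Two threshold rules are
provided because staining studies rarely publish theirs:

* `reference_sd` (default for real material): corpus-callosum mean OD +
  k SD, k = 3. Anchoring to an unstained region transfers across staining
  batches and noise levels.
* `fixed`: a configured OD value. Synthetic work in this package uses the
  generator's stain threshold (0.1 OD) so that estimates are comparable to
  the phantom's thresholded-volume truths.

Relative fiber density mirrors the segmented lesioned-side outline across the
vertical midline, restricts it to the contralateral striatum, re-thresholds
there with the rule resolved on the unlesioned side, and reports
100 x (pooled mean OD of lesioned positives)/(pooled mean OD of contralateral
positives). Pooling across sections (rather than averaging per-section
densities) is a choice the source material leaves open; it is recorded in the
output (`pooled = TRUE`). An empty contralateral positive set yields NA with
a flag, never a silent zero.

Integrated fiber density is total fiber area times relative density / 100.
Its absolute scale is arbitrary (area unit times a fraction); only
comparisons between animals analyzed identically are meaningful.

The dorsoventral ratio sets one horizontal line through the pooled
area-weighted centroid row of the graft core across all sections (a
per-section mode exists behind `perSection = TRUE`), counts positive fiber
pixels strictly dorsal vs strictly ventral of it, and splits center-row
pixels evenly — the even split removes a tie-break asymmetry that would
otherwise bias ratios near 1.

# Behavioral model

Rotometry rates are signed net full-body turns per minute, ipsiversive
positive. Inclusion is strict: more than 4 turns/min at baseline. Group
allocation sorts animals by baseline (ties shuffled under the seed), deals
them serpentine-fashion (1..k, k..1, ...), then applies greedy pairwise swaps
until no exchange reduces the largest group-mean difference; swaps preserve
group sizes and the serpentine layout is already a local optimum in typical
cohorts. Improvement is baseline minus week-5 rate in absolute turns/min
(a percent-of-baseline mode exists); the absolute form was chosen because
relative change is unstable for near-zero baselines. Recovery is classified
as full at rate <= 0 (no rotation or overcompensation).

# Statistical battery

Comparisons are gated by a one-sample KS test against a normal with estimated
mean and SD. Because the parameters are estimated, the plain KS p value is
severely miscalibrated (for 500 uniform draws its median is only ~0.008);
the package therefore uses the Lilliefors null distribution for n >= 5 and
falls back to the uncorrected p only for n of 3-4. Normal-looking pairs go to
the t test (Student by default; Welch available, with Welch-Satterthwaite df
never exceeding the Student df), others to the Mann-Whitney U test, which
reports the U statistic, a tie-corrected normal-approximation Z, and an exact
enumeration p when there are no ties and $n_x n_y \le 400$.

The rotation timecourse uses a univariate mixed repeated-measures ANOVA
(TIME within, GROUP between), sphericity assumed, as is conventional for this
literature; the Greenhouse-Geisser epsilon is computed and reported but not
applied. Post hoc per-group paired t tests against baseline are deliberately
uncorrected for family-wise error (exploratory comparisons). Regressions are
plain OLS with intercept; group enters as documented integer codes
(sham = 0, anodal = 1, cathodal = 2) and both raw and standardized
coefficients are emitted, since published b values in this literature are
usually standardized. The directed BDNF hypothesis (stimulated hemisphere
above sham interhemispheric ratio) uses an upper-tailed Welch t on ratios of
`interhemisphericRatio`; a two-tailed mode is equally available because the
directedness of that contrast is reported inconsistently in the literature.

All four tests hold their nominal 5% type-I error within [0.03, 0.07] under
seeded null simulations of 1000 replicates (tested).

# The phantom: what it emulates, and what it does not

`generatePhantom` builds, in micrometre coordinates (x = cutting axis,
y = dorsoventral with dorsal at smaller y, z = mediolateral):

* two mirror-image striatal ellipsoids (default semi-axes 800 x 500 x 380 um;
  a compact 320 x 200 x 150 um scene is used for cohort simulation),
* a TH-negative corpus-callosum slab dorsal to both,
* a graft-core ellipsoid inside the lesioned striatum (validated for
  containment), stained uniformly at 1.0 OD,
* a fiber field $a\,e^{-d/\lambda}$ around the core (d measured from the core
  border along the normalized ellipsoidal radius), multiplied by $1+\beta$
  dorsally of the core centre — beta is the directional-outgrowth dial,
* spherical TH-ir cells (default D = 12 um) concentrated at the core border
  within a configurable shell, rendered as chord-radius discs on any slab
  their sphere intersects and stained darker (1.4 OD) than fibers so a
  connected-component detector can count them,
* a uniformly TH-positive contralateral striatum (0.5 OD) and optional
  artifact blobs carrying the artifact label.

Rendering converts stain OD to brightfield intensity,
$I = B\,10^{-OD}$ + Gaussian noise, quantized to 8 or 16 bits — so the
downstream OD computation recovers the field by construction. Ground truths
are analytic where closed forms exist (core volume $\tfrac{4}{3}\pi abc$) and
fine-grid integrals otherwise (fiber volume above the stain threshold,
thresholded dorsoventral volume ratio, dorsoventral stain-mass ratio); the
grid step is chosen to keep grid planes symmetric about, and off, the core
centre so that the noiseless stain-mass ratio equals exactly $1+\beta$.

The fiber decay length must be short enough that the supra-threshold halo
dies out before the striatal border (defaults lambda = 80 um full scene,
40 um cohort scene): a saturating halo fills the whole striatum and makes the
dorsoventral ratio blind to beta — a phantom-design constraint worth noting
for anyone re-parameterizing the generator.

What the phantom deliberately omits: microscope PSF and stain unmixing,
tissue deformation and registration artifacts, non-ellipsoidal anatomy, and
cell-size variability (all somata share one diameter). Passing the recovery
tests therefore shows the estimators are correct for cleanly rendered
geometry, not that they are robust to every histological artifact of real
material.

Rasterization at 5.16 um/px undercounts 12 um somata: grazing profiles
smaller than a pixel vanish and touching profiles can merge, giving roughly
10-25% fewer image-counted profiles than the geometric sphere-slab truth
(tested with an explicit tolerance). Real counting is done at much higher
magnification; the image-based counter exists to exercise the full pipeline,
while the Abercrombie bias property is established on the geometric sampler.

# Simulated cohorts and problem sizes

`runConfig`/`runPipeline` simulate a three-group cohort (default 6
animals/group) on the compact scene — 4 sections of 160 x 128 px per animal —
so that a full cohort quantifies in ~2 s and hundred-cohort Monte-Carlo
sweeps stay cheap. Injected effects follow the anodal-stimulation phenotype:
core-volume scale 1.6, fiber-amplitude scale 1.3, dorsal bias beta = 1.0
versus sham beta = 0.15, cell-count scale 1.5; cathodal sits between on
volume with no fiber gain. Between-animal variability is lognormal with
CV 0.25 on core volume and fiber amplitude, matching the tighter of the group
dispersions reported in this literature. Rotometry is coupled to each
animal's *measured* integrated fiber density
(improvement = a + b IFD + noise), so the improvement-on-reinnervation
regression is recoverable end to end. All randomness descends from the single
run seed; reports embed the resolved configuration and a content hash and are
byte-identical across reruns.

# Numerical choices and degenerate inputs

* Thresholding uses strict inequality ("pixels above threshold"); a pixel at
  exactly theta is excluded.
* OD is clipped at 0 and zero intensities clamped to 1 before the log.
* A single-section series has no frustum and returns 0 mm^3 with a warning.
* Zero ventral fiber pixels flag an infinite dorsoventral ratio; zero
  contralateral positives flag an undefined relative density (NA).
* Both-samples-constant t tests, constant-sample KS and constant-response
  regressions are flagged degenerate rather than erroring mid-pipeline;
  rank-deficient regression designs error with the collinear columns named.
* Effect sums of squares below a scale-relative tolerance are reported as
  F = 0, p = 1 (floating-point fuzz would otherwise turn an exactly-null
  within-subject effect into a spurious F).

# Known limitations

Frustum interpolation assumes circular, convex, aligned profiles; strongly
lobed grafts violate it. The Abercrombie correction assumes one shared object
height and no lost caps. The dorsoventral split uses a single pooled centre
line, which blurs per-section directionality when the core drifts across
sections. Integrated fiber density has no absolute unit. The behavioral
generator couples improvement linearly to reinnervation — adequate for
recovering a linear regression, silent on saturating dose-response shapes.
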