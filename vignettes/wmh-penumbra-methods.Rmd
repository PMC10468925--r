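---
title: "Methods: concentric-layer estimation of WMH penumbra extent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concentric-layer estimation of WMH penumbra extent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wmhpenumbra)
```

## The estimand

White matter hyperintensities (WMH) in cerebral small vessel disease are
surrounded by tissue that looks normal on conventional MRI but carries
graded perfusion and microstructural abnormality — the *penumbra*. The
quantity this package estimates is the radial extent of that abnormality, in
millimetres from the lesion edge, separately per lesion class
(periventricular vs deep) and per imaging parameter (CBF from arterial spin
labeling; FA, MD, AD, RD from the diffusion tensor; MK, AK, RK from the
kurtosis model). Units follow the field's reporting conventions: CBF in
ml/100 g/min, diffusivities in 10^-4^ mm^2^/s, FA and kurtosis metrics
dimensionless.

The procedure assumes all volumes for a subject are co-registered on a
common 1-mm isotropic grid, that lesion and tissue masks are probability
maps ready for binarization, and that subjects are exchangeable so paired
t-tests across subjects are meaningful per layer.

## Lesion classification

WMH probability maps are binarized with an inclusive threshold
(`prob >= 0.5` by default; the threshold is configurable because published
pipelines state binarization without a value). Connected components use
26-connectivity by default — the most permissive standard neighbourhood,
matching the notion of a cluster "continuous with" the ventricle margin; a
cluster is periventricular if any voxel overlaps or is 26-adjacent to the
lateral-ventricle mask, deep otherwise. Both the labelling and the adjacency
test use the same neighbourhood so the rule is self-consistent.

Deep clusters lying within `subcortical_margin_mm` (default 3 mm, Euclidean
voxel-centre distance) of the grey-matter mask are tagged `EXCLUDED`:
subcortical white matter behaves differently from deep white matter and the
source analyses removed it without defining the rule, so the rule here is
explicit, configurable and disable-able. Excluded clusters still contribute
their voxels to the cross-class exclusion mask (their signal must not leak
into anyone's "normal-appearing" shells) but are otherwise inert.

## Layer masks by exact distance binning

Layer *k* around a lesion class is defined as the voxels whose Euclidean
distance *d* to the class mask satisfies ((k−1)·h, k·h] with h = 1 mm,
computed with an exact separable squared-distance transform (the
Felzenszwalb–Huttenlocher lower-envelope algorithm, implemented in C++). At
1-mm isotropic spacing the squared distances are integers, so the half-open
binning has no floating-point ambiguity; a relative tolerance of 1e-9 on the
bin edge guards the general case. Distance 0 is reserved for the lesion.
From the binned shells we subtract every WMH voxel of every class, the
ventricle mask, and the GM and CSF masks dilated by 2 voxels with a
Euclidean-ball structuring element (partial-volume control). Subtracting the
*other* class's lesions is deliberate cross-class hygiene: shells are meant
to sample normal-appearing tissue, and a periventricular shell running
through a deep lesion (or vice versa) would not be that.

Binning one distance transform realizes the classical "merge the lesion with
the previous layers, then dilate by 1 mm" construction in continuous
geometry, and automatically prevents overlap between shells of neighbouring
same-class lesions (each voxel joins the bin of its distance to the nearest
lesion). On a voxel lattice, however, the two constructions are *not*
identical: dilating iteratively with a 1-voxel Euclidean ball (which at unit
radius contains only the six face neighbours) generates the city-block
metric, whose "spheres" are diamonds. A voxel at offset (4,4,4) from the
centre of a digital radius-5 sphere has Euclidean distance 2.449 to the
lesion (layer 3) but city-block distance 4 (layer 4). The divergence grows
along oblique directions; no fixed structuring element iterates to Euclidean
shells. We therefore treat distance binning as the definition — it is the
exact geometry the "1 mm per step" language intends — and provide the
literal iterative construction only as a comparison oracle in the test
suite, where the mismatch is demonstrated rather than hidden.

The whole-brain NAWM reference is WM minus all WMH minus the dilated GM/CSF
masks. Whether it should also exclude the 15 penumbral shells is left open
in the source description; the package default keeps them (a literal
"whole-brain" reference) with an `exclude_within_mm` switch. For phantom
studies the switch matters: see below.

## Boundary rules and their conventions

Per layer (or layer pair), a paired t-test across subjects:
t = mean(d)/(sd(d)/√n), df = n − 1, two-sided by default (sidedness is
configurable; the source analysis does not state it). Significance is
inclusive, p ≤ α with α = 0.05. Degenerate cases have fixed conventions:
all-zero differences give p = 1 (no evidence of difference — the scan should
stop there), and zero variance around a non-zero mean raises an error rather
than fabricating an infinite t. No multiplicity correction is applied, to
match the source analysis; a Holm hook exists (`correction = "holm"`).

*Perfusion rule* (layer vs whole-brain NAWM): scanning inward-out, the first
non-significant layer is the outer boundary and the extent counts the
consecutive significant layers before it, extent = (boundary − 1)·h.
*Structural rule* (adjacent layers): the first of two neighbouring layers
whose values no longer differ is the boundary, and the penumbra spans layers
1..boundary, extent = boundary·h. Both conventions are genuinely ambiguous
in the source text ("the first layer … was defined as the outer boundary");
the defaults here are the only readings that keep the published extents in
0–15 mm and are mutually consistent with the published layer profiles (for
example, the periventricular FA profile plateaus at L7 = L8 and is reported
as 7 mm). The alternative reading of each rule is implemented behind
`extent_convention`. Scanning is strictly inward-out: comparisons beyond the
boundary are computed and reported, but later re-gains of significance never
move it. Censoring (no non-significant comparison within the 15 layers) is
reported at the 15-mm ceiling with a flag. Each comparison uses the subjects
with complete data for that comparison (missing regions — e.g. a subject
with no deep lesion — simply drop out; the source does not address this).

## The phantom generator

The generator exists to validate boundary recovery against known ground
truth, because the patient data behind the published extents are not
available. It emulates, not imitates: a spherical-shell "brain" (WM core,
GM shell, outer CSF) with an ellipsoidal ventricle cavity, spherical lesions
either attached to the ventricle or isolated in deep WM, and parametric maps

  value(v) = baseline + (lesion_mean − baseline) · ramp(d(v)) +
             subject_offset + noise(v)

where d is the Euclidean distance to the lesion-class mask, and
ramp(d) = 1 inside the lesion, max(0, 1 − d/T) outside: a monotone linear
ramp reaching baseline *exactly* at the transition distance T. The linear
ramp was chosen over smoother families because it makes the ground-truth
extent unambiguous (the published group profiles show a smooth monotone
approach but no functional form). Contributions of the two lesion classes
add; the default two-lesion geometry keeps the lesions ~29 mm apart so their
ramps never interact at the default transition distances, and the compact
test geometries cap T accordingly.

Calibration defaults are the published cohort values: n = 42 subjects,
in-lesion and NAWM means per class and parameter from the published layer
tables, and transition distances defaulting to the published extents
(deep: AD 5, AK 6, FA 8, MD 7, MK 6, RD 8, RK 6, CBF 13 mm;
periventricular: AD 13, AK 14, FA 7, MD 12, MK 9, RD 11, RK 8, CBF 14 mm).
Two of the published table cells required a formatting decision: the NAWM
CBF cell prints as a run-together "20.0374.343" and is read as
20.037 ± 4.343, consistent with every other cell; the periventricular L15
CBF SD prints "477 1" and is read as 4.771.

The noise model has two levels. A subject-level additive offset, shared by
every voxel of a subject's map, is the minimal mechanism that induces the
within-subject correlation paired t-tests exploit (no covariance information
is published). Per-voxel i.i.d. Gaussian noise sits on top, with defaults a
reader of clinical maps would call plausible relative to each parameter's
scale: CBF 3, diffusivities 1 (10^-4^ mm^2^/s), FA 0.1, MK/AK 0.12, RK 0.15.
The offset SD follows the convention of being 10× the voxel-noise-induced SD
of a layer mean, evaluated at a reference shell of ~2000 voxels
(offset SD = 10·voxel SD/√2000 ≈ 0.22·voxel SD). Because the offset cancels
exactly in paired differences, recovery is driven by the voxel-noise level;
a power check at these defaults puts the non-centrality of the last in-ramp
layer's comparison far above the α = 0.05 threshold (e.g. ≈25 for the deep
CBF cohort's layer 13), so in-ramp layers are detected with near-certainty
and recovery is limited by geometry, not noise.

What the phantom does *not* emulate: cortical folding, anisotropic lesion
shapes, spatially correlated noise, registration error, partial-volume
mixing at tissue boundaries, or any pathophysiology. Passing recovery tests
therefore demonstrates that the estimator recovers the generative transition
under idealized geometry and Gaussian noise — not that it is unbiased on
patient data.

### The NAWM reference on a compact phantom

On a 96³ phantom the 15 shells are a sizeable fraction of all white matter.
If the whole-brain NAWM reference retains them, the reference mean absorbs a
share of the ramp (≈ 0.02–0.03 of the lesion–NAWM contrast at the default
geometry), which exceeds the paired-test detection threshold at n = 42
(≈ 0.3·sd of a paired difference, i.e. a few hundredths of the contrast) —
every beyond-transition layer then differs "significantly" from the
contaminated reference and the perfusion rule censors at 15 mm regardless of
the truth. In a patient brain, whole-brain NAWM dwarfs the shells and the
choice is immaterial. The phantom-study wrapper therefore excludes a
15-mm perilesional band from the reference (`nawm_exclude_within_mm`), which
is exactly the configuration switch the layer module exposes for this open
question.

### Quantization of the structural rule

On a continuous linear ramp, the layer containing the transition point
(bin (T−1, T]) retains roughly half an adjacent-layer step of signal. When
the in-ramp steps are reliably detectable — which the validation conditions
require — that terminal half-step is detected too, so the adjacent-layer
rule reports T + 1 rather than T: an intrinsic +1-layer quantization bias of
the rule itself, not an implementation artifact. The perfusion rule has no
such bias (its boundary is the first *null* layer, and the half-step layer
is still a significant one). Accordingly, recovery of the structural rule is
validated to the 1-mm layer resolution, and exact recovery is asserted only
for the perfusion rule. On the deep-lesion FA cohort with T = 8 mm the rule
reports 9 mm at essentially every seed; this is the expected behaviour.

A related convention note: on a fully null table the perfusion rule reports
extent 0 (its boundary convention subtracts the boundary layer), while the
structural rule reports 1 mm (its boundary *is* the first layer of the flat
pair). The asymmetry follows from the two published boundary definitions and
is preserved as stated.

## Numerical and engineering choices

Distances come from an exact O(N) separable transform; dilation uses the
same transform thresholded at the ball radius (with a 1e-9 slack on the
squared radius). Empty masks are errors where a distance is undefined for
downstream use, and explicit `NA` + voxel-count-zero where a region mean is
simply missing — never a silent 0. Layer construction rejects non-isotropic
grids instead of resampling. Component labelling is a vectorized frontier
flood fill restricted to the mask's bounding box. Tables are plain
tab-separated text written at full precision (17 significant digits) so that
write–read–write round-trips are byte-identical; pipeline manifests omit the
output directory so identical runs produce identical manifests. All
randomness descends from explicit seeds: phantom subject *i* uses a stream
derived from (cohort seed, i), so any subject is reproducible in isolation.

Validation problem sizes were chosen at desk scale: 96³ voxels at 1 mm for
full cohorts (42 subjects, ~30 s per cohort including classification,
layering and extraction), 64³ for module tests, ≤ 20³ for brute-force
geometry oracles, 5000-subject table-mode draws for moment checks, and 1000
replicates for the type-I-error check of the perfusion rule (expected
extent-0 frequency 1 − α under the null, verified within binomial
tolerance).

## Known limitations

Extents are bounded by the 15-layer design and censored at 15 mm; the rules
report layer indices, so resolution is 1 mm; the structural rule carries the
+1-layer quantization discussed above; significance-based boundaries depend
on cohort size and noise as much as on biology (a larger n lengthens
detected extents on any smooth profile); and the phantom validates the
estimator, not the clinical claim. Mixed-effects or spatially smoothed
alternatives to the per-layer t-test rules are out of scope by design.
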