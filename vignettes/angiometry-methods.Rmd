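---
title: "Quantifying engineered microvascular networks: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying engineered microvascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiometry)
```

## The measurement problem

Engineered microvascular cultures — endothelial and stromal cells co-embedded
in a soft hydrogel — self-assemble into branching vessel networks over days of
culture. The biological readouts of such an experiment are morphometric:
how long is the network per unit gel volume, how many vessels and branch
points does it contain, how long is the average branch? These quantities are
extracted from multi-channel confocal z-stacks (typically on the order of
100 µm deep at a 5 µm z-step, with micron-scale in-plane pixels) by
segmenting the vessel channel, reducing the binary mask to a one-voxel-wide
skeleton, and reading counts and lengths off the skeleton graph. Around that
core, the same studies quantify protein colocalization from binary-mask
products, trophoblast spheroid outgrowth from traced areas, secreted
cytokines from dot-blot membranes, and compare conditions with an
assumption-gated statistical battery.

`angiometry` implements this entire measurement chain as testable, seeded
code, and — because raw study images are rarely available and never carry
ground truth — pairs every stage with a synthetic phantom generator whose
ground truth is known exactly by construction. The phantoms are the
package's validation substrate: every headline number the package produces
is checked against phantom truth, not against eyeballed output.

## Segmentation model

Preprocessing is deliberately two-dimensional, slice by slice, mirroring the
macro-style pipelines used in practice (each z-slice is blurred, filtered
and binarized independently); everything downstream of the mask is fully 3D.
The stages, each recorded in the mask's provenance:

* **Gaussian blur** — default sigma 2 µm, converted to pixels via the
  calibration. Suppresses shot noise before thresholding.
* **Background filter** — default a median filter of 3 px (impulse-noise
  removal); a white top-hat of configurable diameter is available for
  slowly varying background.
* **Threshold** — per-slice Otsu by default, matching slice-wise macros.
  For uniformly illuminated synthetic stacks we use a single global Otsu
  threshold instead: a slice that contains only background noise has no
  bimodal histogram, and a per-slice threshold invents foreground there.
  With extreme foreground/background imbalance even the global Otsu
  threshold can collapse into the background mode; the median filter's
  noise suppression prevents this in practice, which is one reason the
  filter stays on by default.
* **Cleanup** — 26-connected components smaller than 27 voxels are
  removed; optional per-slice hole filling.

The exact filters and kernel sizes behind published FIJI macros are usually
unpublished; these defaults are explicit decisions, logged in the output,
and every one is overridable. Binarization at a fixed threshold is monotone
(a higher threshold yields a subset mask), which the tests exploit as an
invariant.

## Skeletonization and the skeleton graph

The mask is thinned to a curve skeleton by topology-preserving erosion in
the (26, 6) digital topology: border voxels that are *simple* (deletable
without changing local connectivity of foreground or background) are
removed in six directional sub-iterations until stable, with voxels that
have a single foreground neighbour protected as curve endpoints. Deletion
is sequential with re-checking, so connectivity can never break, and within
each sub-iteration candidates are visited in the eight parity subfields.
The subfield ordering matters: processed in raster order, a two-voxel-wide
ribbon is "munched" away from its free end voxel by voxel — each receding
end voxel is still simple — and an entire thin branch can vanish. Visited
by parity class, the same pass peels the ribbon to its midline instead.
Reference curve-thinning implementations without this ordering lose or
annihilate even-width structures; this failure mode drives two package
choices: phantom centrelines are snapped to voxel centres (so axis-aligned
tubes rasterize to odd-width cross-sections), and the random-tree phantom
uses a tube radius of two voxels, the resolution below which thinning any
tube is unreliable.

The skeleton graph classifies voxels by their 26-neighbour count:
endpoints (1), chain voxels (2), junctions (≥ 3). Raw thinning produces
junction *clumps*, several mutually adjacent junction voxels at one
anatomical branch point; these are merged into a single junction node at
the cluster centroid, otherwise branch-point counts inflate severely.
Segments are maximal chains between nodes. Their length is the sum of
physical centre-to-centre steps — diagonal steps count √(dx²+dy²+dz²), so
anisotropic z-steps are handled — taken along a chord through every other
path voxel: per-voxel stepping overestimates oblique centrelines by the
staircase effect (observed ~6–8% on oblique branches), while the stride-2
chord brings total-length recovery of tree phantoms to within a few
percent. Spur segments shorter than 3 µm (configurable) with a free end
are pruned and the graph rebuilt; this removes thinning artefacts near
junctions and rims without touching real branches, and pruning is logged.
A closed ring with no node voxel is reported as one cyclic segment with
zero endpoints. Isolated blob-derived voxels become degenerate nodes with
no segment.

Metric conventions, chosen so the field's two common readings are both
recoverable: a **vessel** is a skeleton segment between nodes of degree ≠ 2
(hence *average branch length = total network length / number of vessels*);
**branches** are branch points plus endpoints. Length density is reported
in µm of vessel per mm³ of gel, with the volume taken from the calibrated
stack (optionally an ROI). Multiple ROIs imaged in one gel are summarized
by an unweighted arithmetic mean per metric.

## Phantoms and what they do (and do not) emulate

`generate_vessel_phantom()` rasterizes tube phantoms — a straight tube, a
Y junction, or a recursively bifurcating random tree with enforced
inter-segment clearance of twice the tube radius plus one voxel — by
marking voxels whose centre lies within the tube radius of the centreline
*in physical units*, then applying an isotropic-in-physical-units Gaussian
PSF and additive Gaussian noise (blur before noise, the order of a real
acquisition). Ground truth (polylines, per-segment lengths, counts) is
exact by construction and satisfies the tree identity
`endpoints + junctions = segments + 1`. Default intensities (foreground
200, background 20, noise SD 10, PSF sigma 1 µm) give contrast typical of
well-stained confocal data. Every generator is a pure function of its spec,
seed included, and restores the caller's RNG state.

The phantoms emulate geometry, calibration anisotropy, PSF blur and
Gaussian noise. They do **not** emulate depth-dependent attenuation,
non-uniform staining, autofluorescence, touching/anastomosing vessels
(loops), or lumen structure — so passing recovery tests demonstrates that
the measurement chain is correct, not that segmentation of arbitrary real
stacks is. On real data the preprocessing parameters, not the skeleton
machinery, are the fragile part.

The colocalization phantom constructs two masks with an exactly realized
overlap fraction (integer voxel rounding reported back); the spheroid
phantom builds a disk with radial rectangular protrusions so the true area
has the closed form πr² + n·w·len; the membrane phantom renders duplicate
spots, positive references at normalized level 1 and negative references at
0, under a global affine gain/offset.

Validation problem sizes were chosen to exercise realistic geometry while
keeping the full suite comfortably runnable on a laptop: tube and Y
phantoms on ~1 µm grids of a few hundred thousand voxels, ten random trees
of ≥ 10 segments on 2 µm grids of ~10⁶ voxels, and 2,000 null simulations
for the statistical battery.

## Colocalization, spheroids, membranes

The overlap statistic is the voxel product of two binary masks. The
denominator is the perennial ambiguity; the package always reports all
three conventions (fraction of the vessel mask covered, fraction of the
protein mask covered, Jaccard) with the vessel-mask denominator as the
headline, and leaves intensity-weighted coefficients (Pearson, Costes) out
of scope by design — the statistic of interest is mask-based.

Spheroid outgrowth area is the total area of the outgrowth *including the
body* (the day-0 normalization implies the body is included), in mm². Both
manually traced masks (first-class, reproducing the hand-tracing workflow)
and automatic Otsu-plus-largest-component measurement are provided; up to
three replicate traces are averaged. Fold change is
`(area_d − area_0)/area_0`, dimensionless and invariant to rescaling both
areas.

Membrane densitometry reads the mean intensity in a disk at each spot,
averages duplicates, subtracts the negative-control mean, and divides by
the positive-minus-negative span. The span divisor makes the normalized
values *exactly* invariant to global affine intensity distortion (gain and
offset from exposure changes cancel), which is the property the phantom
tests enforce to 10⁻¹⁰. The more literal convention — divide by the raw
positive mean after subtracting negatives from samples only — is available
as `positive_only = TRUE`; it is affine-invariant in offset but not in gain's
interplay with the positive level, which is why the span form is the
default. Interaction-network summaries (nodes, edges, 2E/N average degree,
mean local clustering with degree-<2 nodes contributing zero) consume a
user-supplied edge list; database retrieval is out of scope so results
cannot drift with a live database version.

## The statistical battery

Group comparisons follow a 2×2 assumption-gated routing:

| normality (Shapiro–Wilk, per group) | variances | omnibus | post hoc |
|---|---|---|---|
| pass | Bartlett pass | one-way ANOVA | Tukey HSD |
| pass | Bartlett fail | Welch ANOVA | Games–Howell |
| fail | Levene (median) pass | Kruskal–Wallis | Dunn |
| fail | Levene (median) fail | trimmed/Winsorized Welch F | Games–Howell |

Design decisions where the procedure is usually left vague:

* Shapiro–Wilk is applied **per group** (the conservative reading for
  n = 3–6 per group); at those sizes the gate has little power, which the
  router reports as a warning rather than refusing.
* Bartlett is used only when normality passed — it assumes normality —
  and the median-centred (Brown–Forsythe) Levene otherwise.
* Dunn p-values are Holm-adjusted by default (Bonferroni and raw
  available); Tukey and Games–Howell are family-wise by construction via
  the studentized range, so their adjusted p equals p.
* The robust route trims 20% per tail by default (the conventional
  choice); at trim 0 the statistic reduces *exactly* to Welch's ANOVA,
  which the tests assert.
* Kruskal–Wallis p-values are computed by exhaustive enumeration of the
  permutation distribution whenever the sample is small and untied (at
  most 10⁵ arrangements, e.g. n = 3+3+3 has 1,680), and by the chi-squared
  approximation otherwise; the result records which was used.

Games–Howell refers the pairwise Welch t statistic (Welch–Satterthwaite
degrees of freedom) to the studentized range with q = t·√2; with equal
variances and equal n it converges to Tukey (observed within ~2% relative
at n = 30). Under 2,000 null simulations (3 normal groups of 6) the routed
omnibus rejects at ~5–6%: assumption pretesting is known to inflate the
level slightly — the heteroscedastic branch is entered precisely when the
sample variances look unequal by chance — and the package reproduces the
published procedure faithfully rather than "fixing" it.

## Numerical and degenerate-input policy

Errors are explicit, never silent: Otsu on a constant image, an empty
trace list, a membrane whose positive controls do not exceed the negatives,
a zero-variance pair in Games–Howell, fully tied ranks in Dunn, a day-0
area of zero. An empty mask skeletonizes to an empty skeleton (not an
error); average branch length with zero vessels is `NA`. Thick (non-
skeleton) input to the graph builder is flagged by a 2×2×2-block test.
All randomness flows from explicit seeds; the pipeline derives per-gel
substream seeds from one root seed so any gel can be regenerated alone.

## Known limitations

* Curve thinning gives no vessel radii or lumen information; radius
  estimation and perfusion are out of scope.
* Skeleton length slightly depends on voxel anisotropy at coarse z-steps;
  at the common 5 µm z-step, short z-oblique branches are measured less
  accurately than in-plane ones.
* Anastomosing (cyclic) networks are measured correctly as graphs, but the
  tree identity diagnostics apply only to acyclic phantoms.
* The statistical router inherits the level inflation intrinsic to
  assumption pretesting; with very small groups the normality gate is
  close to uninformative.

## A worked end-to-end run

```{r, eval = FALSE}
cfg <- system.file("extdata", "demo_config.yaml", package = "angiometry")
run <- run_pipeline(cfg)
run$metrics
glance(run$stats)
plot_network_metrics(run$metrics)
```

The demo generates two conditions of random-tree phantoms (sparse vs
dense), segments and skeletonizes each gel, and routes total network
length through the battery; with the bundled seed the dense condition is
correctly detected as different.
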