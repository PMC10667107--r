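---
title: "Methods: quantifying complement-mediated synapse loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying complement-mediated synapse loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdsynapse)
```

hdsynapse implements the quantitative core of a synapse-loss study in
Huntington's disease (HD) models and patient cohorts: synapse counting by
3D puncta co-localization, complement tagging with a rotation-null chance
control, glial engulfment volumetrics, microglial phagocytic-state
scoring, equal-cell-weight bootstrap comparison of spontaneous EPSC
distributions, and CAP-score / burden-of-pathology cohort stratification.
This vignette records the models behind each stage, the tunable
parameters and their defaults, and the design choices made where the
procedure was genuinely open.

## Synthetic fields and what they do (and do not) emulate

No public imaging data accompany this kind of study, so every pipeline
stage is exercised against a generator with known ground truth.
`gen_synapse_field()` places presynaptic puncta by a homogeneous Poisson
process at `pre_density` (default 0.4 puncta/um^3, a realistic striatal
excitatory-synapse density scale); a Bernoulli(`coloc_fraction`, default
0.6) subset receives a postsynaptic partner at a uniform offset inside a
ball of radius `pair_distance_max_um` (default 0.15 um, safely below the
0.3 um synapse-calling threshold so true pairs are callable); remaining
postsynaptic puncta are placed independently so the two channels have
matched expected density. Complement puncta tag a
`complement_tag_fraction` subset of true pairs, plus an independent
Poisson background (default 0.05 um^-3, kept low so the chance
co-localization rate stays in the low percent range). Channels are
rendered as Gaussian spots (sigma 0.08/0.08/0.2 um, an in-plane-isotropic
confocal-like PSF) at peak-to-background `snr` 10 over a
20-photon-per-voxel background with Poisson shot noise. The default
field is 14 x 14 x 4 um at 0.1 x 0.1 x 0.25 um voxels.

The generator emulates blur, shot noise, density and pairing geometry —
the features the detector and matcher actually respond to. It does not
emulate autofluorescence, uneven illumination, tissue scattering,
anisotropic clustering of synapses, or segmentation-relevant neuropil
structure; passing recovery tests therefore demonstrates correctness of
the measurement chain, not robustness to every real-tissue artifact.

One root `seed` plus the spec determines every output bit-exactly; each
generator derives an isolated stream from the seed and a stage name, so
adding a stage never perturbs another stage's draws.

## Puncta detection

`detect_puncta()` smooths the channel (Gaussian, default sigma matching
the PSF scale), thresholds at a global intensity quantile (default
0.97; quantile thresholding makes counts invariant to uniform intensity
rescaling), labels 6-connected components, and filters them to the
dimension criteria — volume in [0.02, 1.0] um^3, defaults bracketing
typical punctum sizes at high magnification — and a minimal
peak-to-median ratio (default 3) that rejects smoothed-noise blobs.
Because nearby puncta merge above threshold at realistic densities,
components containing more than one intensity local maximum are split by
nearest-peak assignment; maxima closer than 0.25 um are treated as one
peak so noise cannot shatter a single punctum. With these defaults the
detector recovers about 97% of generated puncta at the default density
and SNR. Centers are intensity-weighted centroids reported in physical
micrometers under the center-of-voxel convention ((index - 0.5) x voxel
size), so anisotropic voxels are handled by the physical mapping.

A `mode = "2d"` variant restricts connectivity to the imaging plane,
matching per-z-plane counting on confocal stacks; the default is the
volumetric (`"3d"`) analysis.

## Synapse calling and complement co-localization

`pair_synapses()` pairs presynaptic and postsynaptic centers strictly
closer than 0.3 um, one-to-one. The published rule fixes the threshold
and strictness but not the matching discipline; we use one-to-one
maximum-cardinality matching so a single punctum cannot co-localize with
many partners and density differences cannot inflate counts through
multiple assignment. Plain greedy-by-distance matching is not always
maximum, so the implementation seeds with the greedy assignment and then
runs augmenting paths (Kuhn's algorithm), which guarantees the maximum
pair count; tests verify equality with an independent exhaustive oracle
on thousands of random instances. Ties at exactly the threshold are
excluded (strict inequality). `coloc_fraction()` applies the same
discipline between a reference set (spots, or called synapses via their
presynaptic centers) and a probe channel.

Chance co-localization is calibrated by `rotate_channel_90()`: the probe
channel is rotated 90 degrees in the imaging plane about the field
center, destroying true spatial relationships while preserving intensity
statistics and density. Non-square fields are center-cropped to a square
first (all channels, so shapes stay consistent). Four rotations restore
the channel bit-exactly. Subtracting the rotated from the unrotated
co-localized fraction estimates the tagged fraction; over seeded
simulations at default densities this estimator is accurate to within
about 0.03 absolute — residual bias comes from chance synapse pairs
diluting the reference set, which the published procedure shares.

`summarize_animal()` enforces the three-fields-by-three-planes design
(nine values per animal, averaged); `percent_of_reference()` expresses
group values relative to the wild-type mean at the same age.

## Engulfment volumetrics

`segment_cell()` takes the connected thresholded component of the
cell-marker channel containing a seed point. `percent_engulfment()` is
100 x engulfed cargo volume / cell volume; `input_density()` is the
cargo volume fraction of the whole field; `normalized_engulfment()`
divides the former by the latter so cells in input-rich fields are not
overcredited. The figure-style normalization "to the number of inputs"
and the volume-based definition differ; the volume-based form is the
operative definition here (a count-based density can be formed from a
detected `spot_set` if wanted). Cargo thresholds are per-scene
parameters since original surface-rendering settings are not published.
Per-animal averaging (10–15 cells, then animal means) is the intended
aggregation level.

## Phagocytic-state scoring

The published 0–5 scoring is a manual rubric; reproducing it requires
explicit criteria, so the sub-scores are operationalized as threshold
bands on skeleton and label features, all configurable
(`morphology_bands()`, `cd68_bands()`). Morphology: 3 when no process
edges remain (or total length under 5 um); 2 when branch points <= 3 and
mean thickness >= 1.0 um (thick, retracted, few branches); 1 when mean
thickness >= 0.6 um (thicker but still branched); else 0 (thin, long,
multiply branched). CD68: 0 below 0.5 um^3 total label; 2 when a single
aggregate reaches 5 um^3 or components are spread all over the cell
(>= 12); else 1 (punctate). The generator emits cells inside the bands
for each intended class, and round-trip tests pin the mapping. The
numeric cutoffs are declared assumptions, not published values.
`sholl_profile()` counts sphere crossings, branch points and terminals
per radial shell from the soma; on radially monotone trees the crossing
count at radius r equals the leaf count of the r-truncated subtree,
which the tests exploit as an oracle.

## Bootstrap comparison of sEPSC distributions

Cells contribute unequal event counts, so distribution comparisons are
bootstrapped with equal cell weighting: each iteration draws 100 events
per cell with replacement, pools them, and evaluates the empirical CDF
on a fixed grid; the variance band across 1,000 iterations gives the
error bars. The two-group test resamples both groups per iteration and
compares pooled 75th percentiles (type-7 linear-interpolation quantile);
the fraction f of iterations where group A exceeds group B (ties
counted half) yields the two-sided p = 2 min(f, 1 - f), floored at one
over the iteration count — 0.0002 at the published 5,000 iterations.
Sidedness is not stated in the source description; two-sided is the
default (the reported floor equals one extreme iteration either way) and
one-sided alternatives are available by flag. Each group's resampling
stream is keyed by its cell identities, which makes the p-value exactly
invariant under swapping the groups.

## Cohort stratification and analyte statistics

CAP = 100 x age x (CAG - 30)/627; burden = (CAG - 35.5) x age.
Stratification: healthy (CAG < 36); early premanifest (dcl < 4, CAG >=
40, burden < 250); late premanifest (same but burden >= 250); early
manifest (dcl = 4, CAG >= 36, TFC 7–13 inclusive); everything else —
notably intermediate alleles of 36–39 repeats without motor diagnosis —
is unclassified. The boundary value burden = 250 is unassigned by the
verbal criteria ("<250" vs ">250"); it is assigned to late premanifest
here so the premanifest carriers partition with no gap, and a binary
search across the boundary recovers 250 exactly. "UHDRS score < 4" is
interpreted as the diagnostic confidence level (dcl, 0–4), the only
UHDRS item with that range and the one whose value 4 defines manifest
disease.

Age adjustment fits ordinary least squares of the analyte on age in
controls (>= 3 required) and subtracts b x (age - mean control age);
re-fitting adjusted control values gives slope 0 to numerical precision.
Group comparisons use Kruskal–Wallis plus Dunn's pairwise z tests on the
joint ranks with tie correction; Dunn's test is implemented here (no
installed dependency provides it) and is cross-checked against the
k = 2 identity H = z^2. Multiplicity defaults to Bonferroni, the
family-wise control Dunn's procedure is conventionally reported with.
CAP–analyte associations use two-tailed Spearman rank correlation, for
all expansion carriers and for the premanifest subset; a constant
analyte is flagged undefined rather than reported as zero. Sex is
carried in the tables but not entered as a covariate by default.

The cohort generator samples ages and CAG lengths uniformly inside
per-group ranges, rejection-sampling premanifest subjects so the burden
criteria hold, and builds the analyte as intercept + b_true x age
(+ cap_slope x CAP for carriers) + Gaussian noise. Default group sizes
20/13/18/32 mirror a typical CSF cohort of this design.

## Numerical choices and problem sizes

Distances are Euclidean in physical micrometers. Quantiles are type 7
throughout. Bootstrap p-values are floored, never zero. Degenerate
inputs have defined behavior: empty references give flagged missing
values (not 0%), constant channels give empty spot sets with a warning,
fewer than two events give an empty ISI vector with a warning. The test
suite exercises the imaging recovery at 6 animals x 3 fields per group
and the type-I-error study at 500 null replicates of a 500-iteration
test — sizes chosen to give stable Monte-Carlo estimates on a single
CPU while keeping the full suite in a few minutes.

## Limitations

The generator's simplifications (constant background, isotropic-in-plane
PSF, spherical puncta) mean detector defaults may need retuning on real
stacks, particularly the threshold quantile and volume window. The
rotation-null estimator of the tagged fraction carries a small
density-dependent dilution bias from chance synapse pairs. The
phagocytic-score bands reproduce the rubric's ordering, not any
particular rater's cutoffs. Langbehn-formula onset prediction is out of
scope (its parameters are not part of this codebase), as are raw-trace
event detection, image registration and deconvolution.
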