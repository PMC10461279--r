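---
title: "Evaluating multi-atlas auto-segmentation with atlaseval: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-atlas auto-segmentation with atlaseval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`atlaseval` evaluates atlas-based auto-segmentation (ABAS) of the
structures contoured for breast and loco-regional nodal radiotherapy.
This vignette is the package's own account of its models: what each
component computes, the assumptions and tunable parameters, what the
synthetic data do and do not emulate, and the numerical choices that a
user of the results should know about.

## The evaluation problem

An auto-segmentation (AS) is useful when a clinician can edit it faster
than contouring from scratch. Two properties of an AS matter
separately:

* **How much** it overlaps the reference contour — measured here by the
  Jaccard similarity coefficient (JSC), $J(A,B) = |A \cap B| / |A \cup
  B|$, computed by voxel counting. $J = 1$ means identical voxel sets.
  The Dice coefficient relates to it by $J = D / (2 - D)$; a commonly
  reported Dice of 0.8 corresponds to $J = 0.667$, i.e. 0.7 at one
  decimal (`dice_to_jaccard()`).
* **Where** it deviates — overlap alone cannot say whether an error
  lies on the medial border that sets a field edge or somewhere
  harmless. For this the package computes, per structure, the six
  *directional extents* (most medial, lateral, posterior, anterior,
  superior, inferior occupied voxel-centre coordinate, in cm), the six
  signed *centroid distances* (extent minus centre coordinate on the
  matching axis), and the *centroid distance variants* (CDV): the
  reference-minus-test difference of those distances per direction.

### Sign semantics of the variants

The variant orientation is fixed as **reference − test** because that
is the orientation under which per-structure variant tables reduce, in
the shared-centre case, to differences of mean extents (e.g. a level 2
medial reference extent of 6.4 cm against a test extent of 6.8 cm
gives −0.4). A single global reading "positive = over-contouring"
cannot hold under this orientation on both ends of an axis: on a *min*
direction a negative variant means the AS stops short of the reference
boundary, while on a *max* direction the same clinical meaning carries
the opposite sign. `atlaseval` therefore keeps raw signed variants
(which reproduce published tables exactly) and provides the
direction-aware `classify_variant()`, which maps signs to
under/over-contouring per direction, with a dead band (default 0.05 cm,
half the 0.1 cm reporting unit) below which a variant counts as no
variation.

### Centre modes

The "structure centre" in the centroid distances is the unweighted
centre of mass of the occupied voxels. Two centre conventions are
available:

* `centre_mode = "own"` (default): each mask is measured against its
  own centroid — the closest reading of "extent of a structure to the
  structure centre". A pure translation of the whole structure cancels
  out in this mode (variants ≈ 0 within a voxel).
* `centre_mode = "reference"`: both masks are measured against the
  reference centroid; a pure translation $t$ then appears as variants
  of $-t$ on both ends of each axis. Displacement sensitivity requires
  this mode, so evaluation runs can select it.

The absolute coordinate values printed in published summary tables
cannot be reconstructed from either convention without the original
data; only the variant arithmetic (differences) is asserted by this
package, and the transcription in `published_extents()` flags the cells
where the printed per-case variant differs by one rounding unit from
the difference of printed means.

## The synthetic cohort

No clinical CT structure sets are available, so every pipeline stage is
exercised on parametric thorax phantoms (`make_phantom()`):

* a chest-wall shell (elliptic cylinder) whose lateral semi-axis is
  half the **chest-wall separation**, so separation directly controls
  patient width;
* a half-ellipsoid breast CTV; ellipsoidal heart and lung blob; nodal
  levels 1–4 as a contiguous ellipsoid chain running superior-medial
  (level 4) to inferior-lateral (level 1); interpectoral and internal
  mammary nodes; a thin-tube brachial plexus; a spherical humeral
  head. Combined CTVs (`Level3_4`, `Level1_4`) are voxelwise unions of
  their members by construction;
* the **breast-board incline** (15° or 20°) applied as a rotation of
  the whole anatomy about the medial-lateral axis;
* per-structure placement and size jitter (Gaussian, sd 0.25 cm by
  default) drawn from a per-case seed, plus smooth seeded intensity
  texture and rib-like high-density bands so that registration has
  gradients to work with.

Shape realism is deliberately sacrificed for controllability: each
structure is an analytic primitive whose expected extent, centroid and
volume are known, so metric code can be tested against closed forms.
What the phantoms do **not** emulate: CT physics (noise spectra,
artefacts), true inter-patient anatomical variability beyond affine-ish
size/position changes, organ motion, and the low soft-tissue contrast
that makes structures like the brachial plexus hard in real scans.
Passing tests on phantoms therefore validate the *arithmetic and the
pipeline plumbing*, not clinical segmentation accuracy.

`make_cohort()` draws `n` cases with requested proportions of inclines
and separation classes (realised exactly to integer rounding);
separations are uniform on either side of a configurable small/large
cut (default 19 cm, within a 16–22 cm range — the class boundary is
configuration because no canonical cut value exists). A master seed
derives per-case seeds through a stated counter scheme
(`derive_seed()`), so a cohort can be extended without reshuffling
existing cases. A subset of cases is designated `test`; test cases are
structurally barred from atlas groups (the leakage rule).

**Grid default**: 96 × 96 × 96 voxels at 2.5 mm isotropic — large
enough that 0.1 cm reporting is resolvable, small enough that a full
registration takes seconds-to-minutes on one CPU. The test suite uses
40–48³ grids at 5–6 mm for unit tests and the 96³ default for the
self-atlas check; these sizes are the package's chosen working points
for a desk-scale study.

### Known-truth perturbations

`perturb()` turns reference structures into pseudo-auto-segmentations
with controllable error: per-axis scaling about the structure centroid,
translation, and boundary noise. The affine part is resampled with
trilinear interpolation and binarised at 0.5, so integer-voxel
translations are exact and closed-form expectations hold to one voxel.
Boundary noise softens the mask edge with a Gaussian (default σ = 1.5
voxels), adds a smooth unit-variance noise field scaled so the 0.5
crossing moves by roughly the requested standard deviation, and
re-binarises; the noise is confined to the edge transition band, so it
displaces boundaries without seeding detached islands. Structures much
thinner than the smoothing radius can lose most of their voxels under
noise — a behaviour that usefully mimics how real auto-segmentation
fails on thin structures (and feeds the JSC < 0.5 exclusion rule).
A transform that would push a structure outside the grid is an error,
never a silent clip.

## The multi-atlas segmentation engine

Commercial ABAS internals are proprietary; the engine here reproduces
the published *structure* of such pipelines — rigid registration, then
deformable registration, then label propagation, then consensus fusion
— with standard textbook components, and is presented as exactly that:
a compact emulation for testing evaluation machinery, not a clinical
segmenter.

* **Transform convention.** All transforms map *fixed* (test) grid
  coordinates into *moving* (atlas) space — the pull/resampling
  convention — stated explicitly because either direction is defensible.
* **Rigid** (`rigid_register()`): normalised cross-correlation over
  translations (± quarter field of view) and rotations (± 15°, which
  covers the 15°/20° incline gap). Moment-based initialisation from
  intensity centroids; coarse seeding of the rotation about x (the
  incline axis, −12°…12° in 4° steps); two rounds of Nelder-Mead
  refinement on a 2× downsampled grid. Self-registration returns the
  identity; a constant volume is an error (the similarity is
  undefined).
* **Deformable** (`deformable_register()`): a multi-resolution
  optical-flow scheme in the demons family. Per voxel, the update is
  the intensity mismatch times the fixed-image gradient, normalised by
  the squared gradient magnitude plus the squared mismatch, followed by
  Gaussian smoothing of the field (σ = 1.5 voxels). Defaults: up to 3
  resolution levels (never coarsening below 24 voxels per axis, beyond
  which the anatomy aliases), 50 iterations per level, relative-SSD
  stopping tolerance 10⁻⁴. The iteration keeps the best (lowest-SSD)
  field, so the reported final SSD never exceeds the initial one; five
  consecutive step-to-step SSD increases stop the level with a warning;
  a level whose upsampled initialisation is worse than no deformation
  restarts from zero.
* **Propagation** (`propagate_labels()`): each binary atlas mask is
  resampled through the composed transform (deformable displacement,
  then rigid) with a single trilinear interpolation and binarised at
  0.5. Identity transforms return the masks unchanged, bit for bit.
* **Fusion** (`fuse()`): per structure and voxel, the consensus
  contains a voxel iff the fraction of candidates containing it is at
  least the vote fraction (default 0.5; 1.0 gives the intersection).
  Fusion is permutation-invariant. Optional pre-selection of the top-k
  atlases by post-rigid similarity exists but is off by default, since
  whole atlas groups are normally fused.
* **Leakage**: `auto_segment()` refuses a test case that appears in its
  own atlas group; an `allow_self` bypass exists only for the
  self-atlas sanity check (an atlas identical to the test case must
  reproduce its references nearly perfectly — JSC > 0.95 on the larger
  structures).

On phantom pairs at 96³ a three-atlas segmentation takes on the order
of a minute and shows the qualitative pattern expected of ABAS: high
overlap (≈ 0.8–0.95) for breast, heart, lung, level 1 and humeral
head; failure on the thin interpectoral, internal mammary and brachial
plexus structures.

## Study design and statistics

`group_spec()`/`build_group()` draw seeded atlas groups of a given size
with optional incline and separation-class filters;
`select_test_cases()` implements matching (MTC), non-matching (NMTC)
and unrestricted test-case policies — NMTC test cases must violate at
least one group filter (e.g. 20° test cases against a 15° group).
`run_evaluation()` crosses groups with test cases, producing one row
per (group, case, structure) with JSC and the six variants; the AS can
come from the full engine (`mode = "mas"`) or from known-truth
perturbations (`mode = "pseudo"`), which is how closed-form
expectations enter the test suite.

* **Exclusion rule** (`apply_cdv_exclusion()`): variants are withheld
  for any structure whose mean JSC falls strictly below 0.5 (in
  practice the interpectoral and internal mammary nodes), and
  unconditionally for heart and lung, which treatment planning systems
  contour routinely; a structure at exactly 0.5 is retained (strict
  comparison, chosen and documented). Raw values are kept in `*_raw`
  columns with a machine-readable reason.
* **Aggregation** (`aggregate_evaluation()`): arithmetic means and
  sample standard deviations (n − 1 denominator — the convention when
  none is stated) by structure × group, by group, by size class
  ("larger" = breast, heart, lung, level 1 nodes) and overall; raw
  values retained, printing rounded.
* **ANOVA** (`anova_oneway()`): classical equal-variance one-way
  F test via `stats::oneway.test()`, with the degenerate all-identical
  input reported as F = 0, p = 1 by convention. The test suite checks
  it against an independent sums-of-squares computation.
* **Adjusted R²** (`adjusted_r2()`): univariate OLS with
  $1 - (1 - R^2)(n-1)/(n-2)$; negative values are legitimate and occur
  for uninformative predictors (group size or structure volume against
  JSC behave this way).
* **Clinical flagging** (`flag_clinical()`): a rule table of
  (structure, direction, threshold) pairs; a location is flagged when
  its mean |variant| meets the threshold. The default rule set encodes
  the directions worth reviewing before planning — breast medial and
  posterior, level 1 and 2 posterior, level 3 lateral, level 4 medial
  and lateral, brachial plexus medial, posterior and anterior — with a
  0.3 cm threshold, the smallest variant treated as requiring editing.
  The rule set is data, not code, so stricter or looser readings are a
  configuration choice, and rules hitting excluded structures are
  skipped with a warning rather than silently dropped.

## Numerical choices and degenerate inputs

* Extents and centroids use voxel-centre coordinates (0-based indices
  mapped through origin + spacing); all lengths are cm, spacings mm.
* Two empty masks have JSC 1 (identical); empty vs non-empty is 0; the
  centroid and extents of an empty mask are errors.
* Propagated and perturbed masks binarise at 0.5; fusion compares the
  candidate fraction with a 10⁻⁹ slack so counts at the vote threshold
  are included.
* Variants are reported at one decimal with raw values retained;
  rounding error is bounded by 0.05 cm.
* All randomness flows from explicit seeds; every generator saves and
  restores the caller's RNG state, and identical (parameters, seed)
  reproduce volumes bit for bit.

## Limitations

The package measures an emulated segmenter on synthetic anatomy. Its
property checks (oracle agreement, closed-form recovery, null cases,
rule logic) transfer to real data; its accuracy numbers do not — the
clinical means reported for ABAS on patient cohorts depend on data and
software this package does not contain and makes no claim to
reproduce. The deformable model has no regularity guarantees beyond
Gaussian smoothing (no diffeomorphism constraint), the rigid search is
local after coarse seeding, and DICOM-RT import is out of scope (NIfTI
plus JSON sidecars are the interchange format).
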