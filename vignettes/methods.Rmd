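---
title: "Methods: histology-informed evaluation of short-range prefrontal tractography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histology-informed evaluation of short-range prefrontal tractography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractconcord)
```

## Overview

`tractconcord` evaluates short-range (U-fiber) prefrontal tractography
against the connectivity map established by non-human-primate tract-tracing.
It has three layers: (1) the *atlas and ground truth* — 14 Brodmann areas in
five canonical partitions, the 91 unordered area pairs, and each pair's
histological precedence; (2) the *measurement layer* — streamline geometry,
density maps, weighted Dice, bundle adjacency, a rule-based plausibility
scorer, and prevalence-based connection classification; and (3) a
*synthetic simulator* that produces bundles and cohorts with the statistical
structure the analysis assumes, so the whole pipeline is testable end to end
without imaging data.

## The area scheme and ground truth

The five partitions are dl-PFC (areas 8, 9, 46, 9/46), vl-PFC (44, 45, 47),
OFC (11, 13, 14), frontal pole (10), and ACC (24, 25, 32). Area 14 is kept
as one label even though surface atlases approximate it by orbitofrontal
parcels; parcel composition is metadata, not geometry. Hemispheres are
collapsed to one label per pair, since reconstruction success is highly
symmetric; the ledger schema reserves an optional hemisphere column.

Pairs are unordered; the canonical form sorts the two labels
lexicographically (C locale), which makes serialization deterministic. The
ground truth is shipped as `inst/extdata/ground_truth.csv` (91 rows,
72 `present` / 19 `absent`), and the published per-pair outcomes as
`inst/extdata/paper_ledger.csv`. Both carry an `ambiguous` flag: the
per-pair outcomes exist in the source only as area-by-area prose, which
conflicts with itself for a handful of pairs (for example the 9–13 / 9–14
labels are stated differently in two sections, and two sections disagree on
whether the 9/46–ACC false positives were false negatives). Flagged rows
were reconciled so that the transcription reproduces every published summary
count and percentage that is mutually consistent; the row-level choice is
marked rather than silently made. One published regional count vector (the
OFC's 14/8/4/10 split) is arithmetically irreconcilable with the other four
partitions and the overall counts under the stated scope convention — the
partition sums force a negative intra-partition false-negative count — so
the fixture reproduces the OFC *accuracy* (61%) exactly while its count
split differs; all other published counts and all published accuracies are
reproduced exactly.

The per-partition scope convention is "every pair with at least one member
area in the partition" (intra-partition pairs included). This is the only
convention that yields the published scope sizes 46/36/36/13/36; pairs
spanning two partitions are counted in both, so the scopes sum to 167 > 91.

## Coordinates, grids and file formats

All streamlines live in world RAS mm. A `voxel_grid` is a shape plus an
invertible 4×4 world-from-voxel affine; a world point `p` belongs to voxel
`v` iff `floor(solve(affine) %*% p) == v` (half-open cells), and voxel `v`'s
centre is `affine %*% (v + 0.5)`. The default grid is 90×110×90 at 1 mm
isotropic, matching the resampled resolution the analysis assumes.

TRK and TCK readers/writers are implemented natively (no R package provides
them). TRK stores points in voxel-mm with a half-voxel shift; files are
normalized to world RAS mm on read using
`rasmm = vox_to_ras %*% (voxmm / voxel_size - 0.5)`, the same convention as
the reference Python readers (the test suite cross-checks byte-identical
files against nibabel). TCK stores world mm directly and carries no grid, so
reading one requires a reference volume or grid. Round-trips are lossless to
well under 1e-4 mm (float32 storage). NIfTI masks and density maps go
through RNifti, with shape/affine validation against an expected grid.

## Metrics

**Density maps.** A streamline's voxel visitation is determined by
resampling it at steps of at most 0.2 mm (a fifth of the default voxel) and
collecting unique voxel indices; each streamline contributes at most one
count per voxel. Sub-voxel sampling was chosen over exact voxel traversal
for simplicity at equal practical accuracy; the step is configurable.

**Weighted Dice.** The source literature does not print the formula, so the
two-sided density-weighted form
`wDice = sum_{v in A∩B}(dA[v]+dB[v]) / (sum dA + sum dB)` is adopted and
fixed: it reduces to plain Dice when all counts are 1, is symmetric, equals
1 iff the maps are identical on their support, and 0 for disjoint supports.
Two empty maps are an error rather than a value. Raw counts are used by
default; `normalize = TRUE` switches to fractional densities (the choice is
not documented in the source; raw counts are the default because the two
maps being compared have comparable streamline budgets by construction).

**Bundle adjacency** is computed on binarized supports with voxel-centre
Euclidean distances:
`BA = 0.5*[mean_{A\B} min-dist to S_B + mean_{B\A} min-dist to S_A]`, with
an empty set-difference contributing 0 while the half-weighting is kept.
This matches the worked description of "a value of 3 mm means the
non-overlapping volumes are on average 3 mm apart": two parallel
single-voxel lines 3 voxels apart on a 1 mm grid score exactly 3 mm.

**Outlier rejection.** The source pipeline delegates this to an external
tool whose exact rule is unpublished; a transparent one-pass variant is
implemented: resample to 20 points, compute pairwise mean-direct-flip
distances, and reject streamlines whose mean distance to the others exceeds
`mean + alpha*SD` (alpha default 2). All identical streamlines (SD = 0) keep
everything; fewer than 3 streamlines are returned unchanged with a warning.

**Max-length calibration** is `mean + 1.5 * sample SD` (n−1 denominator) of
the per-subject empirical maxima, and requires at least two values.

## Plausibility scorer and classification

Human visual QA is out of scope; `assess_plausibility()` is an explicit
rule-based proxy used with the simulator, never presented as replicating
human raters. A bundle is `absent` below 20 streamlines (the
negligible-reconstruction bound used when counting negatives); otherwise it
is `implausible` if any of three checks fails: endpoint coverage (fraction
of streamlines with both endpoints inside the designated ROIs after a 2 mm
dilation, minimum 0.8), smoothness (mean absolute turning angle at 1 mm
resampling above 35°/step), or support cohesion (largest 26-connected
component of the density support under 0.75 of the support). The defaults
were set against the simulator: synthetic U-fibers pass all three with wide
margins (turning angles around 5°), synthetic spurious bundles fail the
smoothness and coverage checks by construction (turning angles around 60°).

Connection classification is a total function of the per-subject status
vector and the pair's precedence, with strict thresholds (`> 0.5`, `> 0.8`)
following the published wording; behaviour at exact boundaries (a pair
plausible in exactly half the cohort is FN; exactly 80% is TP, not RTP) is
documented and tested. A precedence-present pair that is reconstructed in
more than half the cohort without either status dominating is classified FN
with a warning — the mixed sparse signal is treated as a failed
reconstruction and logged for audit. With strict thresholds, "majority
plausible" and "majority implausible" cannot co-occur. Reported percentages
are rounded half-up to integers (66/91 → 73%), with raw values retained.

## The synthetic simulator

The simulator defines the study conditions for everything downstream; its
defaults are fixed, not tuned per experiment.

* **U-fibers**: quadratic Bézier centreline between two endpoints with the
  control point displaced `arc_depth` (default 8 mm) perpendicular to the
  chord — two parameters (chord, depth) span the described U-shaped
  morphologies. Each streamline adds smooth correlated Gaussian offsets
  (spline-interpolated knots every ~8 mm, SD `radial_jitter_sd`, default
  1 mm — about one voxel of anatomical spread). Default 100 streamlines.
  Lengths are constrained to `length_range` (default 5–125 mm, inside the
  38–125 mm per-tract maxima regime); an infeasible range against the
  endpoint distance is an error.
* **Spurious bundles**: smoothed random walks launched near one endpoint
  with strong angular diffusion and weak drift to the other; they fail the
  scorer's smoothness and coverage checks at default thresholds.
* **Cohorts**: per subject×pair, status is plausible with probability
  `prevalence`, else spurious with probability `implausible_rate`, else
  absent. Status-level simulation (no geometry) is the default for
  parameter-recovery experiments; `make_bundles = TRUE` adds geometry and
  can write TRK files plus a ledger CSV.
* **Scan–rescan cohorts**: per pair, a template bundle between the
  synthetic area centroids; each subject is a between-mode perturbation of
  the template (smooth jitter SD 2.5 mm plus a rigid shift SD 1 mm standing
  in for residual normalization error), each scan a within-mode perturbation
  (SD 0.5 mm) of the subject's bundle. Within < between is a design
  constraint of `retest_spec`. One shared grid models the common space, so
  between-subject comparison needs no registration.
* Everything is deterministic given (spec, seed); generators use a private
  RNG stream and leave the session RNG untouched.

The synthetic area centroids are laid out so all pairs are 5–70 mm apart
(areas 13 and 14 deliberately close, mirroring their overlapping atlas
definitions). They are labelled synthetic stand-ins, not atlas coordinates.

What the simulator does *not* emulate: diffusion signal, tracking
algorithms, seeding asymmetries, partial-volume effects, crossing-fiber
contamination, or rater disagreement. Passing tests therefore demonstrate
the correctness of the evaluation machinery and the internal consistency of
the classification rules — not that any particular tractography pipeline
achieves these scores on real data. In particular the published within/
between reliability *values* depend on real scan noise and real anatomy and
are not reproducible synthetically; the simulator targets the ordering and
separation (within-subject wDice higher, bundle adjacency lower than
between-subject) which the tests verify on a 20-subject, 10-pair cohort
spanning all five partitions.

## Numerical choices and problem sizes

Strict inequalities at classification boundaries; round-half-up reporting;
float32 tractogram storage (round-trip tolerance 1e-4 mm); 0.2 mm
density-map sampling; between-subject comparisons enumerate all unordered
subject pairs up to 50 subjects and otherwise draw a seeded subsample
(default 1000; the test cohorts cap at 60 per pair). Test and acceptance
problem sizes — 20 subjects × 10 pairs for reliability, 50 replicates of
200-subject cohorts for prevalence recovery, 200 random density maps
against brute-force oracles — were chosen as the smallest sizes at which
the Monte-Carlo orderings are stable across seeds.

## Known limitations

* The plausibility scorer is a simulator-grade proxy; on real tractograms
  its thresholds would need calibration against expert QA.
* Nonlinear spatial normalization is out of scope; only affine transforms
  of streamlines are provided.
* The transcribed per-pair outcome fixture carries the source's internal
  inconsistencies; rows that had to be reconciled are flagged `ambiguous`
  (see above) rather than presented as certain.
* No statistical inference (confidence intervals, tests) is attached to the
  concordance percentages; the source reports none.
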