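---
title: "Automated tooth landmarking and MHB scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tooth landmarking and MHB scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Quantifying the relationship between the upper and lower dental arches is a
core outcome measure in cleft lip and palate care: maxillary growth
disturbance after primary surgery shows up as arch constriction and
crossbite. The modified Huddart–Bodenham (MHB) index scores this
tooth-by-tooth on an ordinal scale from the transverse position of each
maxillary tooth relative to the mandibular arch, and being arithmetic rather
than judgement-based it is well suited to full automation. The missing piece
is landmarking: every cusp tip must be located on a scanned arch before
anything can be scored. `dentomark` implements a fully automatic landmark
recognition pipeline for single-arch triangle meshes (STL, millimetres) and
the MHB scoring that sits on top of it, together with a synthetic arch
generator that provides ground truth for testing every stage.

# Pipeline

The stages mirror how a clinician reads a model: orient it, find the cusp
tips, outline each tooth, name each tooth, then measure.

**Orientation.** A dental arch is wider than it is deep, and deeper than it
is tall, so the principal components of the vertex cloud give the
transverse, anteroposterior and occlusal directions in that order
(`pca_axes()`). PCA leaves signs free. The occlusal (up) sign is set by a
taper test: the convex-hull footprint of the top decile slab of vertices is
smaller than that of the bottom slab, because crowns taper while the cast
base is broad; a footprint ratio within 5% of unity raises a warning and
keeps the provisional sign. The anterior sign is set so the quadratic arch
form fitted to the horizontal vertex coordinates opens towards posterior.
The vertical direction matters more than the horizontal ones, so a coarse
peak pass is followed by one refinement: the occlusal axis is re-estimated
as the total-least-squares normal of the plane through the detected tooth
tips (`refine_occlusal()`). One iteration suffices — a second pass moves the
axis by less than the peak detector's own resolution.

**Peak detection.** Cusp tips and incisal edges are local height maxima.
`find_peaks()` searches only a 6 mm band below the model's highest point —
deep enough for worn or partially erupted teeth, shallow enough to exclude
most of the base — and flags every vertex that dominates its 2-ring
neighbourhood (1-ring is too noise-sensitive on fine meshes; metric-radius
neighbourhoods vary with tessellation density). Ties break to the lowest
vertex index so a flat plateau yields one representative. Non-tooth and
duplicate peaks are permitted: later stages remove them.

**Tooth partition.** The tooth–gingiva junction is a concave crease, so each
peak seeds a breadth-first face traversal that refuses to cross crease
edges (`grow_tooth_region()`). Two crease detectors run together:

* the per-edge signed dihedral (`edge_curvature()`, radians; convex
  positive), with a stop threshold of −0.6 rad for coarse, sharply-creased
  meshes, and
* the minimum principal curvature per vertex (`vertex_concavity()`, 1/mm),
  from a quadric fitted to each vertex's two-ring in its tangent frame,
  with a stop threshold of −0.7/mm.

The second field is the workhorse on realistic meshes: a crease's total turn
is split across several edge rows by tessellation, leaving every individual
dihedral below any usable threshold, and at the saddle cols between
neighbouring teeth the *mean* curvature is near zero even though the surface
is strongly concave across the col. The smaller principal curvature catches
both, and integrating over the two-ring cancels tessellation noise. Both
thresholds were calibrated on the synthetic generator's meshes so that
gingival crease bands block growth while crown surfaces stay passable.

A peak that does not sit on a tooth meets no crease, so growth from it would
flood the model. The guard is the spill rule: no face farther than
`max_travel` (horizontally) from the seed is entered — 12 mm for permanent
teeth, 9 mm for deciduous, "a tooth's width" with margin — and any region
that ever invoked the cap is labelled *spilled* and discarded.

The jawline — a quadratic `ap = a·t² + b·t + c` in the frame's horizontal
coordinates — is least-squares fitted to the non-spilled peaks. Blobs are
then merged: overlapping regions (several cusps of one tooth) are unioned,
and disjoint blobs whose positions along the jawline differ by less than
`merge_distance` (default a third of `max_travel`) are unioned too — the
buccal and lingual halves of a molar do not overlap but sit at the same
station round the arch. Blob positions are measured as *arc length* along
the fitted jawline rather than as the raw transverse coordinate: at the
posterior ends of a quadratic arch the transverse coordinate compresses
(adjacent molars can differ by under 3 mm in `t` while being over 10 mm
apart along the arch), which would make position-based merging collapse
neighbouring molars. With an arc-length parameter, half-blobs of one tooth
sit within ~2 mm of each other while adjacent teeth are at least a
half-tooth apart, which is why the default `merge_distance` is
`max_travel/3`.

**Tooth assignment.** Each merged blob is summarised by five
mirror-invariant features (`compute_features()`): surface area, mesiodistal
width (extent along the local jawline tangent), buccolingual width
(horizontal extent perpendicular to it), crown height, and peak count. A
labelled training set supplies per-type means and standard deviations
(left and right teeth share statistics), and the mismatch between a blob
and a type is the sum of squared z-scores — zero at the type means, 1 when
one feature is one standard deviation out. The covariance is taken as
diagonal: simple, extendable (more characteristics can be added without
changing the metric), and sufficient given the feature spreads.

Labelling is a dynamic programme over (blob, template slot) states against
the arch template (`MMMPPCIIIICPPMMM` for a permanent arch, `mmciiiicmm`
deciduous). Moves: assign blob to slot (mismatch cost); skip a slot
(missing tooth, `gap_penalty` = 6); discard a blob (non-tooth residue,
`discard_penalty` = 9); or fill a molar slot with two consecutive blobs via
its mesial/distal half types (`UR6.0`/`UR6.1`). The penalties are in
squared-z units: a declared gap beats any worse-than-≈2.4σ single-feature
misfit, and replacing an assignment by gap-plus-discard only pays when the
blob is a ≳15-unit misfit to every open slot. The alignment is monotone (no
crossing); ties break towards fewer discards, then towards the
earliest-assigning alignment. The DP is exact — a property suite checks it
against brute-force enumeration on small instances.

Side naming is a convention, not an inference: the mirror image of an arch
is geometrically indistinguishable, so the template anchors the quadrant
sequence to the frame (for a maxillary arch the low-jaw-parameter end is
the patient's right, for a mandibular arch the left — the two jaws have
opposite chirality viewed along their own occlusal axes).

**Landmarks and MHB.** Incisors and canines contribute their highest peak;
premolars and molars the peak with maximal buccal offset from the jawline
(the buccal cusp), falling back to the highest peak. For scoring, the
mandibular cusp landmarks define a chord-length-parameterised natural cubic
spline (the mandibular curve) and a total-least-squares horizontal
reference plane. Every mandibular landmark feeds the curve — including
second and third molars — so the scored first molars are supported from
both sides rather than sitting at a spline endpoint. Each scored maxillary
tooth (positions 1–6 per quadrant, so at most 12 per permanent arch; all 10
in a deciduous arch) is then measured: the closest curve point to its
landmark is found by dense 0.05 mm sampling plus golden-section refinement
(robust to the multiple local minima a horseshoe curve produces), the
landmark-to-curve vector is projected into the reference plane, and its
component along the local buccal direction is the signed transverse
displacement — positive buccal, negative lingual (towards crossbite).

The ordinal mapping is a configuration object (`mhb_mapping()`), not code:
buccal segment — ≥ +1 mm scores 0, −1..+1 scores −1, below −1 scores −2;
labial segment — ≥ +6 scores +1, +1..+6 scores 0, −1..+1 scores −1,
−3..−1 scores −2, below −3 scores −3. Canines score with the labial mapping
by default (configurable). The thresholds are cusp-width-scale values
consistent with the index's category descriptions (normal / edge-to-edge /
crossbite); keeping them in a validated config object makes the scoring
auditable and adjustable without touching code.

# The synthetic generator

No clinical scans ship with the package, so `generate_arch()` builds arches
with exact ground truth: an implicit field — a smooth union of a gingival
base band following the quadratic arch form and per-tooth crown primitives
(a rounded, ovoid-section box plus 1–5 spherical-cap cusps) — surfaced by
marching tetrahedra and lightly Taubin-smoothed i.i.d. Gaussian vertex
noise (0.03 mm, the order of intra-oral scanner noise) is then added.
Determinism is strict: the same spec and seed give identical vertex arrays.

Several geometric choices exist to make the arch *segmentable at all*, the
way real anatomy is:

* crowns neck inward towards the cervix (the emergence profile), so the
  gingival junction is a reentrant crease that survives surfacing at the
  default 0.5 mm grid;
* crown cross-sections are ovoid — a corner-free wall gives the crease ring
  uniform strength, where box corners created locally weak spots;
* interdental gaps are wide enough (≈2 mm wall-to-wall, plus a small
  midline diastema) for the grid to resolve the embrasure;
* molar cusps sit inboard of the proximal faces so facing cusps of
  neighbouring molars do not bulge the gap shut;
* the base band extends well past the terminal molars and beyond every
  offset tooth, so no crown wall ends on the band's rounded rim.

Tooth dimensions (mesiodistal, mm): central incisor 8.5, lateral 6.5,
canine 7.5, premolars 7.0/6.8, molars 10.5/10.0/9.5; deciduous scaled by
0.8. The second premolar and distal molars are slightly smaller than their
mesial neighbours so types remain discriminable by size when teeth are
missing. Cusp counts are 1 (incisor, canine), 2 (premolar), 4 (molar).

Occluded pairs place a mirrored maxillary arch over the mandibular one with
a 2 mm cusp-tip clearance; intended transverse displacements are realised
as per-tooth buccal offsets of the maxillary teeth relative to the shared
arch form, so the MHB ground truth is exact by construction. The mirror
swaps patient left and right, and the generator relabels accordingly, so an
offset requested for `UR6` lands on the tooth the pipeline will recognise
as UR6.

The training set (`generate_training_set()`) is the synthetic analogue of an
expert hand-labelling segmented blobs: size-jittered arches (scales
0.92–1.08) are run through the *actual* pipeline (smoothing, orientation,
peaks, partition) and the resulting blobs are labelled against the
ground-truth masks; mask-split halves supply the molar half-type samples.
Because the generator's upper and lower dimension tables are identical,
each arch contributes samples to both jaws. Standard deviations get
robustness floors — 8% of the type mean for dimensional features, 0.75 for
the integer peak count — because jittered synthetic arches can give
near-zero spreads, and a zero-variance count feature would turn one missed
cusp into an unbounded mismatch; the floors keep costs calibrated against
the gap/discard penalties.

**What passing synthetic tests does and does not show.** The generator
emulates arch geometry, scanner-scale noise, missing teeth, crossbite and
overjet offsets, and occlusal registration. It does not emulate occlusal
fissure patterns, wear facets, gingival inflammation, scan holes,
mixed dentition, or cleft palate morphology itself — so green tests
demonstrate the algorithmic machinery, not clinical performance. On real
scans the published experience of pipelines of this kind is roughly 80%
per-tooth agreement, far below the near-perfect rates seen on clean
synthetic arches.

# Numerical choices and degenerate inputs

* Duplicate vertices are merged at 1e-6 mm (STL repeats vertices per
  facet); zero-area faces are dropped at load time. Non-manifold edges are
  tolerated and treated as boundaries by traversals.
* Face winding is taken from the file; normals are recomputed from winding.
  Reflections in `transform_mesh()` flip winding to keep normals outward.
* PCA requires rank-3 vertex covariance; planar or collinear input is a
  hard error. Occlusal refinement silently skips (keeping the prior frame)
  with fewer than 3 or collinear peaks.
* The marching-tetrahedra field perturbs exact zeros by 1e-12 so no vertex
  lands exactly on a grid sample; the Kuhn cube split keeps the surface
  watertight across cells; triangle winding is fixed per-triangle against
  the inside→outside direction.
* Spline closest-point search samples at 0.05 mm and refines with
  `optimize()` in the bracketing interval; a degenerate (zero) projected
  tangent at the closest point is an error rather than a silent sign flip.
* Zero deviations are floored at 1e-6 mm before logs in the geometric-mean
  statistics. The confidence interval fits a normal to log distances
  (`exp(mean ± 1.96·se)`), the standard model for positive error
  magnitudes — property-tested to ~95% coverage on lognormal simulations.
* Test and validation problem sizes: 20 arches for the end-to-end
  recognition suite, 6 occluded pairs across 3 displacement scenarios for
  ordinal recovery, 200 replicates of n = 500 for CI coverage, 200 random
  instances (≤6 blobs) for the assignment-DP oracle. These sizes give
  stable rates while keeping the default test run comfortably interactive.

# Known limitations

* Exclusively permanent or exclusively deciduous dentitions; mixed
  dentition would need a relaxed template.
* First-versus-second premolar discrimination rests on small size
  differences and the order constraint; with several posterior teeth
  missing it degrades.
* The MHB here covers the transverse (crossbite) dimension only — no
  overjet magnitude or overbite indices, and no emulation of
  examiner-calibrated categorical indices.
* Scoring assumes the two arches arrive registered in occlusion, as
  intra-oral scanners export them; no registration is attempted.
* Side naming relies on the stated jaw; a mislabelled jaw mirrors every
  Palmer code.
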