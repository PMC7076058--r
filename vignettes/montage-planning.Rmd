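---
title: "Posterior-fossa TTFields montage planning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posterior-fossa TTFields montage planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttfplan)
```

## The problem

Tumor Treating Fields (TTFields) are ~200 kHz alternating electric fields
delivered through two orthogonal pairs of scalp transducer arrays; their
antimitotic effect scales with local field intensity, so array placement is
a treatment-planning question. The standard montage targets the
supratentorial brain. For a tumor in the posterior fossa (cerebellum,
brainstem), that montage leaves the target far from every array, and the
planning question becomes: how much is gained by moving the posteroanterior
(PA) array down to the lower occiput/upper neck and pulling the lateral
arrays backward?

`ttfplan` answers this question in a fully synthetic, reproducible setting:
a voxelized head phantom with a dorsal midline cerebellar tumor, seven
named montages, a quasi-static volume-conductor solver, and
histogram-based plan-quality metrics (PQM) that quantify field coverage of
a region of interest (ROI).

## The physics and its discretization

At 200 kHz, tissue is conduction-dominated, so each energized channel
solves the conductivity-weighted Laplace equation

$$\nabla \cdot (\sigma \nabla \varphi) = 0,$$

with fixed potentials on the energized electrode voxels, zero normal
current on the air boundary, $\mathbf{E} = -\nabla\varphi$ and
$\mathbf{J} = \sigma \mathbf{E}$. Permittivity is ignored; published
sensitivity analyses find the intracranial field is governed by
conductivity at this frequency. The two channels are solved independently
(the device time-multiplexes them) and summarized voxelwise, by default as
the arithmetic mean of the two magnitude maps (`solve_settings(combine=)`
also offers `max` and `per_channel`; absolute comparisons against any
specific hardware would additionally need the device's true drive
amplitude, which is not modelled — see Limitations).

The discretization is a voxel finite-volume scheme: one unknown per
conductive voxel, face conductances from the harmonic mean of the two
adjacent conductivities (exact for layered media in series), yielding a
symmetric positive-definite system solved by Jacobi-preconditioned
conjugate gradients to a relative residual of `1e-8` from a zero initial
guess — deterministic, no mesh generator, testable against closed-form slab
solutions. Each channel is solved at a unit potential difference and
rescaled so the delivered current equals the configured
`target_current` (default 0.9 A per channel); by linearity this is exact.
Fields are differentiated by central differences inside the domain and
one-sided differences against excluded (air) neighbors.

### Numerical behavior under grid refinement

The scheme is first-order accurate in the presence of thin
high-contrast shells. On the default phantom the binding constraint is the
5 mm CSF layer: the GTV mean field for the PA-horizontal montage falls
103.3 → 95.1 → 92.9 → 90.3 V/m at 4, 3, 2.5 and 2 mm spacing — a monotone
approach from above. Successive refinements below 3 mm differ by under 5%
(the property the test suite asserts at 2.5 mm vs 2 mm), while 4 mm runs,
used as the default because a full seven-montage study completes in under
a minute, overestimate absolute magnitudes by roughly 10–15% yet preserve
montage rankings and mirror symmetries. Conclusions drawn at 4 mm are
comparative, not dosimetric.

## The phantom

`phantom_spec()` describes a head as four nested ellipsoidal shells
(scalp, skull, CSF, brain; default outer semi-axes 80 × 96 × 90 mm, skull
9 mm and CSF 5 mm thick), a posterior-inferior cerebellar compartment, a
brainstem column, and a neck cylinder with muscle, a vertebral column and
a scalp rind so the entire external surface is scalp. The tumor (GTV) is a
sphere, by default 12 mm radius, placed dorsally on the midline of the
posterior fossa with a 4 mm concentric necrotic core; the GTV mask used by
the metrics includes the core. The paper-style anatomy this emulates had
many more structures (vessels, glands, mandible, ...); those are collapsed
into generic soft tissue here because they are peripheral to the
posterior-fossa field question, while the label vocabulary keeps distinct
codes so real segmentations load unchanged via `read_label_volume()`
(axis-aligned RAS NIfTI with integer labels).

Default conductivities (`conductivity_table()`, S/m: scalp 0.465, skull
0.010, CSF 1.654, brain/cerebellum/brainstem 0.276, muscle 0.355, vertebra
0.010, tumor 0.24, necrotic core 1.0, gel 4.0, electrode 1e4) are
literature-typical low-frequency values and are fully overridable; tumor
conductivity in particular is uncertain in vivo.

The phantom is exactly left/right symmetric by default — the lattice is
aligned so the midsagittal plane is a voxel-center plane — which makes
mirror-image montages produce mirror-image fields to solver precision and
makes lateral-shift comparisons cleanly interpretable. A seed-driven
jitter (`jitter_mm`) displaces the shell centers to break the symmetry
when asymmetry is the thing under test. GTV voxelization was verified
against the analytic sphere volume (within 5% at the default spacing,
converging under refinement).

What the phantom does *not* emulate: real cortical folding and CSF
topology, anisotropic white-matter conductivity, skull layering
(compact/spongy), and any patient-specific tumor geometry. Passing tests
on the phantom therefore validate the machinery and the comparative
physics of montage placement, not patient-level dosimetry.

## Montage geometry

Each transducer array is a 3 × 3 grid of discs (radius 10 mm, pitch
22 mm — the true commercial dimensions are not published; these
approximate them and are configurable). An array is placed by casting a
ray from the cranial centroid along a named anchor direction to the outer
scalp surface, erecting the local tangent frame from the estimated surface
normal, laying out the nine nominal centers at the configured pitch, and
re-projecting each onto the surface:

* **central** projection (default) re-casts through the head centroid and
  suits the convex cranial vault;
* **cylindrical** projection wraps rows around the vertical axis row by
  row and is used for the PA arrays at the lower occiput/neck, where
  central rays graze the surface and would collapse disc spacing;
* **parallel** projection drops nominals along the anchor normal (flat
  test fixtures).

Tangent-plane offsets are arc-length corrected (`t' = R tan(d/R)`) so the
geodesic pitch stays near nominal on curved regions; chords between
adjacent centers on a doubly curved surface still fall a few percent short
of the geodesic distance, so the placement guard flags center distances
below 90% of a disc diameter as degenerate rather than treating every
sub-diameter chord as an overlap. The hard contract `radius > pitch/2` is
checked exactly.

The seven montages encode the study family: the supratentorial baseline
(forehead AP, high occipital PA, temporoparietal laterals); six
posterior-fossa alternatives sharing posteriorly displaced laterals whose
long axis is rotated 15° downward (the quoted "slight angular rotation" is
not quantified; 15° is an explicit, configurable default), with the PA
array horizontal at the lower occiput (optionally shifted ±20 mm
laterally — the montage pair patients use to rotate array positions between
exchanges) or vertical at two heights; and a variant with the AP array
rotated 90°. The baseline approximates output of proprietary planning
software and is documented geometry, not a reproduction of it. All anchor
directions are configuration parameters; the exact neck heights in the
source figures are unquantified, so the defaults are geometric choices
exposed in `default_layout_params()`.

On the exactly symmetric phantom, rotating the AP array by 90° maps the
square 3 × 3 disc lattice onto itself (the anchor normal has no lateral
component), so `AP_PA_HORIZONTAL` rasterizes to the same electrode voxels
as `PA_HORIZONTAL` and their metrics coincide exactly — a degeneracy of
the idealized geometry consistent with the marginal differences reported
for real anatomy.

Rasterization turns each disc into a one-voxel gel layer on the scalp
capped by electrode voxels; electrodes never touch scalp or skull
directly, voxels claimed by two discs go to the nearer center, and
removing the montage restores the anatomy exactly.

## Plan-quality metrics

For a scalar magnitude field and an ROI, the electric-field volume
histogram `EVH(t)` is the fraction of ROI volume with field ≥ t (closed
threshold, exact counting, equal voxel weights); `CDVH` is the analogue
for current density. From these:

* `E_AUC` / `CD_AUC` — area under the histogram from 0 to the ROI
  maximum. With fractional volume on the y-axis this equals the ROI mean
  magnitude (layer-cake identity); the default 2048-point trapezoid is
  within 1% of the exact mean and an exact per-unique-value mode exists
  for verification.
* `E_x%` — the largest threshold t such that at least x% of the ROI
  receives ≥ t (computed as the ⌈xn/100⌉-th largest voxel value):
  `E_50%` is the median intensity, `E_5%` the hotspot intensity (the
  hottest 5% of ROI volume — chosen because no clinical threshold dose
  exists for TTFields), `E_75%` the value exceeded by three-quarters of
  the volume. Ties resolve toward the larger threshold, making the
  duality `V(E_x%) ≥ x` exact (property-tested exhaustively).
* `V_Et` / `V_CDt` — percent ROI volume at or above fixed thresholds
  (E: 75/50/25 V/m; CD: 15/10/5 A/m²).

All metrics are scale-equivariant and the orderings
`E_75% ≤ E_50% ≤ E_5%` and `V_E75 ≤ V_E50 ≤ V_E25` hold by construction
and are asserted on every record.

The comparison report computes percent changes against the baseline
montage (on one-decimal half-up rounded values, the precision of printed
planning tables; percent strings recomputed from rounded entries can
differ from unrounded-internal figures by a few tenths, and differences
≤ 0.3 are treated as rounding-consistent), the arithmetic-mean row over
the six alternatives, and a ranking by `E_AUC`. A bundled worked-example
table (`reference_pqm()`) exercises this arithmetic on realistic numbers:
its alternative-montage means are 60.8 V/m (cerebellum `E_AUC`),
10.0 A/m² (cerebellum `CD_AUC`) and 86.2 V/m (GTV `E_5%`), and its
best-covering montage is PA-horizontal for both ROIs.

## Design choices that were genuinely open

* **Drive normalization.** Reported field metrics scale linearly with the
  drive, which commercial systems do not publish per channel. Normalizing
  to total delivered current (0.9 A default) rather than voltage keeps
  comparisons across montages meaningful; all claims are within-study
  comparisons, never absolute dosimetry.
* **Channel combination.** Whether published per-montage maps are
  per-channel, averaged or enveloped is unstated in this literature; the
  package defaults to the channel-average and exposes the alternatives.
* **Threshold convention.** "≥" everywhere, AUC integrated to the ROI
  maximum, fractional (not percent) volume on the y-axis — chosen once,
  oracle-tested, and consistent with AUC values that behave like mean
  fields.
* **Gel/electrode representation.** One-voxel gel with a quasi-metallic
  electrode cap (1e4 S/m) whose voxels carry the Dirichlet condition;
  electrode conductivity only enters through harmonic-mean face
  conductances, so the adjacent-material contrast stays bounded.

## Degenerate inputs and failure modes

Zero-radius tumors build with a warning and an empty mask (metrics then
refuse the empty ROI); specs whose skull shell is thinner than two voxels
at the requested spacing are rejected; a montage whose anode and cathode
have no conductive path is reported as a singular configuration (detected
by near-zero delivered current against the conductance scale, since the
partitioned Dirichlet system itself stays positive-definite);
non-convergence within the iteration cap carries the residual in its
error. Loaded NIfTI volumes must be integer-labelled and axis-aligned
RAS — anything else errors rather than silently reorienting.

## Problem sizes

The default study runs at 4 mm spacing (≈54 k conductive voxels of a
45 × 53 × 72 grid; two channels × seven montages in well under a minute),
the scale at which the test suite and the acceptance script exercise the
full pipeline. The refinement study above used 3, 2.5 and 2 mm
(≈430 k conductive voxels at 2 mm). The mini phantom used by fast tests
is a smaller head with proportionally thicker shells at 6 mm spacing.

## Known limitations

Single-patient-style geometry; isotropic conductivities; no permittivity
or thermal modelling; scalp placement by ray casting rather than geodesic
unrolling (adequate for convex phantom scalps, approximate for real
heads); montage anchor angles are documented defaults, not fits to any
patient; and absolute field magnitudes at 4 mm carry the discretization
bias quantified above.
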