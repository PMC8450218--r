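---
title: "Measuring and growing 3D unipennate muscle architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and growing 3D unipennate muscle architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pennate)
```

## The problem

A primarily unipennate muscle — fascicles running at a single oblique angle
between two sheet-like superficial aponeuroses — must adapt its architecture
as the organism grows: the belly lengthens and widens dramatically while the
fascicles themselves lengthen modestly and the pennation angle barely moves.
`pennate` provides (i) a measurement pipeline from raw digitized fascicle
polylines to the standard architectural parameters, and (ii) a geometric
growth model that, given one measured architecture and four scalar changes,
predicts the complete fascicle architecture at another size.

The pipeline assumes data in the form produced by point digitizers: one 3D
polyline per fascicle, all in a common coordinate frame, in millimetres, with
optional muscle–tendon-complex (MTC) endpoint landmarks.

## Measurement pipeline

### Smoothing and resampling

Each raw trace is smoothed by fitting each coordinate as a quadratic
polynomial of the *normalized cumulative chord length* of the raw points.
Chord length (rather than sample index/time) is used as the abscissa because
hand-guided digitizers sample at a fixed rate while the stylus speed varies;
both modes are available (`spacing` argument), chord length is the default.
The fitted space curve is evaluated at 20 points with equal *arc-length*
spacing — equal arc rather than equal parameter, because fascicle length L_F
is defined as the sum of the 19 segment lengths and should not depend on the
parameterization. Arc-length inversion uses a cumulative Gauss–Legendre table
(5-point rule on 256 subintervals, effectively exact for the smooth quadratic
speed) with safeguarded Newton refinement to ~1e-13 of the total length.
Degenerate inputs: traces with fewer than 3 points are rejected (with a
warning at the dataset level), collinear traces fit exactly as degenerate
quadratics, all-identical points are an error.

### Muscle frame

The frame comes from PCA of the fascicle endpoints: a provisional PCA of all
endpoints yields a provisional sheet normal; per fascicle, the endpoint with
the larger normal coordinate goes to aponeurosis A, the other to B; separate
PCAs of the two endpoint sets are then averaged (first components →
e₁, second components, orthogonalized → e₃), e₂ = e₃ × e₁ completes a
right-handed triad, and one refinement pass re-assigns the endpoints with the
updated normal. Sign conventions are fixed so results are reproducible: e₁
points proximal→distal when MTC landmarks are present, otherwise so the
endpoint skewness along e₁ is non-negative; A is the aponeurosis on the +e₂
side. A rank-deficient endpoint cloud (e.g. a single fascicle, or all
endpoints collinear) is an error; `muscle_frame()` lets the user supply an
explicit frame for such degenerate data or for phantoms whose frame is known
by construction.

### Parameters

* **Angles** are computed from the fascicle *chord* (endpoint to endpoint),
  not a local tangent, because each fascicle is reported with a single β and
  α: β = deviation of the chord from the e₁–e₃ plane, α = deviation of its
  in-plane projection from e₁, both folded into [0°, 90°]. A chord
  perpendicular to the aponeurosis plane has β = 90° and an undefined α,
  reported as 0 with a flag.
* **Aponeurosis length/width** are endpoint extents along e₁/e₃ per
  aponeurosis; summary tables report the mean of the two sheets.
* **Muscle height** is the distance of the two aponeurosis centroids along
  e₂.
* **Belly length/width** (L_MB, W_MB) are extents of *all* resampled points
  along e₁/e₃ — curved fascicles may bulge past their endpoints. W_MB is
  needed by the width-scaling operation and follows the same extent
  convention as L_MB.
* **Volume** encloses all tracked points in an alpha-complex boundary built
  on a 3D Delaunay tetrahedralization. The shrink fraction in [0, 1]
  interpolates on the sorted spectrum of tetrahedron circumradii between the
  convex hull (shrink 0: all tetrahedra kept, hull volume exact) and the
  critical alpha (shrink 1: smallest alpha whose complex contains every point
  in one face-connected component). The default 0.6 keeps a tight, partly
  non-convex fit. Bit-exact replication of any particular external boundary
  implementation is not promised; the contract is this shrink-spectrum
  definition.
* **Mass and PCSA**: mass = V_m · 1.056·10⁻³ g/mm³ (skeletal muscle density,
  stored internally per mm³), PCSA = V_m / mean L_F. By construction
  PCSA · L̃_F = V_m exactly.
* **Free tendon length** = Euclidean origin–insertion landmark distance minus
  L_MB; a negative value (landmark/frame inconsistency) is returned with a
  warning rather than silently clipped. Chord distance is used for the MTC
  length since landmark pairs, not digitized tendon paths, are recorded.

## Growth model

Four operations, applied per fascicle in a fixed order — length scaling,
width scaling, fascicle lengthening, fascicle rotation — with the frame,
belly dimensions, side split, correction factor and line of action determined
**once** from the input dataset. Fascicle count never changes.

**Length scaling.** Fascicles translate rigidly along e₁ by
Δx_F = x_F · (ΔL_MB / L_MB) · f_c with x_F the arc-midpoint coordinate
measured from the proximal extreme of the point cloud (so the map stretches
rather than translates). Because only midpoints are scaled, the raw shift
under-shoots the intended extent change; f_c ≥ 1 corrects this.
`determine_fc()` defines f_c operationally — the unique factor for which the
shifted cloud's e₁ extent equals L_MB + ΔL_MB — and finds it by bisection
(uniqueness from monotonicity of the extent in f_c). Length scaling is a
per-fascicle isometry and preserves the muscle height.

**Width scaling.** The cross section is divided by the plane spanned by e₁
and e₂ through the centroid of the fascicle midpoints. Each side gets its own
transversal direction from a PCA of that side's endpoints of the *crested*
aponeurosis — chosen as the sheet with the larger out-of-plane PCA residual,
so a central ridge is respected and the cross-sectional shape is preserved;
the direction is the side sheet's in-plane width axis (sheet normal × e₁),
orthogonal to e₁ by construction, pointing away from the dividing plane.
For planar muscles these reduce to ±e₃; a side with fewer than 3 points falls
back to ±e₃ with a warning. Displacements are
Δy_F = y_F · (ΔW_MB / W_MB) along the side direction, with y_F the midpoint's
distance from the dividing plane measured along that direction. All
displacements are ⊥ e₁, so the belly length is untouched.

**Fascicle lengthening.** Endpoint displacements are proportional to the
endpoint's perpendicular distance d to the muscle's line of action
(|u₂|/|u₁| = d₂/d₁, |u₁| + |u₂| = ΔL_F), which limits protrusion of interior
structures. The line of action runs through the MTC landmarks when present,
else along e₁ through the centroid of all points. The displacement
*direction* and the motion of interior points are design choices: the package
stretches all 20 points affinely along the chord about an anchor placed on
the chord at fraction d₁/(d₁+d₂) from endpoint 1, with the stretch factor
solved so the resampled *arc length* (the defining quantity of L_F) equals
L_F + ΔL_F to 1e-9 mm (Newton on the closed-form stretched-polyline length).
For straight fascicles the endpoint conditions then hold exactly; for curved
ones the displacement sum is approximate while the arc-length target is
exact, and fascicle curvature never increases. A fascicle lying on the line
of action splits ΔL_F equally with a warning.

**Fascicle rotation.** Each polyline rotates rigidly by Δβ about the axis
through its arc-length midpoint perpendicular to the vertical plane spanned
by e₂ and the chord's in-plane projection: β increases by exactly Δβ, α, L_F
and the midpoint are unchanged. β + Δβ is clamped to [0°, 90°] with a
warning; fascicles at β = 90° (undefined projection) are skipped.

### Composing the operations: where f_c acts

The lengthening and rotation steps also move points along e₁ (a stretched or
rotated chord has a different e₁ extent), so applying the four operations
naively would miss the target belly length by millimetres. Since the purpose
of the correction factor is precisely that the output belly length *actually*
changes by ΔL_MB, `grow_muscle()` solves the length-scaling rate
g = (ΔL_MB/L_MB)·f_c on the **composed** transformation: a bracketed
regula-falsi iteration (Illinois variant; the extent is piecewise linear in
g) drives the final e₁ extent to L_MB + ΔL_MB within 1e-9 mm. This also
handles ΔL_MB = 0 with nonzero ΔL_F or Δβ, where g compensates the other
operations' extent side-effects. The standalone `scale_length()` /
`determine_fc()` keep the single-operation definition. With all four
parameters zero, `grow_muscle()` returns its input unchanged, bit for bit.
Operation order matters (lengthening acts along the *current* chord), and the
canonical order above is fixed; permuting, e.g., lengthening and rotation
gives a different result whenever the line of action is not a symmetry axis.

## Synthetic muscles and what the tests show

`simulate_muscle()` builds phantoms with known ground truth: fascicles run
between two aponeurosis sheets separated by the muscle height, tilted by the
pennation angle in the length–height plane (transversal angle constructed as
0 — the unipennate idealization), placed on a jittered grid over
length × width; within the last, partial grid row central width columns are
filled first so the layout introduces no length–width covariance (which would
tilt the PCA frame). Fascicle lengths are normal; endpoints lie exactly on
their sheets pre-noise. Options add a central crest (a tent-shaped upper
sheet with a given dihedral), a quadratic bow, and Gaussian digitizer noise
applied to the raw traces *before* preprocessing so the smoothing stage is
exercised. Ground truth (lengths from dense evaluation of the exact curves,
angles and extents from the construction, slab volume for planar
crest-free phantoms) is computed analytically, never through the measurement
pipeline. Defaults were chosen once to mirror a young rabbit plantaris and
its digitizer: 252 fascicles, belly 50.8 × 7.7 mm, fascicles 13.7 ± 1.2 mm at
11.6°, free tendon 14.5 mm, noise sd 0.076 mm (the device accuracy), 25
points per raw trace; height derives as L̄_F·sin β̄ unless given. Scaling all
linear dimensions of the configuration by k scales every length-valued truth
field by k under the same seed.

The phantoms are idealized: real muscles have curved, non-parallel
aponeuroses, fascicles attaching to internal aponeuroses, spatially varying
pennation and genuine transversal angles. Passing closure and recovery tests
therefore certifies the geometry engine and its contracts, not measurement
accuracy on dissected specimens.

Two frame conventions in the test design deserve note. First, *parameter
recovery* (grow, re-measure, compare deltas) is evaluated in the phantom's
exact construction frame, supplied both to the growth context and to the
re-measurement. The model defines its deltas in its fixed preprocessing
frame; with a re-estimated PCA frame, a ~10⁻³ rad frame tilt (finite-sample
jitter of the endpoint grid) projects the ~50 mm belly extent into the width
axis and adds a seed-dependent pseudo-error of up to ~1 % on ΔW_MB — frame
estimation noise, not transformation error. Frame estimation itself is tested
separately (axis recovery to 1e-9 under known rotations; closure of the full
estimated-frame pipeline at fixed seeds). Second, *measurement closure*
against ground truth runs at the generator's default density (252 fascicles);
much sparser clouds let the shrink-0.6 boundary carve gaps between fascicle
columns, which is a property of alpha shapes on sparse data, not of the
estimator.

## Numerical choices

* Arc-length inversion: Gauss–Legendre cumulative table + safeguarded Newton,
  tolerance ~1e-13 of curve length.
* f_c and the composed scaling rate: bisection / Illinois regula falsi on
  monotone piecewise-linear extents, 1e-10–1e-11 mm residuals.
* Lengthening stretch factor: Newton on the closed-form arc length
  Σ√((k·Δa)² + Δp²), residual < 1e-12 mm.
* Delaunay (compiled): incremental Bowyer–Watson with a strict in-sphere
  predicate; the cloud is centred, rotated to its principal axes with
  skewness-fixed signs (making the volume invariant under rigid motion of the
  input by construction), scaled to unit size, and perturbed by a
  deterministic, RNG-independent jitter of 1e-6 of the bounding box to break
  the cospherical degeneracies of grid-like digitized data. Near-flat
  tetrahedra get an effectively infinite circumradius so they are absorbed at
  large alpha without affecting volumes. The shrink threshold indexes the
  sorted circumradius spectrum between the critical alpha and the maximum.
* Ties and degenerates: equal provisional-normal coordinates assign endpoint
  2 to B; a fascicle at β = 90° is skipped by rotation; measured-zero
  baselines are skipped (with warning) in error tables; missing optional
  fields serialize as empty/null, never 0.

## Limitations

* The model transforms fascicles only; landmarks are dropped from grown
  datasets because tendon growth is not modelled.
* |u₁| + |u₂| = ΔL_F is exact only for straight fascicles (documented
  deviation of the chord-stretch realization).
* For strongly crested muscles the width-scaling directions are tilted, so
  the realized e₃-extent change is smaller than ΔW_MB by roughly cos² of the
  crest angle — a property of side-wise scaling, not an implementation error.
* The boundary volume of sparse clouds at high shrink depends on sampling
  density; volumes of datasets with only tens of fascicles should be read
  with corresponding caution.
* Fitting the four growth parameters from two datasets by optimization is out
  of scope; parameters are taken as direct differences of measured summaries.
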