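---
title: "Parametric preparation geometry and volumetric substance removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric preparation geometry and volumetric substance removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

How much tooth substance does a preparation for an all-ceramic restoration
remove, and which preparation parameter drives that loss? prepvol answers
this with a fully digital workflow: a parametric cutter geometry is built
from four preparation parameters, subtracted from a watertight tooth solid
by a Boolean operation, and the removed volume is reported as a percentage
of the intact crown (the root is removed along the cementoenamel junction,
CEJ, so it never enters the denominator). Because every step is
deterministic geometry, a full factorial sweep over the parameter grid
(5 angles x 8 chamfer depths x 6 finish-line distances x 3 occlusal
reductions = 720 designs) is reproducible to the millimetre.

The four parameters, with the package defaults for the factorial grid:

| parameter | meaning | grid levels |
|---|---|---|
| preparation angle | half of the convergence angle: the axial wall's tilt from the crown's long axis, converging occlusally | 6, 8, 10, 12, 14 degrees |
| chamfer depth | radial width of the concave finish-line curvature, equal to the transition-arc radius | 0.2-1.6 mm in 0.2 mm steps |
| finish-line distance | vertical height of the margin above the CEJ; 1 mm is a full crown, 4 mm a partial crown, 6 mm an occlusal onlay | 1-6 mm in 1 mm steps |
| occlusal reduction | vertical clearance created on the biting surface | 0.5, 1.0, 1.5 mm |

## The preparation construction

1. **Margin extraction.** The finish line is placed at each angular
   station a fixed vertical distance above the CEJ, on the tooth surface.
   With a non-planar CEJ the margin follows its waviness (a `"planar"`
   mode exists for fixtures with planar margins).
2. **Chamfer profile.** In local (radial, vertical) coordinates the
   profile starts at the margin with a horizontal floor tangent, follows a
   circular transition arc whose radius is the chamfer depth, and
   continues as a straight axial wall tilted by the preparation angle.
   The profile is C1-continuous by construction; the arc sweep is
   90 degrees minus the preparation angle.
3. **Axial cutter.** Sweeping the profile along the margin (profile
   origin on the margin point, radial axis pointing outward from the tooth
   axis) produces the inner boundary of a hollow cutter solid whose outer
   boundary is a cylinder strictly containing the tooth; it is closed
   below the margin floor and above the apex. Margins must be star-shaped
   about the axis; a margin point on the axis is a geometry error.
4. **Occlusal cutter.** The cutter's lower boundary is the occlusal table
   translated down the axis by the occlusal reduction (anatomic reduction:
   uniform vertical clearance over the cusps), blended to zero within a
   0.8 mm (3D) distance of the margin curve and lightly
   Laplacian-smoothed. The blend is what keeps a chamfer finish line
   intact on an onlay, where the translated surface would otherwise
   undercut its own margin; on a full crown the margin is far from the
   table and the clearance is uniform.
5. **Boolean subtraction and seam smoothing.** Axial cutter first, then
   occlusal cutter, then Taubin smoothing restricted to a band around the
   Boolean seams.

## The Boolean backend

No general-purpose CSG library is used: the subtraction is performed
exactly on the implicit fields that define both operands. Every solid in
the pipeline is axis-star-shaped: it can be written as

```
{ rho <= R(theta, z) }  ∩  { z <= H(x, y) }  ∩  bottom cap,
```

with `R` the lateral radius field and `H` the occlusal height field.
Subtracting the axial cutter replaces `R` by the pointwise minimum of the
tooth field and the exact swept-profile field; subtracting the occlusal
cutter takes the minimum of the height fields. The result is re-meshed on
a boundary-fitted structured grid: wall rows follow the (chamfer-arc
resolving) profile path from the CEJ to the junction where the wall meets
the occlusal field, a polar cap grid covers the top, and a fan cap closes
the bottom. The junction is found by a vectorized march with bisection
refinement. Cutter meshes (for export and inspection) are tessellations of
the same fields, so mesh and field never disagree.

Two subtleties are worth recording:

* The cap surface respects the tooth's *wall envelope* (the largest height
  at which the lateral radius still reaches a given plan radius), so a
  preparation whose margin sits on the occlusal shoulder keeps the
  remaining shoulder in the result instead of capping above it. The
  envelope is sampled conservatively (inner grid value) because its
  inverse is near-vertical at flat radius maxima.
* The junction march uses the occlusal *table* criterion only; the wall
  itself may legitimately revert to the tooth surface where the cutter is
  outside the tooth, and an envelope-based criterion would graze there.

For meshes loaded from file (`tooth_from_mesh()`), the fields are
recovered by casting horizontal rays from the axis (lateral field) and
vertical rays (height field) against the actual triangles; the junction is
taken where the lateral ray data end, since horizontal and vertical probes
degrade in complementary regions of a crown. External meshes must be
watertight, millimetre-scaled (`scale_to_reference()` applies the
reference-mark scaling), +z occlusal, and star-shaped about the axis.

## Volumes and the voxel oracle

Volumes are divergence-theorem sums over triangles; watertightness is
checked (boundary edges, non-manifold edges, winding consistency, and a
sampled triangle-triangle self-intersection test). The independent
cross-check is a voxel oracle: voxel centers are classified by ray parity
along the three coordinate axes with a 2-of-3 majority vote (the grid
origin carries a sub-voxel jitter so centers never lie exactly on
axis-aligned faces). At 0.05 mm voxels the oracle and the mesh volume
agree to well under one volume point on all shipped fixtures.

## Seam smoothing

Boolean seams (dihedral angle above 45 degrees) and the vertices within
0.3 mm of them receive Taubin smoothing (lambda = 0.5, mu = -0.53, 10
iterations - a volume-conserving positive/negative diffusion pair). A
guard limits the smoothing-induced volume change to 0.5% of the removed
volume; if exceeded, the iteration count is halved with a warning, because
aggressive rounding would systematically bias the removal percentages the
package exists to measure. The smoothing delta is recorded in each
result's provenance.

## The synthetic fixtures

The scanned molar that motivates this workflow is not distributable, so
the package generates its own watertight tooth solids:

* `make_cylinder_tooth()` - a right circular cylinder crown with planar
  CEJ and flat top. Its preparations have closed forms (cylinder +
  frustum; revolved chamfer profiles integrate by 1D quadrature), which
  makes it the oracle for the Boolean pipeline: zero-chamfer preparations
  match the frustum formula to better than 0.1 volume points.
* `make_molar_like()` - a molar-like crown: superellipse cross-section, a
  slight cervical bulge (height of contour) over near-vertical axial
  walls with a gentle overall convergence, and a deeply sculpted occlusal
  table (Gaussian cusps, central fossa) closing the crown; below the CEJ
  a simple frustum root (its shape never matters - the denominator is
  crown-only). The CEJ runs as a cosine wave
  (`amplitude x cos(lobes x theta)`).

The molar's default proportions (CEJ radius 5.5 mm, crown height 7.5 mm,
four cusps, 1 mm CEJ wave) sit within published molar anatomy ranges; they
are documented constants, not anatomical claims. The wall profile - slope
below tan(6 degrees) along the whole axial wall - was chosen so that every
preparation wall in the study grid stays in tooth contact over its full
height, which is what makes the factorial response behave like a posterior
crown's: per-step chamfer increments shrink as the chamfer broadens
(circumference effect), the angle response is nearly linear, and
finish-line increments grow toward the CEJ. Cusp positions and heights are
jittered deterministically from the spec seed; identical spec + seed gives
byte-identical meshes.

What passing tests on these fixtures do show: the Boolean pipeline is
volumetrically correct (closed forms, voxel oracle), and the factorial
machinery reproduces the qualitative structure of preparation-parameter
effects (monotonicity, trend shapes, effect ranking, restoration-class
ordering). What they do not show: absolute vol% values for any real tooth
- those are entirely fixture-dependent, and only trends transfer.

## Numerical choices

* Units: millimetres after `scale_to_reference()`; STL input is treated
  as unitless until scaled. Occlusal direction is +z; the CEJ sits near
  z = 0; the frame is right-handed.
* Vertex merge tolerance 1e-6 mm (far below manufacturing relevance).
* Default re-meshing density: 256 angular stations, 72 profile rows,
  44 cap rings (0.01% volume discretization error on the cylinder).
  Factorial sweeps use the `"fast"` preset (144 stations), which keeps a
  cell at roughly half a second while changing removal percentages by
  less than a few hundredths of a volume point; the acceptance script and
  the test suite run their studies at this preset.
* Monotonicity and trend assertions use a 0.05 volume-point tolerance -
  the re-meshing noise floor between neighbouring cells.
* The angle-linearity statistic (relative spread of per-2-degree
  increments) is evaluated on combinations where the angle has a material
  effect (mean increment at least 0.1 vol points). Where a tall finish
  line and a large reduction leave almost no axial wall, the increments
  are all but zero and a relative spread is noise; the same near-zero
  angle effect at tall finish lines is visible in the study this package
  re-implements.
* The root cut: a literal ruled surface from the CEJ curve to its
  horizontal projection on the axis degenerates along an axis segment
  when the CEJ is wavy, so the cap blends the height linearly from the
  curve to its mean level at the center. It passes exactly through the
  CEJ curve, is watertight, and - the property that matters - is
  identical for every specimen cut with the same curve.
* Effect ranking uses the mean absolute swing of removed vol% across a
  parameter's full level range, averaged over the combinations of the
  other parameters; ties are flagged and broken by the declared order.

## Limitations

* Only chamfer finish lines; no shoulder or feather-edge geometry, no
  undercut detection, no path-of-insertion optimization, and no
  restoration (crown) geometry.
* The Boolean backend covers axis-star-shaped solids - exactly the class
  the preparation workflow produces - not arbitrary CSG.
* Scan noise, enamel/dentin sub-volumes and multi-rooted anatomy are not
  modelled; weight-percent conversions (density modelling) are out of
  scope.
* The occlusal-reduction blend width (0.8 mm) and the smoothing settings
  are exposed free constants; results are insensitive to them at the
  guard level but they are choices, not measurements.
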