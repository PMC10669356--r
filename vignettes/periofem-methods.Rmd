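---
title: "Modelling periodontal load capacity with periofem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling periodontal load capacity with periofem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Teeth are suspended in their sockets by the periodontal ligament (PDL), a
soft tissue layer roughly 0.1 mm thick between the root cementum and the
alveolar bone.  Periodontal disease removes attachment — ligament and
supporting bone — progressively from the cemento-enamel junction (CEJ)
toward the apex.  `periofem` asks the biomechanical question behind the
clinical one: as attachment is lost millimetre by millimetre, how does the
pressure transmitted across the remaining PDL–bone interface grow, where
does it concentrate, and at what point does the remaining support become
mechanically hopeless?

The package implements the full pipeline as reusable parts: parametric
layered tooth–PDL–bone geometry, conforming tetrahedral meshing, a static
linear-elastic finite-element solver, contact-pressure extraction on the
PDL–bone interface, and an attachment-loss sweep with failure detection.

## Model and assumptions

All tissues are isotropic linear-elastic; the analysis is a small-strain
static solve.  Units are mm–N–MPa throughout (1 N/mm² = 1 MPa).  The
tissue library is:

| tissue | E (MPa) | nu |
|---|---|---|
| enamel | 84 000 | 0.33 |
| dentin | 18 600 | 0.31 |
| pulp | 2.07 | 0.45 |
| PDL | 68.9 | 0.45 |
| gingiva | 3.0 | 0.45 |
| cortical bone | 13 700 | 0.30 |
| cancellous bone | 1 370 | 0.30 |

Cementum carries no separate entry; it inherits the dentin constants by
default (the two root hard tissues are elastically close and the layer is
50–150 µm thin); `materials_for()` takes overrides.  The PDL is visco-elastic
in reality; the linear-elastic idealization makes the response exactly
proportional to load, which the solver exploits (one factorization per
geometry, ramp steps as exact scalings) and verifies numerically on every
solve (reaction-sum equilibrium to 1e-6 relative, load-scaling residual to
1e-9 relative).  Near-incompressibility (nu = 0.45) is handled with
quadratic (10-node) tetrahedra, the default element order.

## Parametric anatomy

`build_tooth(tooth_params(...))` constructs an idealized single-rooted tooth
(canine/premolar-like) or a two-rooted molar in a bone block:

* crown with an enamel cap (thickness 0.8 mm) that pinches out at the CEJ,
  dentin body, pulp chamber (`pulp_scale` of the dentin envelope, canal
  ending at 75 % of root length);
* root tapering from `root_cervical_radius` to `root_apical_radius` with a
  rounded apex cap;
* cementum between dentin and PDL, stepped 50/100/150 µm over the
  cervical/middle/apical thirds of root height (the step boundaries are not
  anatomically sharp; thirds with abrupt steps are the simplest consistent
  reading, applied along the root axis);
* a uniform 0.1 mm PDL shell from the CEJ to the apex, including an apical
  cap and — for the molar — a furcation-roof sheet;
* alveolar bone as a cancellous core with a cortical shell (1.5 mm) on the
  outer block faces, crest at the CEJ at full attachment.

The frame puts the origin at the CEJ centroid, +z apical, +x ventral; all
models are mirror-symmetric about y = 0.  Tooth dimensions are patient- and
tooth-specific in reality, so the defaults (root length 13 mm single-rooted
/ 12 mm molar, furcation 3 mm below the CEJ, root spread 7 mm) are generic
adult values from standard dental anatomy, and every one is a parameter.

Attachment loss is `reduce_attachment(model, h)`: ligament and supporting
bone are removed coronal to the plane z = h; the exposed root surface is
bare cementum, and reductions past the furcation depth expose the furcation
roof.  Gingiva is excluded from the mechanical model by default (at 3 MPa it
is negligible against bone); `include_gingiva = TRUE` adds a collar over
exposed root surfaces when attachment has been reduced.

## Meshing

The mesher is a deterministic mapped-template extrusion.  A fixed 2D
cross-section template — a tensor background grid with one square port per
root, each filled by an O-grid of concentric rings — is morphed per z-plane
so that every tissue interface (pulp, dentin, cementum, PDL, bone) falls
exactly on template rings, then extruded into prisms between z-planes and
split into tetrahedra.  Quad-face diagonals follow the minimum-vertex rule,
so the two prisms sharing a face always agree and the mesh is conforming
everywhere: bonded contact is shared nodes, with no contact algorithm or
penalty parameter.  The PDL is always two element layers thick — two
template rings through the radial shell, split slabs through the apical cap
and the furcation roof — regardless of the characteristic size.

The molar's inter-radicular web (root trunk) spans the septum between the
two ports above the furcation.  Its buccal/lingual flank cannot carry a
0.1 mm ligament in this template, so a narrow free gap (0.4 mm plus one
guard sector per side) separates the web from the bone there, ending at the
furcation-roof ligament.  The consequence is deliberate: the occlusal load
can reach bone only through the ligament, which the flux checks confirm
(the discrete interface force equals the applied load to solver precision;
the *recovered-stress* integral agrees within about 1 %).

Element labels, not geometry, change with attachment reduction, so sweep
meshes at different reductions share node layouts, and rebuilding a model
twice gives bit-identical meshes; there is no stochastic step anywhere in
the pipeline.

## Loading, supports, readouts

The load protocol is a linear ramp (70 steps by default, kept for parity
with stepped quasi-static protocols) to a terminal force applied as uniform
traction on the occlusal patch: axial (+z, pressing the tooth into the
socket) plus a ventral transverse component at half the axial magnitude.
The whole-jaw masseter figures (700 N cranial, 350 N ventral, resultant
782.6 N) are not a per-tooth load; a single-tooth submodel defaults to a
tenth of them, and `calibrate_load()` rescales the protocol so the
full-support peak PDL pressure matches a chosen anchor (0.48 MPa in the
worked examples).  Because the model is linear this calibration is exact and
makes attachment-loss *trends* comparable across geometries without
asserting a muscle-to-tooth force transmission.  The outer bone-block
boundary (lateral walls and base) is fixed.

Contact pressure on the PDL–bone interface is the normal component of the
transmitted traction, evaluated from the PDL-side element stress,
compression positive, tension negative.  Because element-wise maxima of a
recovered stress are the most mesh-sensitive readout, the maps report the
peak together with the area-weighted 99th percentile and mean.  Zones
partition the interface — cervical: the coronal 25 % of the *remaining*
interface height; apical: the apical 2 mm; furcation roof: within 1.5 mm of
the roof point; mid-root: the rest — with assignment in that priority, so
zone areas always sum to the interface area.  These widths are reporting
conventions, not anatomy, and are arguments of `regional_summary()`.

## The attachment-loss study

`run_sweep()` evaluates reductions 0–9 mm in 1 mm steps, records peak/p99/
mean pressure, zone summaries and solver checks per step, and applies the
failure rule: a tooth is predicted to fail when the peak PDL pressure
exceeds a threshold (default 0.90 MPa, the largest pre-failure value on the
scale the study is calibrated to) or when a step leaves the model without
ligament support.  After a first failure one confirmation step is evaluated
and the remainder are marked not evaluated.  `compare_tooth_classes()`
requires both sweeps to share the calibrated protocol and reports the
failure ordering between classes.

Default problem sizes were chosen as the coarsest meshes whose peak-pressure
readout is mesh-converged (below): sweeps run at characteristic size 2.0 mm
(about 19 000 quadratic tetrahedra for the single-rooted model and 33 000
for the molar), and a sweep of ten reductions completes in a few minutes on
one core.

## Numerical verification and convergence

* **Patch test** — a homogeneous block under uniform uniaxial traction
  reproduces the closed-form stress and strain fields to 1e-8 for every
  library tissue (quadratic elements represent linear fields exactly; the
  remaining error is solver tolerance).
* **Cantilever** — tip deflection at aspect ratio 10 with quadratic
  elements lands within 5 % of Euler–Bernoulli theory (the residual
  difference is genuine shear deformation plus the clamped-face
  constraint, both absent from beam theory).
* **Rigid-body modes** — the unconstrained stiffness has exactly six zero
  eigenvalues.
* **Mesh convergence** — the default three-level study (sizes 2.6, 2.0,
  1.4 mm) tracks the peak PDL pressure of the full-support single-rooted
  model; the change between the two finest levels is below the 2 %
  tolerance.  These levels refine the in-plane discretization; the layer
  resolution through the 0.1 mm ligament is fixed by the anatomy (two
  elements) at every level.  The peak sits at the cervical margin, a free
  edge where the continuum field has a weak concentration: refining the
  *axial* slab height near the crest would keep sharpening the last sample
  row, which is why the 99th percentile is always reported alongside the
  peak and why convergence is assessed at fixed layer resolution.

## What the synthetic geometry does and does not emulate

The parametric models stand in for patient-specific CBCT segmentations.
They reproduce the features that drive the mechanics — layer topology and
thicknesses, root taper and count, furcation, stiffness contrasts, crest
position — but not root curvature, cross-section ovality, bone density
gradients, or real occlusal contact patterns; absolute pressures therefore
depend on these idealizations (and on the calibration anchor), and only
orderings and trends — zone concentration patterns, monotone convex
pressure escalation with attachment loss, the apical shift of transmitted
load, the single/multi failure ordering — are claims the tests make about
real teeth.

Known limitations: linear-elastic PDL (no visco-elasticity, no nonlinear
fibre recruitment), no frictional occlusal contact (traction replaces the
antagonist), single-tooth submodel (no neighbouring teeth or full arch),
and the molar trunk-flank free gap described above.  Imported STL/PLY
surfaces are supported for geometry queries, validation and PDL synthesis,
but volume meshing requires the parametric generator.
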