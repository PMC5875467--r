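---
title: "Methods: EPID-based table rotation alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EPID-based table rotation alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its measurement model, the
numerical choices inside it, and what the built-in simulator does and does
not demonstrate.

## The measurement model

### Coordinate frames and sign conventions

All analysis coordinates live at the isocenter plane: detector millimeters
divided by the magnification $M = \mathrm{SID}/\mathrm{SAD}$. The room
frame is right-handed with lateral positive toward the A side, longitudinal
positive toward the gun (G), and vertical positive up. The MV (panel) frame
at gantry 0 coincides with the horizontal room plane: $u$ toward A, $v$
toward G; image columns increase toward A and rows toward T, so
$u = \text{col}\cdot p/M$, $v = -\text{row}\cdot p/M$ for pixel pitch $p$.
Table rotation is counterclockwise-positive viewed from above.

Vendors do not publish their internal sign conventions for "toward A" /
"toward T" service prescriptions, so this package fixes its own and prints
it in every report (`XGT` positive toward G, `YAB` positive toward A); an
engineer comparing against a vendor worksheet needs to reconcile signs
once per installation.

A room-frame offset $(x_{AB}, y_{GT}, z)$ projects onto the panel at gantry
angle $\gamma$ as $u = x_{AB}\cos\gamma + z\sin\gamma$, $v = y_{GT}$; the
component along the beam axis is invisible. This is what makes the 8-image
placement solve work: the four cardinal gantry angles interrogate the
lateral and vertical components in quadrature while the longitudinal
component appears identically in every image.

### Sub-pixel BB and field localization

The field center in each image is the midpoint of the 50% penumbra
crossings of the central row and column profiles, each crossing located by
linear interpolation between the two straddling pixels. The open-field and
out-of-field levels are estimated from the 99.5% and 5% intensity
quantiles; images whose dynamic range is below 10% of the bright level are
rejected as having no field, and profiles that never drop below threshold
at the panel edge are rejected as truncated fields.

The BB is found inside the field mask (eroded by the BB radius plus 2 mm so
penumbra pixels cannot masquerade as the shadow minimum) as the centroid of
the near-minimal region of a 5×5 box-smoothed copy of the image. Using the
centroid of the near-minimum set rather than `which.min` matters in
noiseless renders, where the shadow bottom is flat and an argmin would sit
at the rim of the tie region. From that guess, 64 radial profiles are
sampled bilinearly at 0.2-pixel steps and the BB edge is located on each as
the sub-pixel crossing of the level halfway between the shadow core and the
local open-field level. A circle with radius fixed to the projected BB
radius (4 mm at isocenter scale for the 8 mm BB) is fitted to the edge
points by minimizing $\sum_i(\lVert p_i - c\rVert - r_0)^2$ over the center
$c$ only, via the fixed-point iteration
$c \leftarrow \overline{p} + r_0\,\overline{(c-p_i)/\lVert c-p_i\rVert}$
seeded by the free (Kasa) fit. The free-radius fit must agree with the
projected BB size within 10% or the detection is rejected — this is the
size constraint that keeps the fit from locking onto non-BB structure. Ray
casting and fitting are run twice (the second pass from the refined
center); one refinement is enough at the noise levels of interest, and a
fixed count keeps runtime bounded.

The intensity-weighted centroid of the shadow is also implemented
(`couchalign:::bb_centroid_intensity`) but only as an independent
cross-check in the test suite; the edge-based constrained fit is the
estimator of record because it is insensitive to intensity gradients across
the field and to the shadow's interior texture.

### The 8-image placement solve

For each cardinal gantry angle, the beam axis is the mean of the field
centers at collimator 0° and 180° (a jaw asymmetry maps to its negation
under the half-turn, so the mean cancels it), and the measured displacement
is the BB centroid minus that axis. The 3D BB offset is the least-squares
solution of the 8-equation system (4 gantry angles × the $u$ and $v$
equations). The $v$ equations are mutually redundant — all four measure the
longitudinal component — and are deliberately kept in the system with equal
weight instead of being averaged first: their residuals then expose
longitudinal inconsistency (gantry sag, panel shifts) as a QC signal in
`per_image_residuals`.

The caliper correction is the negated offset with each component quantized
to the caliper resolution (default 0.05 mm, a Vernier readability figure;
configurable). Exact half-quantum ties round away from zero, implemented
with a 1e-9 relative epsilon before `floor(q + 0.5)` so that decimal ties
such as 0.125/0.05 behave as true ties despite binary floating point.

### Trajectory, circle fit, and adjustment

The first rotation image (table 0°, BB previously placed at isocenter)
defines $(0,0)$; every subsequent BB position is expressed relative to it.
For a rotation-axis offset $c$ the trajectory is $p(\theta) = c -
R(\theta)c$, a circle through the origin centered on $c$ with radius
$\lVert c\rVert$; the maximum rotational error over a ±90° sweep is
$\sqrt{2}\,\lVert c\rVert$, which the acceptance suite checks against the
simulator analytically.

The circle is fitted with the plain algebraic Kasa method: solve
$x^2+y^2 = 2ax + 2by + c$ linearly. Kasa is known to be biased toward
smaller radii on short arcs, but the sequence here spans a half circle and
the test suite bounds the deviation from a brute-force grid-search
minimizer of the summed squared radial deviation (0.005 mm grid) at
0.05 mm. No origin constraint is imposed on the fit even though the
$\theta=0$ point is the origin by construction — the unconstrained center
is what the adjustment needs, and the fitted circle's distance from the
origin doubles as a consistency check. Clockwise and counterclockwise
points are fitted jointly; per-direction centers are reported as a
hysteresis diagnostic because real couches show direction-dependent
profiles from asymmetric braking.

Point clusters with spread below 0.05 mm (an aligned table) are flagged
degenerate and returned as centroid-with-zero-radius rather than an error;
truly collinear configurations raise a degenerate-geometry error.

The default 15-angle sequence
$(0, 30, 60, 90, 60, 30, 0, -30, -60, -90, -90, -60, -30, 0, 0)$ covers
±90° in both directions of travel with deliberate revisits; it is a
configuration item and the analysis accepts any list of at least 3 angles
starting at 0.

### Screw conversion

$\theta_A = X_{GT}/k_{GT} + Y_{AB}/k_{AB}$ (degrees CCW, A-side fixing) and
$\theta_B = X_{GT}/k_{GT} - Y_{AB}/k_{AB}$ (degrees CW, B-side fixing),
with vendor constants $k_{GT} = 0.01779$ and $k_{AB} = 0.01843$ mm/degree
for the supported table base. The inverse is analytic and the round trip is
exact to machine precision. Whether these constants hold for both one- and
two-piece tabletops is not documented by the vendor, so they are
overridable per machine. Outputs are also printed in fractional turns for
service use.

## The virtual linac

The simulator exists so the full measure→adjust loop can be validated
closed-loop against known ground truth. It models:

- the rigid kinematics $p(\theta) = R(\theta)(p_0 - c) + c$ of a BB fixed
  to a tabletop rotating about an offset axis;
- image formation as a separable open square field (50% penumbra at the
  nominal edges, Gaussian blur of SD 0.3 mm at isocenter scale), a BB
  shadow as a blurred attenuation disk of depth 35% of the open-field
  level, optional single-jaw asymmetry whose pattern negates under
  collimator 180°, additive Gaussian pixel noise, and 16-bit quantization;
- actuators: quantized caliper translations of the BB stand and
  fixing-screw rotations that translate the rotation axis via the same
  conversion constants the analysis uses;
- an optional constant per-direction lateral offset as a crude stand-in for
  rotation hysteresis (default 0).

Defaults are a 1024×1024 panel at 0.4 mm pitch with SAD 1000 mm and SID
1600 mm (0.25 mm per pixel at isocenter scale), a 100 mm field, and pixel
noise with SD 2% of the open-field level — chosen so the simulated centroid
repeatability is of the same order as what a physical EPID/BB chain of this
class measures (a few hundredths of a millimeter). Determinism is strict:
each render derives its noise stream from the state seed plus a draw index,
so identical states reproduce bit-identical sessions.

What the simulator does *not* emulate — and therefore what passing tests do
not show about real machines: scatter, beam-energy and detector response
effects; panel sag or mounting tilt; couch sag under load; vertical wobble
during rotation (the gantry-0 method is blind to it, and the simulator
holds the vertical offset constant to match that blind spot); and real
braking hysteresis beyond the constant-offset knob. Closed-loop residuals
in simulation are consequently optimistic; the published-hardware figures
used as acceptance bounds (0.07 mm centroid repeatability, 0.16 mm caliper
tracking, 0.11 mm placement residual, 0.40 mm post-adjustment error) are
upper bounds the simulation must stay under, not values it should
reproduce.

## Problem sizes and numerical tolerances

Unit tests run the same physics on a 256×256 panel with a 40 mm field
(identical pitch, noise, blur, contrast) so the suite stays fast; the
acceptance tests and `scripts/acceptance.R` use the full-scale defaults.
Key tolerances: noiseless centroid recovery 0.01 mm; noiseless placement
recovery 0.02 mm per component; Kasa-vs-oracle agreement 0.05 mm;
free-radius constraint 10%; degenerate-cluster spread 0.05 mm; manifest
angle cross-check 0.5°. Each tolerance is either an explicit contract of
the corresponding function's documentation or a documented parameter
default.

## Known limitations

- Single-BB, open-square-field images only; MLC-shaped fields and multi-BB
  phantoms are out of scope.
- DICOM support is a read-only RTIMAGE subset (explicit-VR little endian,
  uncompressed 16-bit) sufficient for ingesting portal exports, not a
  conformant implementation.
- The method measures the horizontal-plane axis offset only; vertical
  couch behavior under rotation is invisible at gantry 0.
- Signs of service prescriptions must be reconciled against the vendor's
  convention once per site, as discussed above.
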