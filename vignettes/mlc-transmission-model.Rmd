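---
title: "A 2D ray-tracing model of rounded-end MLC leaf transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 2D ray-tracing model of rounded-end MLC leaf transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcray)
```

## The physical problem

Most C-arm linacs shape their photon beams with a multileaf collimator
(MLC) whose tungsten leaves travel linearly and end in a rounded
(circular-arc) tip.  Because the tip is curved, the edge of the
radiation field is not a sharp shadow: rays near the leaf end cross a
continuously varying thickness of tungsten, producing a partial
transmission band.  Two derived quantities matter clinically:

* the offset between the *light-field* edge (the ray tangent to the
  tip, called the visible ray, VR) and the *radiation* edge (the ray
  attenuated to 50%, XR) — the XR–VR offset, **XVO**; and
* the width of the partial-transmission band between the 80% and 20%
  crossings — the beam edge broadening, **BEB**.

Machine position calibration (to the light field) and treatment
planning system (TPS) fluence models commonly assume both are
*constant* with leaf position.  This package implements a
two-dimensional ray-tracing model of a single leaf to test that
assumption: it computes transmission curves at any parked tip position,
extracts VR/XR/BR and the XVO/BEB/TZW metrics, and locates the tip
position `X_break` where the quasi-static (constancy) assumption fails,
including a sweep of `X_break` against tip radius.

## The model

The leaf cross-section, in the plane containing the beam axis and the
travel axis, is a rectangle closed distally by a fitted circle of
radius $R \ge h/2$ centered on the leaf midline.  The circle meets the
top and bottom surfaces on a vertical chord at horizontal distance
$\sqrt{R^2-(h/2)^2}$ from the circle center; the sliver between that
chord and the arc is the *tip region*, the rectangle proximal of it the
*body*.  The two regions partition the leaf interior, so every ray
chord splits exactly into a tip segment and a body segment — the basis
of the path-length analysis.

The source is a point at the origin; depth $z$ increases toward the
isocenter plane at $z = \mathrm{SAD}$.  The proximal leaf surface sits
at $z = \mathrm{SCD}$.  A ray is identified by the position $x$ where
it crosses the isocenter plane, and all reported positions are
isocenter-plane projections ($x_{\mathrm{iso}} = x\,\mathrm{SAD}/z$).

Attenuation is single-valued and exponential: a perpendicular
transmission $T_\perp$ through the full height $h$ defines
$\mu = -\ln(T_\perp)/h$, and a ray with in-leaf chord $r$ transmits
$T(r) = e^{-\mu r}$.  No spectral weighting is applied; one $\mu$ per
run.

### Characteristic rays

* **TR** (tip ray): the projection of the physical tip apex — the
  leaf "position".
* **VR**: the ray tangent to the tip circle on the open-field side,
  solved in closed form.  If the tangent point would fall beyond the
  arc (possible at extreme off-axis positions), the silhouette edge is
  the arc/body corner and the ray through that corner is used instead.
* **BR**: the first ray containing no tip-region path: it passes
  through the partition-chord corner on the side where the slab
  constraint binds.
* **XR, x80, x20**: transmission-level crossings, from a swept curve
  (linear interpolation between bracketing samples) or from the
  closed-form path length with bracketed root finding
  (`analytic_crossings()`, bisection to 1e-10 cm).  The two routes are
  developed independently and checked against each other; on the
  benchmark geometry (8.00 cm radius, 6.13 cm height, 0.950 cm
  half-value layer) their XVO values agree to well below 0.1% at every
  clinical position.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `sad_cm` | 100.00 | source–isocenter distance |
| `scd_cm` | 51.0 | source to *proximal* leaf surface |
| `height_cm` | 6.60 (HDMLC) | leaf height along the beam |
| `tip_radius_cm` | 16.00 (HDMLC) | fitted tip-circle radius |
| `transmission` | 0.0122 (HDMLC, 6 MV flattened) | perpendicular CAX transmission |
| `body_length_cm` | 15 | rectangular body beyond the chord |
| sweep `step` | 1e-5 cm (curves), 1e-4 cm (position scans) | sample spacing |
| break `tolerance` | 0.005 cm | threshold detector deviation |

Body length is not a physical datum here; it only needs to be long
enough that no swept ray exits the proximal end face, which is asserted
at run time (the radius sweep enlarges it automatically for far-out tip
positions).

### Design choices that were genuinely open

**Vertical placement.**  "Source–collimator distance" could reference
the leaf top, center, or bottom; we take it as the proximal (top)
surface, the conventional reading, and expose it through `scd_cm` so it
can be overridden.  The choice moves absolute XVO/BEB by a few
thousandths of a centimeter.

**Bank orientation.**  The sign conventions of the modeled machine
correspond to a leaf whose body extends toward $+x$ (tip facing $-x$);
with that orientation the tip-zone-width minimum falls just short of
the CAX (TR $-1$ cm on a 1 cm grid, where the boundary ray comes
closest to vertical) and the constancy breaks sit asymmetrically
(farther out on the $+$ side).  The mirrored leaf gives exactly
mirrored series — an invariant the tests check — so `bank = "right"`
is only a reporting convention, chosen to match the machine
convention; `bank = "left"` is available.

**Tip position definition.**  TR is the projection of the circle's
distal-most point, which lies on the midline at $z = \mathrm{SCD} +
h/2$, consistent with the leaf being symmetric about its midline.
Note that when the apex sits exactly on the CAX the central ray itself
is tangent to the tip circle, so VR = TR = 0 there for *any* source
distance; the familiar VR–TR offset appears only off-axis.

**Break tolerance.**  The threshold detector compares each series
value against its CAX (TR = 0) value.  On the clinical HDMLC scan the
quasi-static plateau ripples by less than 0.003 cm within
$|\mathrm{TR}| \le 10$ cm while the post-break jumps exceed 0.008 cm
per 1 cm step, so 0.005 cm is a round value cleanly separating the two
regimes; it is the default for both XVO and BEB and is exposed as an
argument (and a CLI flag).

**Two break detectors.**  Because the exact numeric criterion behind
"deviates from near constancy" is a judgment call, the package also
provides a geometric detector that needs no tolerance at all: the
break is attributed to the level-crossing ray's intersection points
moving off the rounded end onto the leaf body, and
`detect_x_break_geometric()` bisects the tip position at which the
level ray (50% for XVO, 20% for BEB) first leaves the arc, to 0.05 cm.
The two detectors agree within 2 cm on the HDMLC; tests assert this.

**Radius sweep detector.**  For the `X_break`-versus-radius sweep the
geometric detector is the default.  The threshold variant is kept as
an option but documented as not guaranteed monotone in radius: for
small radii the slow off-axis drift of XVO crosses any fixed absolute
tolerance before the sharp geometric transition does, which buries the
phenomenon of interest under the drift.

## Numerical choices

* Sweep grids are anchored at the analytic tangent position so VR is
  always bracketed regardless of step; level crossings are refined by
  linear interpolation, removing grid quantization (halving the step
  moves interpolated metrics by less than the coarser step — tested).
* The leaf interior is treated as an open set: chord endpoints on the
  boundary contribute zero length, so the tangent ray itself and
  grazing rays have zero chord (up to floating-point residue below
  1e-4 cm at exact tangency).
* Degenerate geometry $R = h/2$ (a half-disk tip) is supported; the
  partition chord then passes through the circle center.
* Steps coarser than 1e-3 cm trigger a warning because interpolated
  edge metrics begin to degrade.

## Problem sizes

Position scans use 41 tip positions (−20 to 20 cm, 1 cm) at a sweep
step of 1e-4 cm, which resolves the interpolated crossings to ~1e-8 cm
and completes in under a second; single curves and the path-length
analyses use the full 1e-5 cm step (~1e5–2.5e5 samples per curve).
The validation comparison runs all 41 positions at 1e-5 cm.  The
radius sweep probes tip positions up to ±120 cm — far beyond the
physical travel range, deliberately, because small radii push the
break that far out.

## What the model does and does not capture

Passing tests show that the implementation reproduces the geometry and
attenuation of an idealized 2D leaf: a point source, a single
energy-independent transmission value, an infinitely wide leaf in the
third dimension, no tongue-and-groove steps, no drive-screw slot, no
inter- or intra-leaf leakage variation, no depth or lateral dependence
of transmission in water, and a static (parked) leaf rather than a
dynamic delivery.  Real measured edge widths include a finite source
size, so the 80–20 width here is an MLC-only edge broadening, not a
penumbra.  Conclusions about where constancy breaks are geometric
statements about this idealization; they transfer to a real machine
only to the extent that these neglected effects are second order near
the leaf end.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from the installed package, the
constancy-break positions, tip-zone extremes, path-length facts,
radius-sweep break and validation agreement, and writes them to JSON;
see the README for how to run it.
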