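---
title: "Plane-cluster sampling for ray-cast volume rendering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plane-cluster sampling for ray-cast volume rendering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planecast)
```

## The rendering model

planecast renders a regular 3D scalar grid (a CT-like volume) by orthographic
ray casting. Vertex $(i,j,k)$ of a grid with $E_x \times E_y \times E_z$
vertexes and spacing $(\Delta x, \Delta y, \Delta z)$ mm sits at world
position $(i\Delta x, j\Delta y, k\Delta z)$; the volume occupies the box
$[0,(E_x{-}1)\Delta x]\times[0,(E_y{-}1)\Delta y]\times[0,(E_z{-}1)\Delta z]$.
One ray per output pixel is clipped to this box (slab method) and sampled at
a fixed distance $\delta$ starting exactly at the entry distance. Per sample
a transfer function supplies a color $c_i$ and an opacity
$a_i \in [0,1]$, and the pixel color is the front-to-back accumulation

$$c_{out} = \sum_{i=0}^{n-1} c_i \prod_{j=0}^{i-1} (1 - a_j),$$

evaluated in a single pass with a running transparency product (an $O(n^2)$
literal expansion, `compositeBruteforce()`, is kept as an independent
oracle). Index 0 is the viewer-nearest sample — that is what gives $c_0$ the
empty (undimmed) product. A `backToFront` flag can reverse the sample order
for experimentation, but the front-to-back form is the contract the tests
pin down, because it is the form the accumulation formula states literally.

No opacity correction for $\delta$ is applied: halving the step brightens
the image. This keeps the compositing loop the exact literal sum, and is
documented here so users changing $\delta$ understand the brightness shift.

## The two samplers

**Traditional (trilinear).** Each sample point is converted to its voxel
index by floor division, $i = \lfloor x/\Delta x\rfloor$, with local
coordinates $x_n = (x - i\Delta x)/\Delta x \in [0,1]$, and the scalar is
reconstructed by three nested linear interpolations over the eight corner
values $I_0..I_7$: four lerps along $z$ ($F_1..F_4$), two along $x$
($F_5, F_6$), one along $y$ ($F$). The corner layout
($I_0=(i,j,k)$, $I_1=(i{+}1,j,k)$, $I_2=(i{+}1,j,k{+}1)$, $I_3=(i,j,k{+}1)$,
$I_4=(i,j{+}1,k)$, $I_5=(i{+}1,j{+}1,k)$, $I_6=(i{+}1,j{+}1,k{+}1)$,
$I_7=(i,j{+}1,k{+}1)$) is the unique assignment consistent with that chain.
This sampler is exact on all trilinear fields
$a + bx + cy + dz + exy + fyz + gxz + hxyz$, reproduces vertex values, and
is continuous across voxel faces — all asserted against an independent
8-weight oracle in the tests.

**Plane-cluster.** The grid induces three families of equidistant parallel
planes ($X_i = i\Delta x$, etc.). For the cluster along the ray's dominant
direction axis (say $y$), the intersection with plane $j$ is at ray distance
$t_j = (j\Delta y - y_o)/m$ with the other two coordinates from the ray
equation. The property at each intersection is interpolated from **three**
vertexes of the owning voxel face:

$$I_E = I_0 + (I_1 - I_0)\left(\frac{V_i}{\Delta x} - i\right)
            + (I_3 - I_0)\left(\frac{V_k}{\Delta z} - k\right).$$

This is a planar (affine) fit, not bilinear: the face's fourth, diagonal
corner is intentionally unused. Whether that omission is meant as an
approximation or is shorthand for on-face bilinear interpolation cannot be
settled from the method's description alone; this package implements the
literal three-vertex formula and keeps a bilinear oracle in the test suite
to pin the difference: for a face with an in-plane cross term of
coefficient $h$, the formula misses exactly $h/4$ at the face center. On
fields affine over the face the two coincide.

Each regular sample between consecutive intersections $E$ and $Q$ then
costs one definite-proportion division:

$$I_S = I_E + \frac{t - t_j}{t_{j+1} - t_j}\,(I_Q - I_E).$$

Because both the face formula and the segment formula are exact on affine
fields, the whole plane pathway is exact there, and renders of affine
phantoms by the two samplers are pixelwise identical — a property the test
suite asserts at $10^{-6}$.

## Axis choice and degenerate rays

The cluster axis is the one with the largest $|{\cdot}|$ direction
component (ties break $x \to y \to z$). This generalizes the fallback rule
"when a component is zero, use another axis": the dominant component is
never zero, and it also gives the densest bracketing. An explicit axis
override is available on `planeIntersections()`, `planeSampleRay()` and in
`renderConfig()` for users who want a fixed cluster.

Three degenerate situations need decisions the underlying formulas do not
make:

- **Upper box boundary.** A point exactly on the far face of an axis would
  floor to a voxel that does not exist; it clamps to the last voxel with
  local coordinate 1. Identical clamping is used in both samplers so they
  agree on boundaries.
- **The sliver outside the first/last intersection.** Sample positions
  between box entry and the first crossed plane have no bracketing pair.
  They extrapolate linearly from the nearest bracketing pair. Clamping to
  the nearest intersection value was considered and rejected: it is equally
  cheap but not exact on affine fields, which would break the
  pixelwise-identity property above (measured error up to ~3% of the pixel
  range on affine scenes).
- **Grazing rays.** A clipped segment that crosses fewer than two cluster
  planes cannot be bracketed at all. `planeSampleRay()` reports `NA` (no
  plane) or the single intersection's constant value; the renderer instead
  falls back to the trilinear baseline for such rays. They are rare
  (corner-grazing geometry) and the fallback keeps every pixel defined and
  exact where exactness is provable.

Exact incidence of a sample on an intersection needs no tie-break: the
segment formula's endpoint reproduces the face value.

## Classification order

Optical properties can be assigned to all vertexes first and then
interpolated (**pre-classification**, the default, matching the
assign-then-sample ordering of the classic pipeline description) or the
gray value can be interpolated and then classified (**post-classification**,
a config switch). The two orders commute wherever the transfer function is
linear over the gray values met along the ray — a property the render tests
check — and differ across control-point kinks, where pre-classification
smears the classified values and post-classification keeps them sharp.

## Operation counting

The cost comparison uses an instrumented counter: the sampling formulas are
re-executed scalar by scalar with every addition-class operation
(addition, subtraction) and multiplication-class operation (multiplication,
division) routed through a tallying cell; floor, comparison and assignment
are free. This convention is the unique simple one that makes the
traditional pathway cost exactly 17 additions and 16 multiplications per
sample (3 and 9 to locate the voxel: per axis one floor division, one
vertex-position multiply, one subtraction, one normalizing division; then
seven lerps at 2 additions and 1 multiplication each), hence 102/96 for six
points in two voxels, and the segment formula exactly 4 additions and 2
multiplications per sample (24/12 for six). Counts are
structure-determined — identical for any input values — and the instrumented
tallies are asserted equal to the closed-form products in the tests.

For one intersection point this package's accounting yields 9 additions and
8 multiplications (plane distance 1/2, ray coordinates 2/2, owning-voxel
floors 0/2, face formula 6/2 with the floor quotients reused). Published
accountings of the two-intersection cost differ in which divisions they
count and what they reuse; since no reuse convention reconstructs them
uniquely, the package asserts only the per-formula anchors above and prints
its own convention's totals in `opCountTable()`.

Wall-clock speedups are deliberately **not** an acceptance surface: they are
hardware- and implementation-bound. The arithmetic tallies are the portable
comparison.

## Phantoms: what the tests do and do not show

All validation runs on synthetic phantoms with known closed forms:
`constant`, `affine` and `trilinear` (the samplers' exactness classes),
`sphere` and `shell` (hard edges), `gaussian_blob` (smooth compact support),
and `head_like` (a deterministic ellipsoidal "bone" shell around smooth
"soft tissue" with seeded bumps, in a 0–3000 CT-like gray range). Default
extents are $64 \times 64 \times 37$ at $0.486 \times 0.486 \times 0.700$ mm
— a reduced-scale grid with the anisotropic z-spacing typical of clinical CT,
so spacing-dependent behavior is exercised. Identical specs (including the
seed) produce bit-identical volumes, and generation does not disturb the
global RNG stream.

The image-equivalence test renders the Gaussian blob at
$\delta = 0.3\cdot\min(\Delta x,\Delta y,\Delta z)$ with both samplers and requires normalized RMSE
(RMSE over the reference image's dynamic range) below 0.02 — a quantitative
stand-in for visual indistinguishability on smooth data. What these tests
do **not** show: behavior on real CT noise, partial-volume effects at tissue
interfaces sharper than the grid, or transfer functions with many kinks,
where the three-vertex face approximation and pre-classification smearing
both grow. The phantoms bound the method's numerics, not its clinical
appearance.

## Problem sizes and numerical choices

Test and acceptance runs use $64^3$-scale volumes and $64 \times 64$ images
(about $1.3\times10^5$ samples per sampler per render) — large enough to
cross hundreds of voxel boundaries per ray while keeping the whole suite in
seconds. Tolerances: exactness properties at $10^{-9}$ (accumulated fp error
over a few dozen flops), compositing oracle equivalence at $10^{-12}$,
geometric residuals (plane and ray equations) at $10^{-9}$ mm. Box
membership checks allow $10^{-9}$-relative slack so samples produced by
clipping are never rejected by downstream floor operations. Ray directions
are normalized at construction so all $t$ values are metric (mm).

## Known limitations

- Orthographic camera only; the projection and in-plane frame rule
  ($u = \hat\zeta \times a$ normalized with $a = +z$, or $+x$ for nearly
  axial views; $v = u \times \hat\zeta$) are package conventions, since a
  camera model is not part of the sampling method itself.
- Single-channel (luminance) rendering by default; RGB transfer functions
  are supported but all channels share one opacity.
- No gradient shading, no perspective, no empty-space skipping; the point
  is sampler numerics, not rendering features.
- `float32` raw storage truncates doubles; use `float64` for lossless
  round trips.
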