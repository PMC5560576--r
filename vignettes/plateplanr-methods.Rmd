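---
title: "Geometric methods behind plateplanr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric methods behind plateplanr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateplanr)
```

`plateplanr` plans the placement of straight osteosynthesis miniplates on a
triangulated bone surface. This vignette documents the geometric model, the
tunable parameters and their defaults, the numerical choices, and the design
decisions that were genuinely open — in enough detail that a maintainer can
predict the package's behaviour without reading the code.

All coordinates are millimetres. STL itself is unitless; the package declares
mm throughout, consistent with catalog plate lengths of 23–35 mm.

## The baseline model

A miniplate is planned in two stages. The first stage reduces the plate to a
**baseline**: an ordered chain of markers on the bone surface, each holding a
position $p_i$, the flat normal $N_i$ of the triangle it lies on, and a unit
tangent $D_i$ pointing to the next marker. The baseline carries everything
placement needs — position, direction, and the surface curvature along the
intended plate path — at a fraction of the cost of building the full implant
mesh.

Markers are found by ray casting. The ray–triangle kernel is the
Möller–Trumbore change-of-basis solution: for ray origin $O$ and direction
$D$, solve

$$O + t\,D = (1-u-v)\,V_0 + u\,V_1 + v\,V_2$$

for $(t, u, v)$ directly via triple products, accepting a hit when
$u \ge 0$, $v \ge 0$, $u + v \le 1$ and $t > \varepsilon$. The triangle's
plane equation is never formed. Two numerical choices:

* $\varepsilon = 10^{-9}$ both for the determinant (rays parallel to the
  plane are no-hits) and as the minimum accepted $t$, so a ray whose origin
  lies exactly on the surface does not hit it at $t = 0$;
* hits are accepted from **either side** (no backface culling): rays are cast
  along $-N$ onto the outward-facing surface, and patient meshes have
  imperfect winding, so hit acceptance must be orientation-agnostic.

`cast_ray()` is an exhaustive scan over all faces, returning the minimal-$t$
hit with ties broken by lowest face index. The exhaustive scan *is* the
reference semantics; no acceleration structure is used, which is adequate for
desk-scale meshes (the 20 000-face fixtures here cast in ~10 ms, and meshes
up to a few hundred thousand faces remain practical).

Normals are flat per-face — the nearest triangle's normal, not a
vertex-interpolated one. Whether smoothing would be preferable is surfaced as
a deliberate non-choice: interpolated normals would require well-defined
vertex normals on facet-soup STL input, and flat normals are what the ray
hits actually provide.

### Two trace modes

`trace_cascade()` is the literal construction: from the seed frame (foot
point, normal $N$, direction $D$), ray origins are laid out on the straight
line $\text{foot} + s\,D + \text{lift}\,N$ for
$s \in \{-L/2, -L/2+\Delta, \dots, L/2\}$ and all rays are cast along the
one fixed $-N$. This is simple and exactly reproduces the plate length on a
flat surface, but a single global cast direction cannot place markers on a
face parallel to it (a 90° step's vertical wall), and on strongly curved
surfaces the marker *arc* spacing grows with the slope.

`trace_marching()` (the default) grows the baseline symmetrically from the
center marker and recomputes the frame at every step: $N_i$ is the hit
face's normal and $D_i$ is the previous direction re-projected into the new
tangent plane. The next origin is $p_i + \Delta\,D_i + \text{lift}\,N_i$,
cast along $-N_i$. Two failure signatures get corner handling: if the cast
misses entirely, or lands farther than $2\Delta$ from the current marker,
the frame $(D, N)$ is rotated $\pm 90°$ about $D \times N$ — concave first
(climbing a wall that rises ahead: $(D,N) \to (N,-D)$), then convex (walking
off an edge: $(D,N) \to (-N,D)$) — and the cast retried. The accepted-step
bound of $2\Delta$ doubles as the baseline invariant that consecutive
markers are never farther apart than twice the spacing. This corner rule is
the package's own mechanism: the behaviour (baselines that follow waves and
right-angle steps) is what is specified; the mechanism behind the original
interactive tool is not described, and a plain re-projected march provably
cannot land markers on a wall parallel to its cast direction.

Each arm takes a step only while
$\text{arc} + \Delta \le L/2 + \Delta/2$, so on flat and axis-aligned step
surfaces the total arc length equals the request exactly, and in general it
is within about one spacing (slightly more on steep waves, where a tangent
step of $\Delta$ covers more than $\Delta$ of arc — the same overshoot the
cascade has).

On a flat plane the two modes agree to $10^{-9}$ mm, which is tested, as are:
marker adherence to the analytic wave and step surfaces (< 0.05 mm),
rotation equivariance of the trace angle, and arc-length calibration (the
contract that makes catalog lengths testable end-to-end).

### Parameters

| parameter | default | units | why |
|---|---|---|---|
| `spacing` | 0.5 | mm | one marker every half millimetre gives ≥ 2 interior cross-sections even on the shortest catalog bar (1.17 mm), honoring the at-least-two-blocks bridge rule |
| `lift` | 10 | mm | ray-origin height; must exceed local relief between neighbouring markers — 10 mm clears the 10 mm step fixture and typical craniofacial relief |
| `angle` | — | rad | trace orientation about the seed normal; replaces interactive mouse-wheel rotation |
| `mode` | marching | — | cascade retained for fidelity to the parallel-ray construction and for tests |

The reference tangent for angle 0 is the global $+x$ axis projected into the
tangent plane, falling back to $+y$ when the normal is within 0.99 of
$\pm x$ — deterministic and resolution-independent.

## The plate catalog and its layout closure

A plate is parameterized by ring counts, overall length, cross-section
dimensions and bar lengths. Ring elements are annuli (outer diameter $d$,
screw hole, thickness) with flat chordal sides where bars attach; the chord
for a bar of width $w$ sits at $x_c = \sqrt{(d/2)^2 - (w/2)^2}$ from the
ring center, so a ring's footprint between two attachment faces is the
**attachment width** $2 x_c < d$.

Bar lengths in the catalog are the *physical face-to-face bridge lengths*.
Consecutive ring centers are therefore spaced by $2x_c + \text{bar}$, and
the layout closes on the printed overall length $L$:

$$L = d + (n-1)\,·\,2x_c + \sum_j \text{bar}_j ,$$

the end rings contributing one radius each beyond the outermost centers.
This convention was a genuine design decision. The alternative — spacing
centers by the full diameter $d$ — makes the two printed dimensions of the
29 mm model mutually inconsistent: its central bar is printed as 9 mm, and
under diameter spacing the face-to-face bar would measure
$9 + (d - 2x_c) \approx 9.6$ mm, while under the face-to-face convention
both the overall length and the central bar are reproduced exactly on a flat
surface. Given only printed lengths, the free bars are solved from the
closure: all equal when no bar is pinned; with a pinned 9 mm central bar the
remaining bars are equal. For the shipped catalog
($d = 4$, $w = 2$, so $2x_c = 2\sqrt{3} \approx 3.464$):

```{r catalog}
for (id in c("M-4138", "M-4320", "M-4322")) print(get_plate_spec(id))
```

Only the overall lengths (23/29/35 mm) and the 9 mm bar are catalog-printed;
the cross-section defaults (ring OD 4.0 mm, hole 2.0 mm, thickness 1.0 mm,
bridge 2.0 × 1.0 mm) are the package's own choices, consistent with a 2.0 mm
screw system, and are overridable per model in
`inst/extdata/plate_catalog.yaml`. A diameter of 5 mm was rejected because
six such rings plus a 9 mm bar cannot fit a 35 mm plate (the closure would
need negative bars); 4 mm keeps every catalog bar positive. The 35 mm model
pins its central bar at 9 mm and solves the four remaining bars equal
(1.17 mm); treating it as "the 29 mm model plus one extra ring and bar per
side" also yields negative bars, so that reading was rejected. Likewise, the
9 mm figure is taken as the central bar's total length, not as an extension
(23 + 9 ≠ 29 rules out the extension reading for overall lengths).

Ring meshes are built parametrically as watertight solids (every edge shared
by exactly two faces, verified in tests): four vertex rings (outer/inner ×
top/bottom) over a shared angle list, with the outer boundary clamped to the
chord plane(s) and the chord corner angles inserted into the angle list so
the four attachment-face corners are exact mesh vertices. End rings have one
flat side (+x), middle rings two (±x). `attachment_corners()` computes the
face corners analytically in the canonical frame; tests confirm they
coincide with an exhaustive nearest-vertex search on the built mesh (the
search is the oracle, the analytic corners the implementation). Screw holes
are plain cylinders — countersinks and threading are not modelled.

## Ring placement and bridge sweeping

`place_rings()` maps each catalog offset (symmetric about 0) to the arc
position `arc_length/2 + offset` on the baseline via `point_at_arc()`, which
interpolates positions linearly and takes normal/tangent from the nearer
marker. The pose of a ring is composed of:

1. `rotation_between(z, N)` — the minimal (Rodrigues) rotation taking the
   canonical ring normal to the marker normal; the antipodal case falls back
   to a rotation by π about a deterministic perpendicular axis;
2. a rotation about $N$ aligning the mapped canonical $+x$ with the marker
   tangent's projection onto the tangent plane.

The normal is thus aligned in full 3D and the direction only within the
tangent plane — full 3D direction alignment is impossible because the
marker's normal and tangent need not be perpendicular, while the ring's are.
The final end ring is placed with its tangent reversed so its single
attachment side faces its bridge. Rings are rigid: placement is a proper
isometry of the canonical template (pairwise vertex distances preserved to
$10^{-9}$ relative, tested on plane, wave and hemisphere).

Bridges connect consecutive attachment faces. The cross-section sequence is:
the near ring's transformed attachment corners; a rectangle
(`bridge_cross_rect()`) at every baseline marker whose arc position lies
strictly between the two faces; the far ring's corners. Every strictly
interior marker is used (no subsampling), which guarantees at least two
blocks per bridge at the default spacing. Each rectangle is spanned by the
lateral axis $D \times N$ (width) and the marker normal (height); torsion
between consecutive rectangles is not minimized (no parallel transport) —
the construction is deliberately per-marker. The far face's corners are
re-ordered into the marker convention (a fixed index permutation, derived
from the frame algebra) so the sweep attaches without twist. Triangulation
is per side quad: $T_1 = (N_1, N_2, N_3)$, $T_2 = (N_1, N_3, N_4)$, exactly
$8(k-1)$ triangles for $k$ rectangles, wound outward. Bridge ends stay open:
they abut the ring faces, whose corner vertices they reuse exactly, but the
merged implant is not welded into one watertight solid — merging is pure
concatenation so that face counts stay exact bookkeeping sums, which the
tests rely on.

Two placement conventions worth knowing:

* By default rings sit with their **mid-plane through the marker**, so half
  the plate thickness interpenetrates the surface, as in typical planning
  renderings; `surface_offset = thickness/2` (CLI `--surface-offset`) lifts
  the plate fully above the surface. The flat-plane tests assert the
  mid-plane bound ($z \ge -t/2$).
* Plate–bone intersection is never detected or prevented;
  `implant_clearance()` reports the minimum signed clearance as a diagnostic
  (on a deterministic subsample of implant vertices) but never blocks
  assembly.

## STL input and output

STL is the sole interchange format, in both dialects. Binary files follow
the de-facto little-endian layout (80-byte header, uint32 facet count,
50-byte facets; attribute byte count written as 0 and ignored on read), so a
binary file is $84 + 50m$ bytes and round-trips are bit-exact for
coordinates representable in single precision. Dialect detection trusts the
byte-count arithmetic first and the `solid` keyword second (binary files may
legally start with "solid"). Because STL stores a facet soup, import welds
coincident vertices on a $10^{-6}$ mm quantization grid — fine enough to
never merge distinct features at plate scale, coarse enough to restore
shared topology for adjacency and nearest-triangle queries. Zero-area facets
are dropped with a warning rather than an error. Parse errors name the byte
or line offset. No mesh repair, decimation or smoothing is performed, and
DICOM/CT segmentation is out of scope: input is already a surface.

## Synthetic fixtures and what passing them shows

The four generators are deterministic (bit-identical meshes for identical
parameters; grid diagonals split lower-left to upper-right):

* `make_plane()` — ground truth for lengths: on a flat surface the assembled
  implant must be the straight catalog plate, end-to-end extents
  23/29/35 mm within one marker spacing;
* `make_wave()` (defaults amplitude 5 mm, wavelength 40 mm — large relative
  to plate length so curvature effects are visible) — smooth-adherence
  checks against the analytic height;
* `make_step()` (default 10 mm) — the corner-handling stress test;
* `make_hemisphere()` — smooth doubly-curved stand-in for a skull cap.

Fixture resolutions in the tests are chosen so that mesh discretization sits
well below the 0.05 mm adherence tolerance (a wave gridded at 1 mm has facet
sag ≈ 0.015 mm). One consequence worth stating: markers lie on the *mesh*,
so their deviation from the *analytic* surface can never beat the facet sag
— on a resolution-100 hemisphere of radius 50 mm that is ≈ 1.5 × 10⁻³ mm,
which is why hemisphere adherence is asserted against the sag bound, not
against an absolute 10⁻⁶.

These fixtures emulate curvature regimes, not anatomy: they have no noise,
no holes, no self-intersections, no winding defects and no anisotropic
triangulation. Passing them validates the geometry kernel and the assembly
bookkeeping; it does not certify behaviour on segmentation artefacts, and
real patient meshes should be visually reviewed after planning (the
exported STL makes that cheap).

## Problem sizes and determinism

The test suite and the acceptance script run on fixtures of 5 000–20 000
faces with baselines of 47–71 markers; a full trace-and-assemble cycle takes
well under a second per plate at these sizes. Nothing in the pipeline is
random: traces, ring builds and exports are deterministic, and identical
configurations produce byte-identical binary STL outputs (tested). The only
randomness anywhere is in the property tests' instance generators, which run
under fixed seeds.

## Known limitations

* No pre-bent or circular plate variants; straight plates only.
* No screws, drill trajectories, or bending mechanics.
* The merged implant is not globally watertight (open bridge/ring seams share
  vertices but faces are not re-welded); slicers tolerate this, but
  downstream tools demanding 2-manifold input may need a welding pass.
* Baselines longer than the locally traceable surface are truncated with a
  warning (missed rays are skipped; > 50 % missed is an error).
* `cast_ray()` is an exhaustive scan; very large meshes (millions of faces)
  would need an acceleration structure, which would be required to match the
  scan exactly.
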