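# plateplanr

Headless computer-aided position planning of osteosynthesis **miniplates** on
bone surface meshes.

Facial fractures are stabilized with small titanium plates — chains of annular
screw-hole ring elements joined by rectangular bars — that the surgeon must
bend intra-operatively to fit the bone contour. `plateplanr` lets a planner
pre-compute that fit on a CT-derived surface mesh (STL): pick a seed point and
an orientation angle, and the package

1. traces a **baseline** — an ordered chain of on-surface markers (position
   `p_i`, facet normal `N_i`, tangent `D_i`) that stands in for the plate —
   by casting rays onto the triangulated surface with the
   **Möller–Trumbore** ray–triangle intersection, which solves the hit record
   `(t, u, v)ᵀ` (distance along the ray plus barycentric coordinates) by a
   change of basis without ever forming the triangle's plane equation;
2. places each catalog ring element rigidly at its arc-length position: the
   ring normal is aligned to the marker normal in full 3D
   (Rodrigues rotation `R: z → N_i`), then the attachment direction is
   aligned to the marker tangent *within the tangent plane only* — `N_i` and
   `D_i` need not be perpendicular on a curved surface, while the ring's own
   frame always is;
3. sweeps each **bridge section** through a cross-section rectangle at every
   intermediate baseline marker and triangulates consecutive rectangle pairs
   (per side quad: `T1 = (N1, N2, N3)`, `T2 = (N1, N3, N4)`, so a bridge with
   `k` rectangles has exactly `8·(k − 1)` triangles);
4. exports the assembled implant — or a whole multi-implant planning
   session — as ASCII or binary STL, ready for 3D printing a bending
   template.

The shipped catalog holds three straight plates of a 2.0 screw system:
**M-4138** (23 mm, 2 end + 2 middle rings), **M-4320** (29 mm, 9 mm central
bar) and **M-4322** (35 mm, 4 middle rings). The catalog is a plain YAML file
(`inst/extdata/plate_catalog.yaml`); new models need no code changes.

Synthetic validation surfaces — plane, sinusoidal wave, right-angle step,
hemisphere — are built in (`make_plane()`, `make_wave()`, `make_step()`,
`make_hemisphere()`), so everything can be exercised without patient data.

## Worked example

```r
library(plateplanr)

bone <- make_hemisphere(radius = 50, resolution = 100)  # skull-cap stand-in
spec <- get_plate_spec("M-4320")
spec
#> <plate_spec> M-4320: 2 end + 2 middle rings, overall 29 mm
#>   bars [mm]: 2.80385, 9, 2.80385
#>   ring OD 4, hole 2, thickness 1, bridge 2 x 1 mm

bl <- trace_baseline(bone, seed = c(0, 0, 60), angle = pi / 6,
                     length = spec$overall_length)
bl
#> <baseline> 59 markers, mode marching, spacing 0.5 mm, arc length 29.0007 mm

implant <- assemble_implant(bone, bl, spec)
implant
#> <implant_model> M-4320: 4 rings, 3 bridges, 2400 faces

write_stl(implant$mesh, "m4320_dome.stl")   # binary STL, 120084 bytes
```

The seed `(0, 0, 60)` is projected onto the dome apex; 59 markers spaced
0.5 mm give an arc length of 29.0007 mm — the plate's overall length plus the
curvature overshoot of one marching step. All four ring centers land on the
triangulated sphere at radius 49.998 mm (the facets of a resolution-100
hemisphere sag ≈ 1.5 × 10⁻³ mm below the analytic sphere, and the rings sit
on the facets). The 2400 faces are the exact bookkeeping sum: two end rings
of 528 faces, two middle rings of 544, plus `8·(k−1)` triangles per bridge
(256 in total).

Multi-implant sessions mirror the save/export split of an interactive
planner: `set_current()`, `save_current()` (immutable), then
`export_session()` writes one combined STL.

## Command line

A thin Rscript front-end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "plateplanr.R", package = "plateplanr"))')
Rscript "$CLI" fixture wave --out wave.stl --resolution 101
Rscript "$CLI" place --mesh wave.stl --seed 0,0,0 --angle 30 \
               --model M-4320 --out implant.stl
Rscript "$CLI" batch --config plans.yml --out session.stl
```

## Scope

The package is a headless planning library: it does not read DICOM or
segment CT volumes (input is an STL surface), does not detect or prevent
plate–bone interpenetration (a signed-clearance diagnostic,
`implant_clearance()`, is provided), and does not simulate titanium bending
or screw trajectories. See the methods vignette
(`vignettes/plateplanr-methods.Rmd`) for the geometric model, parameter
defaults and design decisions.
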