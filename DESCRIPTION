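Package: plateplanr
Title: Computer-Aided Position Planning of Osteosynthesis Miniplates on Bone Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Headless planning of osteosynthesis miniplate placement on
    CT-derived bone surface meshes. Traces a surface-adherent baseline from a
    seed point and orientation angle by casting rays onto a triangulated
    surface (Moeller-Trumbore ray-triangle intersection), assembles a catalog
    miniplate (annular ring elements joined by swept, triangulated bridge
    sections) along the baseline, and exports the result as STL for 3D
    printing of bending templates. Includes an STL reader/writer (ASCII and
    binary), synthetic test surfaces (plane, sinusoidal wave, right-angle
    step, hemisphere), a parametric plate catalog, and a command-line
    interface for single and multi-implant planning sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
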