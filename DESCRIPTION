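Package: petworld
Title: Mesoscale Molecular Model Building with Coarse-Grained Pet Atoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling mesoscale biomolecular models from an
    intermediate coarse-grained representation in which molecules are shrunk
    to one tenth of their size and approximated by bonded spherical "pet
    atoms" (twelve pseudo-elements with van der Waals radii 0.1 to 1.2
    Angstrom). Includes the two-pass density-grid shrinking algorithm,
    sequence-based builders for single- and double-stranded pet nucleic
    acids, rule-based transmembrane-segment detection and membrane
    orientation, construction of rhombic pet membrane blocks and greedy
    rhombus tessellation of triangle meshes, AMBER-functional-form force
    field parameter assignment with energy evaluation and minimization,
    expansion back to instanced all-atom models, reduced level-of-detail
    isosurface meshing from density grids, and mmCIF input/output with
    per-object instancing extensions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: bio3d, stats, grDevices
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
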