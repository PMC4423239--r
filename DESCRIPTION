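Package: aptastruct
Title: Structural Annotation of Mirror-Image Aptamer Complexes and SPR Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural and biophysical analysis of mirror-image
    (L-configured) nucleic-acid aptamers (Spiegelmers) in complex with protein
    targets. Reads PDB/mmCIF coordinates into a flat atom table, detects sugar
    chirality and performs exact mirror transforms, annotates nucleotide
    conformation (glycosidic syn/anti, sugar pucker by pseudorotation),
    detects hydrogen bonds, base pairs, G-tetrads and G-quadruplex topology,
    characterizes metal-ion coordination spheres and scores ion identity
    against canonical metal-oxygen distance statistics, computes solvent
    accessible and buried surface areas with interface footprints, performs
    Kabsch rigid-body superposition, and simulates and fits surface plasmon
    resonance sensorgrams under a 1:1 Langmuir model with mass-transport
    limitation. Includes deterministic synthetic-structure generators (ideal
    A-form duplexes in D and L chirality, stacked G-tetrads with channel ions,
    ion coordination sites, sphere clusters) so every algorithm is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
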