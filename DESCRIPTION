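Package: ringscan
Title: Structural and Evolutionary Survey of RING-Domain E3 Ubiquitin Ligases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative survey of RING-domain E3 ubiquitin
    ligases: classification of RING types from zinc-ligand residue patterns,
    consensus and conservation scoring of alignment columns with a
    residue-class alphabet, detection of structurally conserved regions from
    superposed C-alpha ensembles, hydrophobic-core and solvent-accessibility
    analysis, tiered E2/E3 interface contact mapping, reciprocal-best-hit
    orthology and domain-architecture comparison.  Includes seeded synthetic
    generators that emit every input format with planted ground truth so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
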