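Package: structvar
Title: Structure-Based Annotation of Disease-Associated Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates and explains missense variants on predicted protein
    structure models. Residues are quality-gated by per-residue model
    confidence (pLDDT), mutations are tested for proximity (5 Angstrom,
    heavy-atom) to predicted ligand-binding sites, protein-protein
    interfaces and conserved positions, for structural destabilization
    (ddG) and for predicted pathogenicity, and evidence is merged across
    two structure models of the same domain. Includes Shrake-Rupley
    solvent accessibility with relative-accessibility burial calls,
    scorecons-style conservation scoring with alignment diversity metrics
    (Neff, DOPs), cell-list neighbor search, Kabsch superposition, a
    disease-versus-polymorphism cohort comparison (Mann-Whitney tests and
    amino-acid composition enrichment), and a synthetic-data generator
    that produces complete input bundles with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
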