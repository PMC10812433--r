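Package: contactmap
Title: Contact-Based Analysis of Protein-Protein Interfaces and Ligand
    Recognition Ensembles
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise how a receptor protein recognises an
    ensemble of protein ligands from the structures of their complexes.
    Extracts and types interfacial contacts, predicts binding free energy
    from interfacial-contact counts and non-interacting-surface composition
    (the IC/NIS linear model), converts free energies to dissociation
    constants, performs alanine-scanning of interface residues, aggregates
    per-residue contact frequencies across complex ensembles to call
    statistical "contact hot spots", builds C-alpha contact and
    energy-weighted residue networks (centralities, hydropathy-class
    subnetworks, energy neighbours), assembles contact areas by category,
    and projects residue sets onto homologous structures through
    sequence-guided rigid superposition (Needleman-Wunsch + Kabsch).
    Includes synthetic-data generators with exact ground truth so that the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
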