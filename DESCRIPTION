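Package: holophos
Title: Discriminating Inter-Holoenzyme Phosphorylation from Subunit
    Exchange in CaMKII
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analyses that distinguish inter-holoenzyme
    trans-autophosphorylation from subunit exchange in
    calcium/calmodulin-dependent protein kinase II (CaMKII).  Provides a
    global two-component kinetic model for concentration-dependent
    autophosphorylation time courses, mixed-isotope (14N/15N)
    crosslinking mass-spectrometry quantification (heterotypic/homotypic
    mixing ratios, domain-pair heatmaps, crosslink-to-structure
    C-alpha distance mapping), Gaussian-mixture decomposition of
    mass-photometry particle-mass distributions with oligomer assignment
    and monomer-fraction bookkeeping, single-molecule TIRF colocalization
    scoring (top-fraction threshold masks, Pearson correlation, Dunnett
    many-to-one comparisons), and seeded synthetic-data generators with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    multcomp,
    jsonlite,
    yaml,
    tiff,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
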