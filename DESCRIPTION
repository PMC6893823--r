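Package: pvlBBB
Title: In Silico Blood-Brain-Barrier Permeability Screening of
    Phenyl-gamma-valerolactone and Phenylvaleric Acid Metabolites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for screening gut-microbial flavan-3-ol metabolites
    (phenyl-gamma-valerolactones, phenylvaleric acids and their phase-II
    sulfate, glucuronide and methyl conjugates) for predicted blood-brain
    barrier permeability. Enumerates the circulating metabolite library from
    a scaffold and conjugation grammar, computes a twelve-descriptor
    physicochemical panel with open QSPR models (topological polar surface
    area, atomic-contribution logP, linear logBB and permeability
    regressions, grid-based van der Waals volume and point-charge dipole),
    scores drug-likeness (Lipinski rule of five, reduced star count) and a
    0-12 BBB permeation score against curated descriptor ranges, and
    analyses the descriptor space by principal component analysis with
    silhouette statistics for conjugation-class clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    ChemmineR,
    ChemmineOB,
    cluster,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Cheminformatics, Metabolomics, QSAR
RoxygenNote: 7.3.3
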