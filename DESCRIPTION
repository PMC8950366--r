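Package: CypDiscriminant
Title: Fe-Heme Distance Discriminant for CYP2D6 Substrate Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semi-quantitative assessment of cytochrome P450 2D6 (CYP2D6)
    substrate metabolism from structural trajectories. The discriminant is
    the per-frame distance between a ligand's reactive atom (the atom at
    which hydroxylation or demethylation occurs) and the heme iron,
    summarised as mean +/- SE over frames and compared between missense
    variants and the wild-type enzyme with two-sample t tests. Includes
    Kabsch superposition and RMSD stability series, sustained-detachment
    detection, CYP2D6 star-allele bookkeeping with a ddG stability rule,
    heme-binding-motif scanning and MSA column conservation, and an
    Ornstein-Uhlenbeck synthetic-data generator that emulates the
    statistical structure of molecular-dynamics distance traces at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'structure_io.R'
    'variant_model.R'
    'geometry.R'
    'discriminant_stats.R'
    'conservation_msa.R'
    'synthetic_data.R'
    'pipeline.R'
    'plots.R'
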