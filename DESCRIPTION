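Package: varstab
Title: Missense Variant Triage and Protein Stability Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for triaging genetic variants in a protein-coding gene
    and quantifying their structural and kinetic consequences. Implements
    consensus deleteriousness classification of missense variants from an
    eight-predictor panel, codon-usage relative-adaptiveness profiling and
    rare-codon cluster detection for synonymous variants, rigid-body
    (Kabsch) superposition analytics for molecular-dynamics trajectories
    (RMSD, per-residue RMSF, radius of gyration, equilibrium-window
    statistics and group comparison), and first-order degradation kinetics
    with half-life estimation from cycloheximide-chase densitometry.
    Seeded synthetic-data generators with ground-truth manifests allow
    every stage to be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
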