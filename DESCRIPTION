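Package: nucdyn
Title: Trajectory Analysis of Canonical and Partially Disassembled Nucleosomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Post-processing toolkit for molecular-dynamics trajectories of
    nucleosome-like DNA-histone complexes, including nucleosomes lacking one
    histone dimer (hexasomes and H3/H4-deleted models). Provides rigid-body
    Kabsch superposition under two alignment conventions (whole complex
    without histone tails, or histone cores only), RMSD time series,
    per-nucleotide C1' RMSF profiles, essential-dynamics PCA of nucleosomal
    DNA with mode projections and kernel-density free-energy landscapes,
    nucleotide-amino-acid contact-frequency matrices under a C1'-Calpha
    distance cutoff, backbone hydrogen-bond based alpha-helix occupancy, and
    a deterministic synthetic-trajectory generator that emulates DNA
    breathing and histone-tail repositioning for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    MASS,
    stats,
    utils,
    tools,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
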