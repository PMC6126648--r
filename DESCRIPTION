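Package: loopgraft
Title: Homology-Based Completion of Missing Protein Loops in Crystallographic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects unmodeled internal loops in crystallographic protein
    structure models and rebuilds them by grafting the equivalent region
    from homologous structures. Candidate loops are superposed onto the
    anchor residues flanking the gap with a quaternion least-squares fit,
    screened by a clash-importance hierarchy (including crystallographic
    symmetry mates), regularized by restrained real-space refinement
    against an electron-density map, and accepted or rejected on geometric
    restraint Z scores, peptide-bond omega angles, a Ramachandran Z score
    with a Grubbs outlier comparison, and a loop-to-control density ratio.
    Also includes reconstruction of one to three missing peptide-backbone
    atoms from peptide-plane geometry, terminal-oxygen (OXT) completion,
    occupancy normalization, and a synthetic-fixture generator (ideal
    backbones, perturbed homologs, Gaussian-atom density maps) so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    bio3d,
    Biostrings,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
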