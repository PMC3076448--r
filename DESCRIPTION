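Package: curvafm
Title: Sequence-Encoded DNA Curvature, Duplex Stability and AFM Single-Molecule Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts intrinsic DNA curvature and sequence-encoded supercoiling from
    primary sequence with a dinucleotide wedge-angle trajectory model and a
    phasing-pitch-scanned Ends-ratio statistic, computes sliding-window duplex
    stability (free energy) profiles from nearest-neighbor thermodynamics, and
    quantifies atomic force microscopy height images of single DNA molecules:
    background flattening, skeletonization and sub-pixel contour tracing,
    sequence-based molecule orientation, nucleosome dyad and bound-protein
    mapping, loop detection, and time-lapse tracking of the curvature apex.
    Includes seeded synthetic generators for phased A/T-tract promoter-like
    sequences and AFM-like images of two-dimensionally equilibrated worm-like
    chains, so every stage of the analysis runs against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
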