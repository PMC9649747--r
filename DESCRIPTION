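Package: megastitch
Title: Fragment Assembly and Tunnel Profiling for Megaprotein Structure Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assembling full-length structural models of very large
    (megadalton-scale) single-chain proteins from overlapping fragment
    predictions, and for characterizing the assembled models. Plans
    overlapping fragment windows for sequences that exceed a structure
    predictor's length limit, superposes neighbouring fragments on their
    shared residues by constrained least-squares (Kabsch) fitting, and
    splices them into a single model with junction quality metrics.
    Downstream characterization includes rod-length measurement, a
    HOLE-style maximal-ball radius profile along an estimated central axis,
    lining-residue hydrophobicity, pseudo-side-chain modelling of
    point-mutation tunnel blockage, and sequence-level annotation of
    transmembrane hydropathy segments, amphipathic (hydrophobic-moment)
    windows and polybasic motifs. A seeded synthetic-tube generator
    provides ground-truthed benchmark structures for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
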