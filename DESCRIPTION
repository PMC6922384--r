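Package: mbandIg
Title: Structural Fingerprinting of Titin M-Band Immunoglobulin Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative structural analysis of the immunoglobulin (Ig) domains
    of the titin M-band segment. Provides rigid-body (Kabsch) superposition with
    iterative core trimming, structure-based pairwise and reference-anchored
    multiple alignment of Ig folds, per-residue spatial deviation profiles,
    Kabsch-Sander style backbone hydrogen-bond detection with beta-sheet strand
    labelling (A, A', B, C, C', D, E, F, G) and cross-structure hydrogen-bond
    conservation counting, Shrake-Rupley solvent accessibility with cysteine
    redox classification and disulfide/metal-site detection, Bjellqvist
    isoelectric points, cross-species conservation categorisation, and
    structural annotation of missense variants mapped from full-length titin
    coordinates. Includes a deterministic generator of idealized beta-sandwich
    folds and sequence families with planted ground truth, so the whole
    pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
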